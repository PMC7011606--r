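#' Stratified random train/test split plan
#'
#' Reproduces the evaluation protocol: the labeled action instances are
#' randomly split `n_splits` times into training and testing sets, each
#' training set containing `train_frac` of the instances *of each class*
#' (per-class ceiling rounding — with the study's printed class counts
#' 166/228/406/248 and an 80% fraction this yields exactly 840 training and
#' 208 testing instances per split).
#'
#' @param bags List of labeled [mv_instance()] bags.
#' @param n_splits Number of random splits (default 5).
#' @param train_frac Per-class training fraction in (0, 1); default 0.8.
#' @param seed Integer seed; the plan is reproducible from it.
#' @return Object of class `split_plan`: list with `splits` (each a list of
#'   `train`/`test` instance-id character vectors), `n_splits`, `train_frac`,
#'   `seed`.
#' @export
make_splits <- function(bags, n_splits = 5L, train_frac = 0.8, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  labels <- bag_labels(bags)
  if (anyNA(labels)) stop("every instance must be labeled", call. = FALSE)
  ids <- vapply(bags, function(b) as.character(b$instance_id), character(1L))
  if (anyDuplicated(ids)) stop("instance_ids must be unique", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("cannot stratify: class(es) with fewer than 2 instances: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng())
  classes <- sort(unique(labels))
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    train <- character(0)
    for (cl in classes) {
      cl_ids <- ids[labels == cl]
      n_train <- ceiling(train_frac * length(cl_ids))
      train <- c(train, sample(cl_ids, n_train))
    }
    splits[[s]] <- list(train = train, test = setdiff(ids, train))
  }
  if (!length(splits[[1L]]$test)) {
    warning("per-class ceiling rounding at train_frac = ", train_frac,
            " leaves no test instances", call. = FALSE)
  }
  structure(list(splits = splits, n_splits = as.integer(n_splits),
                 train_frac = train_frac, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  n_tr <- length(x$splits[[1L]]$train)
  n_te <- length(x$splits[[1L]]$test)
  cat(sprintf("split_plan: %d splits, train_frac %.2f (%d train / %d test)\n",
              x$n_splits, x$train_frac, n_tr, n_te))
  invisible(x)
}
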