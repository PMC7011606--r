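#' Evaluate a classification approach over a split plan
#'
#' For every split of the plan, trains the requested approach on the training
#' bags and predicts the held-out test bags, reporting the percentage of
#' correctly classified action instances per split, the mean over splits, and
#' the row-normalized confusion matrix (rows = ground truth, entries in
#' percent, each row summing to 100) per split and averaged.
#'
#' @param approach `"svm-mv"` or `"mi-svm"`.
#' @param bags List of labeled [mv_instance()] bags.
#' @param split_plan A [make_splits()] plan over those bags.
#' @param C SVM regularization constant (default 1).
#' @param seed Seed recorded with the models.
#' @param max_alternations MI-SVM alternation cap (default 20).
#' @return Object of class `eval_result`: `per_split_accuracy` (percent),
#'   `mean_accuracy`, `confusion` (list of per-split matrices),
#'   `mean_confusion`, `approach`.
#' @export
evaluate <- function(approach = c("svm-mv", "mi-svm"), bags, split_plan,
                     C = 1, seed = 1, max_alternations = 20L) {
  approach <- match.arg(approach)
  stopifnot(inherits(split_plan, "split_plan"))
  ids <- vapply(bags, function(b) as.character(b$instance_id), character(1L))
  names(bags) <- ids
  acc <- numeric(split_plan$n_splits)
  confs <- vector("list", split_plan$n_splits)
  for (s in seq_len(split_plan$n_splits)) {
    sp <- split_plan$splits[[s]]
    if (!all(c(sp$train, sp$test) %in% ids)) {
      stop("split plan refers to instance_ids not present in `bags`",
           call. = FALSE)
    }
    train_bags <- bags[sp$train]
    test_bags <- bags[sp$test]
    model <- if (approach == "svm-mv") {
      train_svm_mv(train_bags, C = C, seed = seed)
    } else {
      train_mi_svm(train_bags, C = C, seed = seed,
                   max_alternations = max_alternations)
    }
    pred <- predict(model, test_bags)
    truth <- bag_labels(test_bags)
    acc[s] <- 100 * mean(pred == truth)
    confs[[s]] <- confusion_matrix(truth, pred)
  }
  structure(list(approach = approach, per_split_accuracy = acc,
                 mean_accuracy = mean(acc), confusion = confs,
                 mean_confusion = Reduce(`+`, confs) / length(confs)),
            class = "eval_result")
}

# Row-normalized confusion matrix in percent; rows = ground truth.
confusion_matrix <- function(truth, pred) {
  cls <- action_classes()
  m <- table(factor(truth, levels = cls), factor(pred, levels = cls))
  m <- unclass(m)
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  100 * m / rs
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result (%s): mean accuracy %.2f%% over %d splits\n",
              x$approach, x$mean_accuracy, length(x$per_split_accuracy)))
  cat("  per split:", paste(sprintf("%.2f", x$per_split_accuracy),
                            collapse = " "), "\n")
  invisible(x)
}
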