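#' Action classes
#'
#' The four gross-motor action classes of interest, in canonical order. The
#' fixed order also serves as the documented deterministic tie-break for
#' classifier score ties.
#'
#' @return Character vector `c("crawling", "sitting", "standing", "walking")`.
#' @export
action_classes <- function() c("crawling", "sitting", "standing", "walking")

#' Multi-view action instance (a MIL bag)
#'
#' One action instance is observed simultaneously by up to five cameras; its
#' bag collects one embedding per available view and carries a single action
#' label. Views missing from a bag (camera dropout, discarded feed) are simply
#' absent rather than imputed.
#'
#' @param instance_id Identifier, unique within a collection.
#' @param embeddings Numeric matrix, one row per view.
#' @param view_ids Integer camera indices (0-based) matching the rows.
#' @param label Action label from [action_classes()], or `NA` at prediction
#'   time.
#' @param informative_views Optional logical vector marking which views carry
#'   the action signal (known only for synthetic bags; used to audit MI-SVM
#'   witness recovery).
#' @return Object of class `mv_instance`.
#' @export
mv_instance <- function(instance_id, embeddings, view_ids = NULL,
                        label = NA_character_, informative_views = NULL) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 1L) stop("a bag needs at least one view",
                                  call. = FALSE)
  if (is.null(view_ids)) view_ids <- seq_len(nrow(embeddings)) - 1L
  stopifnot(length(view_ids) == nrow(embeddings))
  if (!is.na(label) && !label %in% action_classes()) {
    stop("unknown action label: ", label, call. = FALSE)
  }
  structure(list(instance_id = instance_id, embeddings = embeddings,
                 view_ids = as.integer(view_ids), label = label,
                 informative_views = informative_views),
            class = "mv_instance")
}

bag_labels <- function(bags) {
  vapply(bags, function(b) b$label, character(1L))
}

bag_dim <- function(bags) {
  dims <- unique(vapply(bags, function(b) ncol(b$embeddings), integer(1L)))
  if (length(dims) != 1L) stop("all bags must share one embedding dimension")
  dims
}

# Stack all views of all bags into one matrix with bag/view bookkeeping.
unroll_bags <- function(bags) {
  x <- do.call(rbind, lapply(bags, function(b) b$embeddings))
  bag_of_row <- rep(seq_along(bags),
                    vapply(bags, function(b) nrow(b$embeddings), integer(1L)))
  list(x = x, bag = bag_of_row, label = bag_labels(bags)[bag_of_row])
}

#' Generate labeled synthetic feature-space bags
#'
#' Draws multi-view bags directly in feature space, bypassing rendering, for
#' fast classifier experiments. Informative views of a class-`c` bag are drawn
#' from an isotropic Gaussian at that class's mean (class means are mutually
#' orthogonal directions scaled by `class_separation`); with probability
#' `occlusion_rate` a view is instead drawn from the shared zero-mean
#' background distribution and marked uninformative in the bag metadata —
#' emulating a camera view in which the child is occluded and the feed shows
#' only scene clutter.
#'
#' @param n_per_class Integer vector of bag counts per class (recycled to 4).
#' @param dim Feature dimension (default 16).
#' @param occlusion_rate Per-view probability of an uninformative view
#'   (default 0.4).
#' @param class_separation Distance scale between class means and background
#'   (default 2.5).
#' @param n_views Views per bag (default 5).
#' @param seed Integer seed.
#' @return List of labeled [mv_instance()] bags with `informative_views`
#'   metadata.
#' @export
make_feature_bags <- function(n_per_class, dim = 16L, occlusion_rate = 0.4,
                              class_separation = 2.5, n_views = 5L, seed = 1) {
  stopifnot(all(n_per_class >= 1L), class_separation > 0,
            occlusion_rate >= 0, occlusion_rate < 1, dim >= 4L)
  n_per_class <- rep_len(as.integer(n_per_class), 4L)
  rng <- local_rng(seed)
  on.exit(rng())
  # orthonormal class directions in feature space; rows = class means
  basis <- qr.Q(qr(matrix(stats::rnorm(dim * 4L), dim, 4L)))
  means <- t(basis) * class_separation
  bags <- vector("list", sum(n_per_class))
  idx <- 0L
  for (ci in 1:4) {
    for (b in seq_len(n_per_class[ci])) {
      idx <- idx + 1L
      occluded <- stats::runif(n_views) < occlusion_rate
      emb <- matrix(stats::rnorm(n_views * dim), n_views, dim)
      for (v in seq_len(n_views)) {
        if (!occluded[v]) emb[v, ] <- emb[v, ] + means[ci, ]
      }
      bags[[idx]] <- mv_instance(
        instance_id = sprintf("syn_%s_%04d", action_classes()[ci], b),
        embeddings = emb, view_ids = seq_len(n_views) - 1L,
        label = action_classes()[ci],
        informative_views = !occluded)
    }
  }
  bags
}
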