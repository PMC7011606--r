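#' Linear one-vs-rest SVM machinery
#'
#' Both classification approaches share the same base learner: a linear
#' C-SVM (libsvm via e1071, `scale = FALSE`, default `C = 1`) trained
#' one-vs-rest, one binary machine per action class. The fitted machine is
#' reduced to an explicit weight vector and bias so that per-view decision
#' scores are cheap and auditable.
#'
#' @name linear-ovr-svm
#' @keywords internal
NULL

# Fit one binary linear SVM; returns explicit (w, b) with the convention
# that positive score means the positive class. libsvm's internal sign
# depends on label ordering, so the sign is calibrated on the training data.
fit_binary_linear_svm <- function(x, y_pos, C = 1) {
  stopifnot(is.matrix(x), is.logical(y_pos), nrow(x) == length(y_pos))
  if (!any(y_pos) || all(y_pos)) {
    stop("binary SVM needs both positive and negative examples",
         call. = FALSE)
  }
  y <- factor(ifelse(y_pos, "pos", "neg"), levels = c("pos", "neg"))
  m <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  sc <- drop(x %*% w) + b
  if (mean(sc[y_pos]) < mean(sc[!y_pos])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

# Score matrix: rows of x against every class machine -> n x n_classes.
ovr_scores <- function(model, x) {
  x <- as.matrix(x)
  s <- x %*% model$W
  sweep(s, 2L, model$b, `+`)
}

# Regularized hinge objective 0.5||w||^2 + C sum hinge on a labeled set;
# used to audit MI-SVM alternation monotonicity.
hinge_objective <- function(w, b, x, y_pos, C) {
  sc <- drop(x %*% w) + b
  margins <- ifelse(y_pos, sc, -sc)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - margins))
}

new_cri_svm <- function(approach, W, b, C, seed, extra = list()) {
  structure(c(list(approach = approach, classes = action_classes(),
                   W = W, b = b, C = C, seed = seed), extra),
            class = "cri_svm")
}

#' @export
print.cri_svm <- function(x, ...) {
  cat(sprintf("cri_svm: %s, %d classes, dim %d, C = %g\n", x$approach,
              length(x$classes), nrow(x$W), x$C))
  if (!is.null(x$converged)) {
    cat("  MI-SVM converged:", paste(x$converged, collapse = " "), "\n")
  }
  invisible(x)
}

#' Train the majority-vote approach (SVM-MV)
#'
#' Label transfer: every view of a training bag inherits the bag's action
#' label, and one one-vs-rest linear SVM is fitted on the unrolled per-view
#' embeddings. Label transfer can inject noise — an occluded view is trained
#' with a label its pixels never showed — which is exactly the weakness the
#' multiple-instance approach targets.
#'
#' @param train_bags List of labeled [mv_instance()] bags.
#' @param C SVM regularization constant (default 1).
#' @param seed Seed recorded in the model metadata (the libsvm solve is
#'   itself deterministic).
#' @return A `cri_svm` model with `approach = "svm-mv"`.
#' @export
train_svm_mv <- function(train_bags, C = 1, seed = 1) {
  u <- unroll_bags(train_bags)
  present <- action_classes() %in% u$label
  if (!all(present)) {
    stop("class(es) absent from training set: ",
         paste(action_classes()[!present], collapse = ", "), call. = FALSE)
  }
  d <- ncol(u$x)
  W <- matrix(0, d, 4L, dimnames = list(NULL, action_classes()))
  b <- stats::setNames(numeric(4L), action_classes())
  for (cl in action_classes()) {
    fit <- fit_binary_linear_svm(u$x, u$label == cl, C = C)
    W[, cl] <- fit$w
    b[cl] <- fit$b
  }
  new_cri_svm("svm-mv", W, b, C, seed,
              extra = list(n_train_views = nrow(u$x)))
}

#' Predict a bag label by per-view voting
#'
#' Each view is classified independently by the one-vs-rest machine; the bag
#' receives the label predicted in the majority of its views. Vote ties
#' (possible with 5 votes over 4 classes) are broken by the larger sum of
#' per-view decision scores among the tied classes, then by the fixed class
#' order of [action_classes()].
#'
#' @param model A `cri_svm` trained with [train_svm_mv()].
#' @param bag An [mv_instance()].
#' @return Predicted action label.
#' @export
predict_mv <- function(model, bag) {
  stopifnot(inherits(model, "cri_svm"), inherits(bag, "mv_instance"))
  if (model$approach != "svm-mv") {
    stop("model was not trained with the SVM-MV approach", call. = FALSE)
  }
  if (nrow(bag$embeddings) == 0L) stop("empty bag", call. = FALSE)
  s <- ovr_scores(model, bag$embeddings)
  view_pred <- apply(s, 1L, which.max)
  votes <- tabulate(view_pred, nbins = 4L)
  tied <- which(votes == max(votes))
  if (length(tied) == 1L) return(model$classes[tied])
  sums <- colSums(s)[tied]
  model$classes[tied[which.max(sums)]]
}

#' Train the multiple-instance approach (MI-SVM)
#'
#' One-vs-rest MI-SVM by witness alternation. For each class, positive bags
#' start with all their views as positive instances (the label-transfer
#' initialization); each round then (i) selects per positive bag the single
#' *witness* view with the highest current decision score and (ii) refits the
#' linear SVM on the witnesses against all views of the negative bags.
#' Alternation stops when the witness assignment is unchanged or after
#' `max_alternations` rounds (in which case the current model is returned
#' with its convergence flag `FALSE`). The regularized hinge objective over
#' (witnesses, negatives) is recorded each round; it is non-increasing from
#' the first witness selection on.
#'
#' @inheritParams train_svm_mv
#' @param max_alternations Cap on witness-refit rounds (default 20).
#' @return A `cri_svm` with `approach = "mi-svm"`, per-class `converged`
#'   flags, witness indices (`witnesses`, view row chosen per positive bag)
#'   and per-class `objective` traces.
#' @export
train_mi_svm <- function(train_bags, C = 1, seed = 1, max_alternations = 20L) {
  labels <- bag_labels(train_bags)
  present <- action_classes() %in% labels
  if (!all(present)) {
    stop("class(es) absent from training set: ",
         paste(action_classes()[!present], collapse = ", "), call. = FALSE)
  }
  d <- bag_dim(train_bags)
  W <- matrix(0, d, 4L, dimnames = list(NULL, action_classes()))
  b <- stats::setNames(numeric(4L), action_classes())
  converged <- stats::setNames(logical(4L), action_classes())
  witnesses <- stats::setNames(vector("list", 4L), action_classes())
  objective <- stats::setNames(vector("list", 4L), action_classes())
  init_positive_rows <- stats::setNames(integer(4L), action_classes())
  for (cl in action_classes()) {
    pos_bags <- train_bags[labels == cl]
    neg_x <- do.call(rbind, lapply(train_bags[labels != cl],
                                   function(bb) bb$embeddings))
    pos_views <- lapply(pos_bags, function(bb) bb$embeddings)
    # round 0: label transfer — every view of every positive bag is positive
    n_pos0 <- sum(vapply(pos_views, nrow, integer(1L)))
    x0 <- rbind(do.call(rbind, pos_views), neg_x)
    y0 <- c(rep(TRUE, n_pos0), rep(FALSE, nrow(neg_x)))
    fit <- fit_binary_linear_svm(x0, y0, C = C)
    wit <- rep(-1L, length(pos_bags))
    obj <- numeric(0)
    ok <- FALSE
    for (round in seq_len(max_alternations)) {
      new_wit <- vapply(pos_views, function(v) {
        which.max(drop(v %*% fit$w) + fit$b)
      }, integer(1L))
      if (identical(new_wit, wit)) {
        ok <- TRUE
        break
      }
      wit <- new_wit
      wx <- do.call(rbind, Map(function(v, k) v[k, , drop = FALSE],
                               pos_views, wit))
      x1 <- rbind(wx, neg_x)
      y1 <- c(rep(TRUE, nrow(wx)), rep(FALSE, nrow(neg_x)))
      fit <- fit_binary_linear_svm(x1, y1, C = C)
      obj <- c(obj, hinge_objective(fit$w, fit$b, x1, y1, C))
    }
    if (!ok) {
      warning("MI-SVM witness alternation for class '", cl,
              "' did not converge in ", max_alternations, " rounds",
              call. = FALSE)
    }
    W[, cl] <- fit$w
    b[cl] <- fit$b
    converged[cl] <- ok
    witnesses[[cl]] <- wit
    objective[[cl]] <- obj
    init_positive_rows[cl] <- n_pos0
  }
  new_cri_svm("mi-svm", W, b, C, seed,
              extra = list(converged = converged, witnesses = witnesses,
                           objective = objective,
                           init_positive_rows = init_positive_rows,
                           max_alternations = as.integer(max_alternations)))
}

#' Predict a bag label by max-over-views scoring
#'
#' The bag score of a class is the maximum decision score that class's
#' machine assigns to any view in the bag; the predicted label is the argmax
#' over classes. No voting is involved: a single clear view suffices. Exact
#' score ties between classes are broken by the fixed order of
#' [action_classes()].
#'
#' @param model A `cri_svm` trained with [train_mi_svm()].
#' @param bag An [mv_instance()].
#' @return Predicted action label.
#' @export
predict_mi <- function(model, bag) {
  stopifnot(inherits(model, "cri_svm"), inherits(bag, "mv_instance"))
  if (model$approach != "mi-svm") {
    stop("model was not trained with the MI-SVM approach", call. = FALSE)
  }
  if (nrow(bag$embeddings) == 0L) stop("empty bag", call. = FALSE)
  s <- ovr_scores(model, bag$embeddings)
  bag_scores <- apply(s, 2L, max)
  model$classes[which.max(bag_scores)]
}

#' Predict labels for a list of bags
#'
#' @param object A `cri_svm` model (either approach).
#' @param bags List of [mv_instance()] bags.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.cri_svm <- function(object, bags, ...) {
  fun <- if (object$approach == "svm-mv") predict_mv else predict_mi
  vapply(bags, function(b) fun(object, b), character(1L))
}
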