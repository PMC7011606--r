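#' Fit a Fisher-vector codebook
#'
#' The codebook is a diagonal-covariance Gaussian mixture ("dictionary of
#' codewords") fitted to a training sample of trajectory descriptors after a
#' PCA projection (default: halving the descriptor dimension). Descriptors
#' must be drawn from training videos only, so that encoding held-out videos
#' is leakage-free.
#'
#' @param descriptor_sample Numeric matrix, one descriptor per row.
#' @param K Number of mixture components (default 64). If the sample has
#'   fewer distinct rows than `K`, `K` is reduced with a warning.
#' @param projected_dim PCA output dimension; default `floor(D / 2)`, capped
#'   by the sample size.
#' @param seed Integer seed (controls the EM initialization subset).
#' @param max_init_subset Size cap of the hierarchical-initialization subset
#'   used by the mixture fit (default 2000).
#' @return Object of class `fisher_codebook`: mixture `weights` (sum to 1),
#'   `means` and `variances` (`projected_dim x K`), the PCA `center` and
#'   `rotation`, `K`, and `seed`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_codebook <- function(descriptor_sample, K = 64L, projected_dim = NULL,
                         seed = 1, max_init_subset = 2000L) {
  x <- as.matrix(descriptor_sample)
  if (nrow(x) == 0L) stop("descriptor sample is empty", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (n_distinct < K) {
    warning(sprintf("only %d distinct descriptors; reducing K from %d",
                    n_distinct, K), call. = FALSE)
    K <- max(1L, n_distinct)
  }
  d_in <- ncol(x)
  if (is.null(projected_dim)) projected_dim <- max(2L, floor(d_in / 2))
  projected_dim <- min(projected_dim, d_in, nrow(x) - 1L)
  rng <- local_rng(seed)
  on.exit(rng())
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                       rank. = projected_dim)
  z <- pca$x
  dp <- ncol(z)
  if (K == 1L) {
    w <- 1
    mu <- matrix(colMeans(z), dp, 1L)
    va <- matrix(pmax(apply(z, 2L, stats::var), 1e-6), dp, 1L)
  } else {
    subset <- sample(nrow(z), min(nrow(z), max_init_subset))
    fit <- Mclust(z, G = K, modelNames = "VVI",
                  initialization = list(subset = subset),
                  verbose = FALSE)
    if (!is.null(fit)) {
      w <- as.numeric(fit$parameters$pro)
      mu <- matrix(fit$parameters$mean, dp, K)
      sig <- fit$parameters$variance$sigma    # dp x dp x K
      va <- matrix(vapply(seq_len(K),
                          function(k) pmax(diag(sig[, , k]), 1e-6),
                          numeric(dp)), dp, K)
      w <- w / sum(w)
    } else {
      # EM can fail on tiny or degenerate samples (duplicate rows, near-zero
      # variance); fall back to a hard-assignment mixture from k-means
      km <- stats::kmeans(z, centers = K, nstart = 5)
      w <- as.numeric(km$size) / nrow(z)
      mu <- t(km$centers)
      va <- matrix(1e-6, dp, K)
      for (k in seq_len(K)) {
        zk <- z[km$cluster == k, , drop = FALSE]
        if (nrow(zk) > 1L) {
          va[, k] <- pmax(apply(zk, 2L, stats::var), 1e-6)
        }
      }
    }
  }
  structure(list(K = as.integer(K), weights = w, means = mu, variances = va,
                 center = pca$center, rotation = pca$rotation,
                 projected_dim = dp, seed = seed),
            class = "fisher_codebook")
}

#' @export
print.fisher_codebook <- function(x, ...) {
  cat(sprintf("fisher_codebook: K = %d over %d-dim projected descriptors\n",
              x$K, x$projected_dim))
  invisible(x)
}

#' Fisher-vector encoding of a descriptor set
#'
#' Embeds the descriptors of one video as the concatenated first- and
#' second-order deviations from the codebook mixture (soft-assigned by
#' posterior responsibility, averaged over descriptors), followed by signed
#' square-root and L2 normalization. The output length is
#' `2 * K * projected_dim`. Averaging over descriptors makes the embedding
#' invariant to duplicating the descriptor set.
#'
#' An empty descriptor set (e.g. a fully static or fully occluded view)
#' encodes to a zero vector flagged with attribute `empty = TRUE`;
#' downstream multi-view classification tolerates such uninformative views.
#'
#' @param descriptors Numeric matrix of raw descriptors (may have 0 rows).
#' @param codebook A [fit_codebook()] result.
#' @param view_id,instance_id Optional identifiers carried on the result.
#' @return Numeric vector of length `2 * K * projected_dim` with attributes
#'   `view_id`, `instance_id`, `empty`; unit L2 norm unless empty.
#' @export
encode_fisher <- function(descriptors, codebook, view_id = NA_integer_,
                          instance_id = NA_character_) {
  stopifnot(inherits(codebook, "fisher_codebook"))
  K <- codebook$K
  dp <- codebook$projected_dim
  len <- 2L * K * dp
  if (is.null(descriptors) || nrow(as.matrix(descriptors)) == 0L) {
    return(structure(numeric(len), view_id = view_id,
                     instance_id = instance_id, empty = TRUE))
  }
  x <- as.matrix(descriptors)
  z <- sweep(x, 2L, codebook$center) %*% codebook$rotation
  n <- nrow(z)
  mu <- codebook$means
  va <- codebook$variances
  w <- codebook$weights
  # posterior responsibilities via log-sum-exp
  logp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    zc <- sweep(z, 2L, mu[, k])
    logp[, k] <- log(w[k]) - 0.5 * sum(log(2 * pi * va[, k])) -
      0.5 * rowSums(sweep(zc^2, 2L, va[, k], `/`))
  }
  m <- apply(logp, 1L, max)
  gamma <- exp(logp - m)
  gamma <- gamma / rowSums(gamma)
  phi1 <- matrix(0, dp, K)
  phi2 <- matrix(0, dp, K)
  for (k in seq_len(K)) {
    zc <- sweep(z, 2L, mu[, k])
    zn <- sweep(zc, 2L, sqrt(va[, k]), `/`)
    g <- gamma[, k]
    phi1[, k] <- colSums(zn * g) / (n * sqrt(w[k]))
    phi2[, k] <- colSums((zn^2 - 1) * g) / (n * sqrt(2 * w[k]))
  }
  v <- c(as.vector(phi1), as.vector(phi2))
  v <- sign(v) * sqrt(abs(v))
  nv <- sqrt(sum(v^2))
  empty <- nv == 0
  if (!empty) v <- v / nv
  structure(v, view_id = view_id, instance_id = instance_id, empty = empty)
}

#' Full clip-to-embedding pipeline
#'
#' Convenience wrapper: [extract_trajectories()], [compute_descriptors()],
#' [encode_fisher()]. A clip with no surviving trajectories yields the
#' flagged zero embedding.
#'
#' @param clip A [video_clip()].
#' @param codebook A [fit_codebook()] result.
#' @param instance_id Optional identifier.
#' @param ... Passed to [extract_trajectories()].
#' @return See [encode_fisher()].
#' @export
encode_clip <- function(clip, codebook, instance_id = NA_character_, ...) {
  trs <- extract_trajectories(clip, ...)
  desc <- compute_descriptors(trs, clip)
  encode_fisher(desc, codebook, view_id = clip$view_id,
                instance_id = instance_id)
}
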