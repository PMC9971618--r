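#' Sample kernel from a reconstructed relation
#'
#' Inner-product ("kernel trick") kernel K = M M' where `M` has samples on
#' rows; pass the transpose of a (feature, sample) reconstruction.
#'
#' @param R_hat Numeric matrix with samples on rows.
#' @return Symmetric PSD kernel matrix (samples by samples).
#' @export
kernel_from_reconstruction <- function(R_hat) {
  R_hat <- as.matrix(R_hat)
  if (any(!is.finite(R_hat))) stop("reconstruction contains non-finite entries")
  K <- tcrossprod(R_hat)
  (K + t(K)) / 2
}

# uniform box filter with edge replication, applied to a square matrix
.box_smooth <- function(M, window) {
  if (window <= 1) return(M)
  if (window %% 2 == 0) stop("smoothing window must be odd")
  h <- (window - 1) / 2
  n <- nrow(M)
  idx <- pmin(pmax(seq(1 - h, n + h), 1), n)   # replicated edge index
  P <- M[idx, idx]
  # separable moving average via cumulative sums
  run <- function(A) {
    cs <- rbind(0, apply(A, 2, cumsum))
    (cs[(window + 1):(n + window), , drop = FALSE] -
       cs[1:n, , drop = FALSE]) / window
  }
  t(run(t(run(P))))
}

#' Cosine-normalize, smooth and PSD-project a kernel
#'
#' Normalizes to unit self-similarity, K'(a, b) = K(a, b) /
#' sqrt(K(a, a) K(b, b)), applies a 2-D uniform moving-average filter of the
#' given odd window with edge replication (window 1 disables smoothing),
#' symmetrizes, and clips negative eigenvalues to restore positive
#' semidefiniteness (smoothing does not preserve it).
#'
#' @param K Symmetric kernel with strictly positive diagonal.
#' @param window Odd box-filter width; default 3.
#' @param smooth_first Apply the filter before normalizing instead of after.
#' @return Symmetric PSD kernel of the same dimension.
#' @export
normalize_and_smooth <- function(K, window = 3, smooth_first = FALSE) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("kernel must be symmetric")
  normalize <- function(M) {
    dg <- diag(M)
    if (any(dg <= 0)) {
      bad <- which(dg <= 0)[1]
      nm <- if (!is.null(rownames(M))) rownames(M)[bad] else bad
      stop("non-positive kernel diagonal for sample '", nm, "'")
    }
    M / sqrt(outer(dg, dg))
  }
  M <- if (smooth_first) normalize(.box_smooth(K, window))
       else .box_smooth(normalize(K), window)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  if (min(eig$values) < 0)
    M <- eig$vectors %*% (pmax(eig$values, 0) * t(eig$vectors))
  M <- (M + t(M)) / 2
  dimnames(M) <- dimnames(K)
  M
}

#' Bundle kernels with shared samples and binary labels
#'
#' @param kernels Named list of symmetric PSD kernels over the same ordered
#'   samples.
#' @param y Vector of labels in `{-1, +1}` (or a 2-level factor, first level
#'   mapped to +1), one per sample.
#' @return A `kernel_set`.
#' @export
kernel_set <- function(kernels, y) {
  if (!length(kernels)) stop("at least one kernel is required")
  n <- nrow(kernels[[1]])
  for (K in kernels) {
    if (nrow(K) != n || ncol(K) != n) stop("kernels must share dimensions")
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
      stop("kernels must be symmetric")
  }
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2) stop("labels must have exactly two levels")
    y <- ifelse(y == levels(droplevels(y))[1], 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (length(y) != n) stop("one label per sample is required")
  if (is.null(names(kernels))) names(kernels) <- paste0("K", seq_along(kernels))
  structure(list(kernels = kernels, names = names(kernels), y = as.numeric(y)),
            class = "kernel_set")
}
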