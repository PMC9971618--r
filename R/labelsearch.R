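#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' Equals the fraction of concordant (positive, negative) score pairs, ties
#' counted one half.
#'
#' @param scores Numeric decision scores, higher favouring the positive
#'   class.
#' @param positive Logical vector marking positive samples.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, positive) {
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stop("both classes are needed for AUC")
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# confusion-matrix metrics at a fixed score threshold
.threshold_metrics <- function(scores, positive, threshold = 0) {
  pred <- scores > threshold
  tp <- sum(pred & positive); fn <- sum(!pred & positive)
  tn <- sum(!pred & !positive); fp <- sum(pred & !positive)
  c(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / length(scores))
}

#' Enumerate binary class-label combinations
#'
#' All one-vs-one pairs plus all one-vs-rest splits, deduplicated under
#' left/right swap; for three classes this gives the canonical six
#' combinations.
#'
#' @param classes Character vector of class labels (at least two).
#' @return List of `label_combination` shells with elements `left`, `right`,
#'   `name`.
#' @export
enumerate_combinations <- function(classes) {
  classes <- unique(as.character(classes))
  m <- length(classes)
  if (m < 2) stop("at least two classes are required")
  combos <- list()
  add <- function(left, right) {
    combos[[length(combos) + 1]] <<- structure(
      list(left = left, right = right,
           name = paste(paste(left, collapse = "+"), "vs",
                        paste(right, collapse = "+"))),
      class = "label_combination")
  }
  for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) add(classes[i], classes[j])
  if (m > 2) for (i in seq_len(m)) add(classes[i], classes[-i])
  combos
}

#' @export
print.label_combination <- function(x, ...) {
  cat("<label_combination>", x$name)
  if (!is.null(x$metrics))
    cat(" | AUC =", format(x$metrics[["auc"]], digits = 4))
  cat("\n")
  invisible(x)
}

# stratified fold assignment, seeded
.stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Score one class-label combination by cross-validated AUC
#'
#' Samples are restricted to the two sides (left = positive class), then the
#' classifier is evaluated under seeded stratified k-fold cross-validation;
#' out-of-fold decision scores are pooled and give the AUC plus
#' threshold-zero confusion metrics.
#'
#' @param combo A shell from [enumerate_combinations()].
#' @param kernels Named list of sample-by-sample kernels over all samples
#'   (the pipeline's fused kernels), or `NULL` when `expr` is used.
#' @param annot Sample annotation factor.
#' @param folds Number of folds; reduced with a warning when a side is
#'   smaller.
#' @param seed Fold-assignment seed.
#' @param classifier `"mkl"` (default, on the kernels) or `"pam"`
#'   (nearest shrunken centroids on `expr`).
#' @param expr Gene-by-sample matrix, required for the `"pam"` backend.
#' @param pi,C MKL hyper-parameters.
#' @return The combination with `metrics` (sensitivity, specificity,
#'   precision, npv, accuracy, auc) and pooled `scores` filled in.
#' @export
score_combination <- function(combo, kernels, annot, folds = 10, seed = 1,
                              classifier = c("mkl", "pam"), expr = NULL,
                              pi = 1, C = 1) {
  classifier <- match.arg(classifier)
  lab <- as.character(annot)
  keep <- names(annot)[lab %in% c(combo$left, combo$right)]
  if (!length(keep)) stop("no samples on either side of the combination")
  ybin <- ifelse(as.character(annot[keep]) %in% combo$left, 1, -1)
  names(ybin) <- keep
  if (!any(ybin > 0) || !any(ybin < 0))
    stop("a side of '", combo$name, "' has no samples")
  nmin <- min(sum(ybin > 0), sum(ybin < 0))
  if (nmin < folds) {
    warning("reducing folds from ", folds, " to ", nmin,
            " for '", combo$name, "'")
    folds <- max(2, nmin)
  }
  fold <- .stratified_folds(ybin, folds, seed)
  scores <- numeric(length(ybin)); names(scores) <- keep
  if (classifier == "mkl") {
    kl <- if (inherits(kernels, "kernel_set")) kernels$kernels else kernels
    kl <- lapply(kl, function(K) K[keep, keep, drop = FALSE])
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      ktr <- lapply(kl, function(K) K[tr, tr, drop = FALSE])
      model <- fit_soft_margin_mkl(kernel_set(ktr, ybin[tr]), pi = pi, C = C,
                                   max_outer = 20, seed = seed + f)
      kte <- lapply(kl, function(K) K[tr, te, drop = FALSE])
      scores[te] <- decision_scores(model, kte)
    }
  } else {
    if (is.null(expr)) stop("the pam classifier needs an expression matrix")
    x <- expr[, keep, drop = FALSE]
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- pam_train(x[, tr, drop = FALSE], factor(ybin[tr]))
      pr <- pam_predict(fit, x[, te, drop = FALSE])
      scores[te] <- pr$posterior[, "1"] - 0.5
    }
  }
  pos <- ybin > 0
  metrics <- c(.threshold_metrics(scores, pos), auc = auc_score(scores, pos))
  out <- combo
  out$metrics <- metrics
  out$scores <- scores
  out$labels <- ybin
  out$folds <- folds
  out
}

#' Pick the combination with the highest AUC
#'
#' Ties are broken by higher accuracy, then lexicographic name.
#'
#' @param scored List of scored `label_combination` objects.
#' @return The winning combination.
#' @export
best_combination <- function(scored) {
  if (!length(scored)) stop("no scored combinations")
  auc <- vapply(scored, function(s) s$metrics[["auc"]], numeric(1))
  acc <- vapply(scored, function(s) s$metrics[["accuracy"]], numeric(1))
  nm <- vapply(scored, `[[`, character(1), "name")
  scored[[order(-auc, -acc, nm)[1]]]
}

#' Tabulate scored combinations
#'
#' @param scored List of scored combinations.
#' @return Data frame with one row per combination and the six metrics.
#' @export
combination_table <- function(scored) {
  do.call(rbind, lapply(scored, function(s)
    data.frame(combination = s$name, t(s$metrics), check.names = FALSE)))
}
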