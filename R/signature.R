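#' Mean pairwise Pearson correlation within a module
#'
#' @param expr Gene-by-sample matrix covering the module's genes.
#' @param module A module (`list(module_id, genes)`) or a character vector of
#'   genes.
#' @return Mean over all unordered within-module gene pairs of the Pearson
#'   correlation.
#' @export
module_mean_pcc <- function(expr, module) {
  genes <- if (is.list(module)) module$genes else module
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2) stop("a module needs at least two genes")
  cc <- stats::cor(t(expr[genes, , drop = FALSE]))
  mean(cc[upper.tri(cc)])
}

#' Elect the gene signature
#'
#' The module with the maximal mean pairwise Pearson correlation wins; ties
#' go to the larger module, then the lexicographically smaller id. The
#' unassigned (grey) pool never competes.
#'
#' @param expr Gene-by-sample matrix (selected samples).
#' @param modules A `gene_modules` object.
#' @return The elected module with `mean_pcc` added.
#' @export
elect_signature <- function(expr, modules) {
  elig <- Filter(function(m) length(intersect(m$genes, rownames(expr))) >= 2,
                 modules)
  if (!length(elig)) stop("no eligible module with at least two genes")
  pcc <- vapply(elig, function(m) module_mean_pcc(expr, m), numeric(1))
  size <- vapply(elig, function(m) length(m$genes), numeric(1))
  id <- vapply(elig, `[[`, character(1), "module_id")
  win <- elig[[order(-pcc, -size, id)[1]]]
  win$mean_pcc <- max(pcc)
  win
}

#' Train a nearest-shrunken-centroids (PAM) classifier
#'
#' Class centroids are shrunk toward the overall centroid by soft
#' thresholding the standardized centroid differences
#' `d_kg = (xbar_kg - xbar_g) / (m_k (s_g + s0))` at `Delta`; shrinkage
#' performs embedded gene selection. When `delta` is `NULL` it is chosen by
#' inner cross-validation over an even grid from 0 to `max |d_kg|`
#' (minimum error, ties to the strongest shrinkage).
#'
#' @param x Gene-by-sample training matrix.
#' @param y Factor of class labels (one per column of `x`).
#' @param delta Shrinkage threshold, or `NULL` to tune.
#' @param n_delta Grid size for tuning.
#' @param inner_folds Folds of the tuning cross-validation.
#' @param seed Seed for the tuning folds.
#' @return A `pam_fit` with shrunken centroids and scale information.
#' @export
pam_train <- function(x, y, delta = NULL, n_delta = 30, inner_folds = 5,
                      seed = 1) {
  y <- droplevels(factor(y))
  K <- nlevels(y)
  if (K < 2) stop("at least two classes are required")
  n <- ncol(x)
  nk <- table(y)
  if (any(nk < 2)) stop("each class needs at least two training samples")
  xbar <- rowMeans(x)
  cent <- vapply(levels(y), function(k) rowMeans(x[, y == k, drop = FALSE]),
                 numeric(nrow(x)))
  ss <- 0
  for (k in levels(y))
    ss <- ss + rowSums((x[, y == k, drop = FALSE] - cent[, k])^2)
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- sweep(cent - xbar, 2, mk, "/") / (s + s0)

  if (is.null(delta)) {
    dmax <- max(abs(d))
    grid <- seq(0, dmax, length.out = n_delta)
    folds <- min(inner_folds, min(nk))
    if (folds < 2) {
      delta <- 0
    } else {
      fold <- .stratified_folds(as.character(y), folds, seed)
      err <- numeric(length(grid))
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit_f <- pam_train(x[, tr, drop = FALSE], y[tr], delta = 0)
        for (gi in seq_along(grid)) {
          fit_g <- .pam_shrink(fit_f, grid[gi])
          pr <- pam_predict(fit_g, x[, !tr, drop = FALSE])$class
          err[gi] <- err[gi] + sum(pr != y[!tr])
        }
      }
      delta <- grid[max(which(err == min(err)))]
    }
  }
  fit <- structure(list(levels = levels(y), xbar = xbar, cent = cent, d = d,
                        s = s, s0 = s0, mk = mk,
                        prior = as.numeric(nk) / n, delta = delta),
                   class = "pam_fit")
  .pam_shrink(fit, delta)
}

# apply soft-threshold shrinkage Delta to a fitted centroid system
.pam_shrink <- function(fit, delta) {
  dshr <- sign(fit$d) * pmax(abs(fit$d) - delta, 0)
  cent_shr <- fit$xbar + sweep(dshr, 2, fit$mk, "*") * (fit$s + fit$s0)
  fit$delta <- delta
  fit$d_shrunk <- dshr
  fit$cent_shrunk <- cent_shr
  fit$active_genes <- rownames(fit$cent)[rowSums(abs(dshr)) > 0]
  fit
}

#' Predict with a PAM classifier
#'
#' Discriminant score `delta_k(x) = sum_g (x_g - c_kg)^2 / (s_g + s0)^2 -
#' 2 log pi_k`; the class with the smallest score wins and Gaussian
#' posteriors are `exp(-delta_k / 2)` renormalized.
#'
#' @param fit A `pam_fit`.
#' @param newx Gene-by-sample matrix with the training genes.
#' @return List with `class` (factor) and `posterior` (samples by classes).
#' @export
pam_predict <- function(fit, newx) {
  newx <- newx[names(fit$xbar), , drop = FALSE]
  sc <- vapply(seq_along(fit$levels), function(k) {
    colSums((newx - fit$cent_shrunk[, k])^2 / (fit$s + fit$s0)^2) -
      2 * log(fit$prior[k])
  }, numeric(ncol(newx)))
  sc <- matrix(sc, ncol = length(fit$levels),
               dimnames = list(colnames(newx), fit$levels))
  post <- exp(-(sc - apply(sc, 1, min)) / 2)
  post <- post / rowSums(post)
  cls <- factor(fit$levels[apply(sc, 1, which.min)], levels = fit$levels)
  list(class = cls, posterior = post, score = sc)
}

#' Evaluate a gene signature with PAM under repeated cross-validation
#'
#' For each repeat, seeded stratified folds are drawn, the
#' nearest-shrunken-centroids classifier is trained out-of-fold and its
#' pooled predictions give sensitivity, specificity, precision, accuracy at
#' the posterior-0.5 threshold and the AUC from pooled posterior scores.
#' Summaries are means and standard deviations over repeats.
#'
#' @param expr Gene-by-sample matrix restricted to the signature genes.
#' @param labels Binary factor (first level is the positive class).
#' @param folds,repeats Cross-validation layout; folds are reduced with a
#'   warning when a class is smaller.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param delta Optional fixed shrinkage (tuned per training fold when
#'   `NULL`).
#' @return A `signature_report`: list with `per_repeat` (data frame),
#'   `summary` (mean and sd per metric), `mean_auc`, `folds`, `repeats`.
#' @export
pam_cv_evaluate <- function(expr, labels, folds = 10, repeats = 10, seed = 1,
                            delta = NULL) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("binary labels are required")
  pos_level <- levels(labels)[1]
  nmin <- min(table(labels))
  if (nmin < folds) {
    warning("reducing folds from ", folds, " to ", nmin)
    folds <- max(2, nmin)
  }
  per <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(as.character(labels), folds, seed + r)
    post <- numeric(ncol(expr))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2) {
        warning("refolding: fold ", f, " left one class in training")
        fold <- .stratified_folds(as.character(labels), folds, seed + r + 1000)
        tr <- fold != f
      }
      fit <- pam_train(expr[, tr, drop = FALSE], labels[tr], delta = delta,
                       seed = seed + r)
      post[!tr] <- pam_predict(fit, expr[, !tr, drop = FALSE])$posterior[, pos_level]
    }
    posv <- labels == pos_level
    mets <- .threshold_metrics(post - 0.5, posv)
    per[[r]] <- data.frame(repeat_id = r, t(mets),
                           auc = auc_score(post, posv), check.names = FALSE)
  }
  per <- do.call(rbind, per)
  met_cols <- c("sensitivity", "specificity", "precision", "npv", "accuracy",
                "auc")
  summ <- data.frame(metric = met_cols,
                     mean = vapply(per[met_cols], mean, numeric(1)),
                     sd = vapply(per[met_cols], stats::sd, numeric(1)),
                     row.names = NULL)
  structure(list(per_repeat = per, summary = summ,
                 mean_auc = mean(per$auc), folds = folds, repeats = repeats,
                 positive_class = pos_level),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("<signature_report> ", x$repeats, " x ", x$folds,
      "-fold CV (positive class: ", x$positive_class, ")\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f (+/- %.4f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
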