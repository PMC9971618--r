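#' Drop features with missing values
#'
#' Methylation-array style filtering: any feature row containing at least one
#' missing entry is removed entirely.
#'
#' @param layer An [omics_layer()].
#' @return The layer with only complete feature rows.
#' @export
drop_missing_features <- function(layer) {
  keep <- stats::complete.cases(layer$values)
  if (!any(keep))
    stop("layer '", layer$layer_name, "': every feature has missing values")
  omics_layer(layer$values[keep, , drop = FALSE], layer$layer_name,
              feature_to_gene = layer$feature_to_gene[layer$feature_ids[keep]])
}

#' Zero-mean normalize each feature row
#'
#' Each feature is centred and scaled to unit spread, x' = (x - mu) / sigma,
#' using the population standard deviation (divide by n; no Bessel
#' correction). Constant rows have sigma = 0 and are dropped with a warning.
#'
#' @param layer An [omics_layer()] without missing values.
#' @param bessel Use the n-1 denominator instead of n.
#' @return Normalized layer; every retained row has mean 0, sd 1.
#' @export
zero_mean_normalize <- function(layer, bessel = FALSE) {
  if (anyNA(layer$values))
    stop("layer '", layer$layer_name, "': drop missing features before normalizing")
  x <- layer$values
  n <- ncol(x)
  mu <- rowMeans(x)
  cx <- x - mu
  denom <- if (bessel) n - 1L else n
  sigma <- sqrt(rowSums(cx^2) / denom)
  keep <- sigma > 0
  if (!all(keep)) {
    warning("layer '", layer$layer_name, "': dropped ", sum(!keep),
            " constant feature(s)")
    if (!any(keep)) stop("layer '", layer$layer_name, "': all features constant")
  }
  omics_layer(cx[keep, , drop = FALSE] / sigma[keep], layer$layer_name,
              feature_to_gene = layer$feature_to_gene[layer$feature_ids[keep]])
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used by the moment-matching prior fit.
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

# Moment-matching fit of the scaled inverse-chi-square prior for the feature
# variances: s2 ~ s0^2 F(d, d0). Matches mean/variance of log s2.
.fit_variance_prior <- function(s2, d, d0_cap = 1e6) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0_sq = stats::median(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  rhs <- stats::var(e) - trigamma(d / 2)
  if (rhs <= 0) {
    d0 <- d0_cap
  } else {
    d0 <- min(2 * .trigamma_inverse(rhs), d0_cap)
  }
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  if (!is.finite(s0_sq)) s0_sq <- exp(ebar)
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated statistics for one omics layer
#'
#' Per feature, group means give the contrast estimate and a pooled
#' within-group variance s2 with d = n - (number of groups) degrees of
#' freedom. A scaled inverse-chi-square prior (d0, s0^2) is fitted across
#' features by moment matching on log s2, and each feature's variance is
#' replaced by the posterior blend
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' yielding a moderated t (two classes) with d0 + d degrees of freedom or a
#' moderated F across m > 2 classes with (m - 1, d0 + d) degrees of freedom.
#'
#' @param layer An [omics_layer()] without missing values.
#' @param annot Sample annotation covering the layer's samples; at least two
#'   classes with at least two samples each.
#' @param d0 Optional fixed prior degrees of freedom (e.g. `0` for the
#'   unmoderated classical statistic); estimated when `NULL`.
#' @param d0_cap Upper bound for the estimated d0 (kept finite).
#' @return A `moderated_stats` object: a data frame with per-feature columns
#'   `feature_id`, `beta_hat`, `s2`, `s2_post`, `t_mod` (2 classes), `F_mod`,
#'   `p_value`, plus attributes `d0`, `s0_sq`, `d`, `group_sizes`.
#' @export
fit_ebayes <- function(layer, annot, d0 = NULL, d0_cap = 1e6) {
  x <- layer$values
  if (anyNA(x)) stop("layer '", layer$layer_name, "' has missing values")
  grp <- annot[layer$sample_ids]
  if (anyNA(grp)) stop("unannotated samples in layer '", layer$layer_name, "'")
  grp <- droplevels(grp)
  m <- nlevels(grp)
  if (m < 2) stop("at least two classes are required")
  sizes <- table(grp)
  if (any(sizes < 2))
    stop("class '", names(sizes)[which(sizes < 2)[1]], "' has fewer than 2 samples")
  n <- ncol(x)
  d <- n - m
  idx <- split(seq_len(n), grp)
  means <- vapply(idx, function(j) rowMeans(x[, j, drop = FALSE]),
                  numeric(nrow(x)))
  ss_within <- 0
  for (k in seq_along(idx)) {
    cx <- x[, idx[[k]], drop = FALSE] - means[, k]
    ss_within <- ss_within + rowSums(cx^2)
  }
  s2 <- ss_within / d
  if (all(s2 == 0)) stop("all features are constant within groups")
  if (is.null(d0)) {
    prior <- .fit_variance_prior(s2, d, d0_cap)
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else {
    s0_sq <- if (d0 > 0) .fit_variance_prior(s2, d, d0_cap)$s0_sq else stats::median(s2)
  }
  s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
  grand <- rowMeans(x)
  ss_between <- rowSums(vapply(seq_along(idx),
                               function(k) length(idx[[k]]) * (means[, k] - grand)^2,
                               numeric(nrow(x))))
  F_mod <- (ss_between / (m - 1)) / s2_post
  p <- stats::pf(F_mod, m - 1, d0 + d, lower.tail = FALSE)
  if (m == 2) {
    beta_hat <- means[, 1] - means[, 2]
    m1 <- length(idx[[1]]); m2 <- length(idx[[2]])
    t_mod <- beta_hat / (sqrt(s2_post) * sqrt(1 / m1 + 1 / m2))
    p <- 2 * stats::pt(abs(t_mod), d0 + d, lower.tail = FALSE)
  } else {
    beta_hat <- means[, 1] - means[, m]
    t_mod <- rep(NA_real_, nrow(x))
  }
  out <- data.frame(feature_id = layer$feature_ids,
                    beta_hat = beta_hat,
                    s2 = s2,
                    s2_post = s2_post,
                    t_mod = t_mod,
                    F_mod = F_mod,
                    p_value = p,
                    stringsAsFactors = FALSE)
  structure(out, d0 = d0, s0_sq = s0_sq, d = d,
            group_sizes = as.integer(sizes),
            layer_name = layer$layer_name,
            class = c("moderated_stats", "data.frame"))
}

#' Select significant features and collapse probes to genes
#'
#' Keeps features with p below `alpha`; when several features map to one gene
#' the minimum-p feature represents it (ties broken by lexicographic feature
#' id). The result is ordered by increasing p-value.
#'
#' @param stats A `moderated_stats` object from [fit_ebayes()].
#' @param mapping Named character vector feature id -> gene symbol; identity
#'   when `NULL`.
#' @param alpha Significance cutoff on the (possibly adjusted) p-value.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   the default `"none"` matches raw p < alpha screening.
#' @return A `significant_features` data frame with columns `gene`,
#'   `feature_id`, `p_value`.
#' @export
select_significant <- function(stats, mapping = NULL, alpha = 0.05,
                               adjust = "none") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- stats::p.adjust(stats$p_value, method = adjust)
  gene <- if (is.null(mapping)) stats$feature_id else {
    g <- mapping[stats$feature_id]
    g[is.na(g)] <- stats$feature_id[is.na(g)]
    unname(g)
  }
  keep <- which(p < alpha)
  if (!length(keep)) {
    message("no significant features at alpha = ", alpha)
    out <- data.frame(gene = character(), feature_id = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene = gene[keep], feature_id = stats$feature_id[keep],
                     p_value = p[keep], stringsAsFactors = FALSE)
    df <- df[order(df$p_value, df$feature_id), ]
    out <- df[!duplicated(df$gene), ]
  }
  structure(out, alpha = alpha, layer_name = attr(stats, "layer_name"),
            row.names = seq_len(nrow(out)),
            class = c("significant_features", "data.frame"))
}

#' Union of significant gene sets across layers
#'
#' @param sets List of `significant_features` objects.
#' @return Sorted character vector of unique gene symbols (the screened
#'   feature universe used for fusion).
#' @export
union_features <- function(sets) {
  if (!length(sets)) stop("at least one significant-feature set is required")
  sort(unique(unlist(lapply(sets, function(s) s$gene), use.names = FALSE)))
}
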