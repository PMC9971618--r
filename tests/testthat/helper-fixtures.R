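# Shared fixtures and independent brute-force oracles.

# equicorrelated gene block: each row is sqrt(rho) * factor + sqrt(1-rho) * noise
make_block <- function(n_genes, n_samples, rho, prefix = "g") {
  f <- rnorm(n_samples)
  x <- t(vapply(seq_len(n_genes),
                function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samples),
                numeric(n_samples)))
  rownames(x) <- sprintf("%s%03d", prefix, seq_len(n_genes))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  x
}

# small two-class omics layer with optional mean shift on the first features
make_layer <- function(n_features = 20, n1 = 6, n2 = 6, shift = 0,
                       n_shifted = 0, name = "expr") {
  x <- matrix(rnorm(n_features * (n1 + n2)), n_features)
  if (n_shifted > 0)
    x[seq_len(n_shifted), seq_len(n1)] <- x[seq_len(n_shifted), seq_len(n1)] + shift
  rownames(x) <- sprintf("f%03d", seq_len(n_features))
  colnames(x) <- sprintf("s%03d", seq_len(n1 + n2))
  list(layer = omics_layer(x, name),
       annot = sample_annotation(setNames(rep(c("case", "control"), c(n1, n2)),
                                          colnames(x))))
}

# nested-loop TOM oracle, straight from the definition
tom_oracle <- function(X) {
  n <- nrow(X)
  T <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sh <- 0
    for (v in seq_len(n)) if (v != i && v != j) sh <- sh + X[i, v] * X[j, v]
    ki <- sum(X[i, -i])
    kj <- sum(X[j, -j])
    T[i, j] <- (sh + X[i, j]) / (min(ki, kj) - X[i, j] + 1)
  }
  T
}

# concordant-pair AUC oracle (ties count one half)
auc_oracle <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  tot <- 0
  for (a in ps) for (b in ns)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# double-sum SVM dual oracle
dual_oracle <- function(K, y, alpha) {
  n <- length(y)
  quad <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    quad <- quad + alpha[i] * alpha[j] * y[i] * y[j] * K[i, j]
  sum(alpha) - quad / 2
}

# diagonal-covariance nearest-centroid classifier (PAM at zero shrinkage)
nearest_centroid_oracle <- function(xtrain, ytrain, xtest, s0, prior) {
  lev <- levels(ytrain)
  cent <- vapply(lev, function(k) rowMeans(xtrain[, ytrain == k, drop = FALSE]),
                 numeric(nrow(xtrain)))
  ss <- 0
  for (k in lev)
    ss <- ss + rowSums((xtrain[, ytrain == k, drop = FALSE] - cent[, k])^2)
  s <- sqrt(ss / (ncol(xtrain) - length(lev)))
  pred <- character(ncol(xtest))
  for (m in seq_len(ncol(xtest))) {
    d <- vapply(seq_along(lev), function(k)
      sum((xtest[, m] - cent[, k])^2 / (s + s0)^2) - 2 * log(prior[k]),
      numeric(1))
    pred[m] <- lev[which.min(d)]
  }
  factor(pred, levels = lev)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# tiny planted relational system: R = G S G' from non-negative factors
planted_system <- function(seed = 99, n1 = 30, n2 = 20, r1 = 3, r2 = 2) {
  set.seed(seed)
  G1 <- matrix(abs(rnorm(n1 * r1)), n1, r1)
  G2 <- matrix(abs(rnorm(n2 * r2)), n2, r2)
  S12 <- matrix(abs(rnorm(r1 * r2)), r1, r2)
  R <- G1 %*% S12 %*% t(G2)
  sys <- structure(list(
    types = c(a = n1, b = n2),
    ids = list(a = paste0("a", seq_len(n1)), b = paste0("b", seq_len(n2))),
    relations = list("a~b" = list(i = "a", j = "b", R = R, mask = NULL,
                                  shift = 0)),
    tau = list(a = NULL, b = NULL), annot = NULL),
    class = "relational_system")
  list(sys = sys, R = R, ranks = c(a = r1, b = r2))
}

# planted kernel fixture: one class-informative kernel plus pure-noise kernels
planted_kernels <- function(seed = 5, n = 100, n_noise = 3, sep = 1.2) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  mk <- function(X) {
    K <- normalize_and_smooth(tcrossprod(X), window = 1)
    rownames(K) <- colnames(K) <- sprintf("S%03d", seq_len(n))
    K
  }
  Ks <- c(list(informative = mk(matrix(rnorm(n * 5), n, 5) +
                                  outer(y, rep(sep, 5)))),
          lapply(seq_len(n_noise),
                 function(i) mk(matrix(rnorm(n * 5), n, 5))))
  names(Ks)[-1] <- paste0("noise", seq_len(n_noise))
  list(kernels = Ks, y = y)
}
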