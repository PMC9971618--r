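#' SVM dual objective for a fixed dual vector on one kernel
#'
#' \deqn{D_{SVM}(K, \alpha) = \sum_n \alpha_n - \tfrac12 \sum_{n,m}
#'   \alpha_n \alpha_m y_n y_m K(x_n, x_m).}
#'
#' @param K Kernel matrix.
#' @param y Labels in `{-1, +1}`.
#' @param alpha Dual coefficients; must be feasible (non-negative, class
#'   balanced `sum(y * alpha) = 0`, below the box constraint).
#' @param C Box constraint used for the feasibility check.
#' @param tol Feasibility tolerance.
#' @return Scalar dual objective value.
#' @export
svm_dual_objective <- function(K, y, alpha, C = Inf, tol = 1e-8) {
  if (length(alpha) != length(y) || length(y) != nrow(K))
    stop("alpha, y and K dimensions disagree")
  if (any(alpha < -tol))
    stop("infeasible alpha: negative coefficient at position ",
         which(alpha < -tol)[1])
  if (any(alpha > C + tol))
    stop("infeasible alpha: coefficient exceeds C at position ",
         which(alpha > C + tol)[1])
  if (abs(sum(y * alpha)) > tol * max(1, sum(abs(alpha))))
    stop("infeasible alpha: sum(y * alpha) = ", sum(y * alpha), " is not 0")
  ay <- alpha * y
  sum(alpha) - 0.5 * drop(crossprod(ay, K %*% ay))
}

# soft-margin SVM dual via quadratic programming (kernlab interior point);
# the ridge keeps the low-rank reconstructed kernels numerically definite
.solve_svm_dual <- function(K, y, C, ridge = NULL) {
  n <- length(y)
  if (is.null(ridge)) ridge <- 1e-6 * mean(diag(K)) + 1e-10
  sv <- NULL
  for (try in 1:4) {
    H <- (K + ridge * diag(n)) * tcrossprod(y)
    sv <- tryCatch(
      kernlab::ipop(c = matrix(-1, n, 1), H = H,
                    A = matrix(y, 1, n), b = 0,
                    l = matrix(0, n, 1), u = matrix(C, n, 1), r = 0,
                    sigf = 9, maxiter = 200),
      error = function(e) NULL)
    if (!is.null(sv)) break
    ridge <- ridge * 1e3   # ill-conditioned kernel: re-solve more stiffly
  }
  if (is.null(sv)) stop("SVM dual solver failed on an ill-conditioned kernel")
  alpha <- pmin(pmax(drop(kernlab::primal(sv)), 0), C)
  # restore the equality constraint exactly after box clipping
  free <- alpha > 1e-9 & alpha < C - 1e-9
  gap <- sum(y * alpha)
  if (abs(gap) > 1e-12 && any(free))
    alpha[free] <- alpha[free] - y[free] * gap / sum(free)
  pmin(pmax(alpha, 0), C)
}

# offset b from the KKT conditions: average over margin support vectors,
# falling back to the midpoint rule for a hard-margin solution
.svm_offset <- function(K, y, alpha, C) {
  f0 <- drop(K %*% (alpha * y))
  margin <- alpha > 1e-7 * C & alpha < C * (1 - 1e-7)
  if (any(margin)) return(mean(y[margin] - f0[margin]))
  sv <- alpha > 1e-10
  if (!any(sv)) stop("no support vectors")
  pos <- y > 0 & sv; neg <- y < 0 & sv
  lo <- if (any(pos)) min(f0[pos]) else min(f0[y > 0])
  hi <- if (any(neg)) max(f0[neg]) else max(f0[y < 0])
  -(lo + hi) / 2
}

#' Fit the hinge-loss soft-margin multiple kernel learning model
#'
#' Alternates between (a) solving the single-kernel SVM dual on the combined
#' kernel `K_mu = sum(mu_p * K_p)` and (b) the kernel-wise hinge-loss
#' subproblem: with per-kernel dual values `D_p = D_SVM(K_p, alpha)`, the
#' margin target is the `ceiling(1/pi)`-th smallest `D_p` (the exact
#' minimizer of `-theta + pi * sum(max(0, theta - D_p))`), each kernel's
#' slack is `zeta_p = max(0, theta - D_p)`, and the combination weights move
#' multiplicatively toward kernels whose quadratic form
#' `(alpha y)' K_p (alpha y)` is large (kernels aligned with the learned
#' discriminant), with a backtracking step so the traced objective
#' `-theta + pi * sum(zeta)` never increases.
#'
#' @param kset A [kernel_set()] with binary labels.
#' @param pi Slack trade-off; must satisfy `pi >= 1/P` or there is no
#'   solution.
#' @param C SVM box constraint for the inner dual.
#' @param max_outer Maximum outer iterations.
#' @param tol Convergence tolerance on the objective change.
#' @param seed Unused randomness hook kept for interface stability (the
#'   solver is deterministic).
#' @return An `mkl_model` with fields `alpha`, `theta`, `zeta`, `hinge`,
#'   `mu`, `pi`, `C`, `b`, `objective`, `objective_trace`, `D`, `y`,
#'   `sample_ids`.
#' @export
fit_soft_margin_mkl <- function(kset, pi = 1, C = 1, max_outer = 50,
                                tol = 1e-6, seed = 1) {
  stopifnot(inherits(kset, "kernel_set"))
  P <- length(kset$kernels)
  if (pi < 1 / P - 1e-12)
    stop("pi = ", pi, " is below the feasible range: pi >= 1/P = ", 1 / P)
  for (p in seq_len(P)) {
    ev <- min(eigen(kset$kernels[[p]], symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8 * max(1, max(abs(kset$kernels[[p]]))))
      stop("kernel '", kset$names[p], "' is not positive semidefinite")
  }
  y <- kset$y
  n <- length(y)
  if (length(unique(y)) < 2) stop("both classes must be present")

  eval_state <- function(mu) {
    Kmu <- Reduce(`+`, Map(`*`, kset$kernels, mu))
    alpha <- .solve_svm_dual(Kmu, y, C)
    ay <- alpha * y
    q <- vapply(kset$kernels, function(K) drop(crossprod(ay, K %*% ay)),
                numeric(1))
    D <- sum(alpha) - q / 2
    k <- ceiling(1 / pi - 1e-9)
    theta <- sort(D)[k]
    zeta <- pmax(0, theta - D)
    list(mu = mu, alpha = alpha, q = q, D = D, theta = theta, zeta = zeta,
         obj = -theta + pi * sum(zeta), Kmu = Kmu)
  }

  mu <- rep(1 / P, P)
  st <- eval_state(mu)
  trace <- st$obj
  if (P > 1) {
    for (it in seq_len(max_outer)) {
      if (max(st$q) - min(st$q) < 1e-12 * max(1, max(abs(st$q)))) break
      eta <- 1
      accepted <- FALSE
      for (ls in 1:12) {
        w <- st$mu * (pmax(st$q, 0) + 1e-12)^eta
        cand <- eval_state(w / sum(w))
        if (cand$obj <= st$obj + 1e-12) { accepted <- TRUE; break }
        eta <- eta / 2
      }
      if (!accepted) break
      delta <- st$obj - cand$obj
      st <- cand
      trace <- c(trace, st$obj)
      if (delta < tol * max(1, abs(st$obj))) break
    }
  }
  b <- .svm_offset(st$Kmu, y, st$alpha, C)
  structure(list(alpha = st$alpha, theta = min(st$D + st$zeta),
                 zeta = st$zeta, hinge = pmax(0, st$zeta), mu = st$mu,
                 pi = pi, C = C, b = b, D = st$D,
                 objective = st$obj, objective_trace = trace,
                 kernel_names = kset$names, y = y,
                 sample_ids = rownames(kset$kernels[[1]])),
            class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat("<mkl_model> ", length(x$mu), " kernel(s), pi = ", x$pi,
      ", C = ", x$C, "\n", sep = "")
  cat("  weights:", paste(sprintf("%s=%.3f", x$kernel_names, x$mu),
                          collapse = ", "), "\n")
  cat("  theta =", format(x$theta, digits = 5),
      " objective =", format(x$objective, digits = 5),
      " support vectors:", sum(x$alpha > 1e-8), "\n")
  invisible(x)
}

#' Decision scores of a fitted MKL model
#'
#' Standard SVM decision function on the combined kernel,
#' `f(s) = sum_n alpha_n y_n K_mu(n, s) + b`; higher scores favour the +1
#' class.
#'
#' @param model An `mkl_model`.
#' @param kernels A [kernel_set()] or named list of kernels whose rows cover
#'   the training samples and whose columns cover the requested samples.
#' @param test_columns Column indices or names to score; defaults to all
#'   columns.
#' @return Named numeric vector of decision scores.
#' @export
decision_scores <- function(model, kernels, test_columns = NULL) {
  kl <- if (inherits(kernels, "kernel_set")) kernels$kernels else kernels
  if (length(kl) != length(model$mu))
    stop("kernel count does not match the fitted model")
  if (sum(model$alpha > 1e-10) == 0) stop("no support vectors")
  K1 <- kl[[1]]
  rows <- if (!is.null(model$sample_ids) && !is.null(rownames(K1)))
    match(model$sample_ids, rownames(K1)) else seq_along(model$y)
  if (anyNA(rows)) stop("training samples missing from the kernel rows")
  if (is.null(test_columns)) test_columns <- seq_len(ncol(K1))
  Kmu <- Reduce(`+`, Map(`*`, lapply(kl, function(K)
    K[rows, test_columns, drop = FALSE]), model$mu))
  drop(crossprod(Kmu, model$alpha * model$y)) + model$b
}
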