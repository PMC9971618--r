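rel_key <- function(i, j) paste(i, j, sep = "~")

# order-independent 32-bit string hash, used to give each object type its own
# reproducible initialization stream regardless of type ordering
.type_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

#' Build the relational block system from screened omics layers
#'
#' Object types are `gene`, `sample`, and one feature-space type per layer
#' whose features are not exactly the gene set (multi-probe layers). A
#' gene-keyed layer contributes a single (gene, sample) data relation when
#' that slot is still free (one relation per type pair); a multi-probe layer
#' contributes a binary (gene, feature) membership relation plus a
#' (feature, sample) data relation. Data relations are shifted by their
#' minimum so all stored entries are non-negative (the shift is recorded);
#' missing entries are zero-filled and flagged in the observed mask.
#'
#' @param layers List of [omics_layer()] objects sharing one ordered sample
#'   set (see [intersect_samples()]).
#' @param annot Sample annotation for those samples.
#' @param genes Character vector of gene symbols to which features are
#'   restricted (typically the screened union from [union_features()]);
#'   defaults to the sorted union of all mapped genes.
#' @return A `relational_system`: list with `types` (named integer sizes),
#'   `ids` (identifiers per type), `relations` (each `list(i, j, R, mask,
#'   shift)`), `tau` (constraint matrices, `NULL` = zero), `annot`.
#' @export
build_relational_system <- function(layers, annot, genes = NULL) {
  if (!length(layers)) stop("at least one layer is required")
  sample_ids <- layers[[1]]$sample_ids
  for (ly in layers)
    if (!identical(ly$sample_ids, sample_ids))
      stop("layers do not share an identical ordered sample set")
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(layers, `[[`, "feature_to_gene"),
                                use.names = FALSE)))
  types <- c(gene = length(genes), sample = length(sample_ids))
  ids <- list(gene = genes, sample = sample_ids)
  relations <- list()

  add_rel <- function(i, j, R, mask = NULL, shift = 0) {
    relations[[rel_key(i, j)]] <<- list(i = i, j = j, R = R, mask = mask,
                                        shift = shift)
  }

  for (ly in layers) {
    keep <- ly$feature_to_gene[ly$feature_ids] %in% genes
    if (!any(keep)) next
    feats <- ly$feature_ids[keep]
    vals <- ly$values[feats, , drop = FALSE]
    mask <- !is.na(vals)
    vals[!mask] <- 0
    mn <- min(vals)
    shift <- if (mn < 0) -mn else 0
    vals <- vals + shift
    gmap <- ly$feature_to_gene[feats]
    gene_keyed <- setequal(feats, genes)
    if (gene_keyed && is.null(relations[[rel_key("gene", "sample")]])) {
      vals <- vals[genes, , drop = FALSE]
      add_rel("gene", "sample", vals, mask[genes, , drop = FALSE], shift)
    } else {
      tname <- paste0("feat_", ly$layer_name)
      if (tname %in% names(types))
        stop("duplicate layer name '", ly$layer_name, "'")
      types[tname] <- length(feats)
      ids[[tname]] <- feats
      member <- matrix(0, length(genes), length(feats),
                       dimnames = list(genes, feats))
      member[cbind(match(gmap, genes), seq_along(feats))] <- 1
      add_rel("gene", tname, member)
      add_rel(tname, "sample", vals, mask, shift)
    }
  }
  if (length(types) < 2 || !length(relations))
    stop("relational system needs at least two object types and one relation")
  structure(list(types = types, ids = ids, relations = relations,
                 tau = stats::setNames(vector("list", length(types)), names(types)),
                 annot = annot),
            class = "relational_system")
}

#' @export
print.relational_system <- function(x, ...) {
  cat("<relational_system> ", length(x$types), " object types, ",
      length(x$relations), " relation block(s)\n", sep = "")
  for (nm in names(x$types))
    cat("  type ", nm, ": ", x$types[[nm]], "\n", sep = "")
  for (r in x$relations)
    cat("  R[", r$i, ", ", r$j, "]: ", nrow(r$R), " x ", ncol(r$R), "\n", sep = "")
  invisible(x)
}

.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 0) & s$d > 0
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

.tri_objective <- function(sys, G, S) {
  obj <- 0
  for (key in names(sys$relations)) {
    r <- sys$relations[[key]]
    resid <- r$R - G[[r$i]] %*% S[[key]] %*% t(G[[r$j]])
    obj <- obj + sum(resid^2)
  }
  for (p in names(sys$types)) {
    tau <- sys$tau[[p]]
    if (!is.null(tau)) obj <- obj + sum(diag(crossprod(G[[p]], tau %*% G[[p]])))
  }
  obj
}

#' Fit the penalized non-negative tri-factorization
#'
#' Minimizes
#' \deqn{\sum_{(i,j)} \| R_{ij} - G_i S_{ij} G_j^T \|_F^2 +
#'       \sum_p \mathrm{tr}(G_p^T \tau_p G_p), \quad G_p \ge 0,}
#' by block-coordinate descent: each `S_ij` is the exact least-squares solve
#' `pinv(G_i' G_i) G_i' R_ij G_j pinv(G_j' G_j)`, and each non-negative `G_p`
#' takes a multiplicative update with positive/negative splitting of the
#' gradient (semi-NMF style, `tau` split as tau+ - tau-), which keeps the
#' objective non-increasing. The trace is asserted non-increasing every sweep.
#'
#' @param sys A `relational_system` from [build_relational_system()].
#' @param ranks Named integer vector of factorization ranks per object type;
#'   default `min(ceiling(n_p / 10), 50)`.
#' @param max_iter Maximum number of sweeps.
#' @param tol Relative objective decrease below which iteration stops.
#' @param seed Integer seed for the `|N(0,1)|` initialization.
#' @return A `tri_factorization`: list with `G` (non-negative factors per
#'   type), `S` (latent relation per block), `ranks`, `objective_trace`,
#'   `sys_types`, `ids`.
#' @export
fit_trifactorization <- function(sys, ranks = NULL, max_iter = 500,
                                 tol = 1e-6, seed = 1) {
  stopifnot(inherits(sys, "relational_system"), max_iter >= 1)
  sizes <- sys$types
  if (is.null(ranks)) ranks <- pmin(ceiling(sizes / 10), 50L)
  ranks <- ranks[names(sizes)]
  if (anyNA(ranks)) stop("ranks must be named by object type")
  if (any(ranks < 1) || any(ranks > sizes))
    stop("each rank must satisfy 1 <= r_p <= n_p")

  allR <- unlist(lapply(sys$relations, function(r) mean(r$R)))
  mbar <- max(mean(allR), 1e-8)
  G <- list()
  for (p in names(sizes)) {
    set.seed(.type_seed(seed, p))
    G[[p]] <- matrix(abs(stats::rnorm(sizes[[p]] * ranks[[p]])) *
                       sqrt(mbar / ranks[[p]]),
                     sizes[[p]], ranks[[p]])
  }

  solve_S <- function() {
    S <- list()
    for (key in names(sys$relations)) {
      r <- sys$relations[[key]]
      Gi <- G[[r$i]]; Gj <- G[[r$j]]
      S[[key]] <- .pinv(crossprod(Gi)) %*% t(Gi) %*% r$R %*% Gj %*%
        .pinv(crossprod(Gj))
    }
    S
  }

  S <- solve_S()
  trace <- .tri_objective(sys, G, S)
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    # multiplicative non-negative update of each G_p, others fixed;
    # types are visited in name order so results do not depend on how the
    # system was assembled
    for (p in sort(names(sizes))) {
      A <- matrix(0, sizes[[p]], ranks[[p]])
      Bpos <- matrix(0, ranks[[p]], ranks[[p]])
      Bneg <- Bpos
      touched <- FALSE
      for (key in names(sys$relations)) {
        r <- sys$relations[[key]]
        if (r$i == p) {
          H <- G[[r$j]] %*% t(S[[key]])           # n_j x r_p
          A <- A + r$R %*% H
          B <- crossprod(H)
          Bpos <- Bpos + pmax(B, 0); Bneg <- Bneg + pmax(-B, 0)
          touched <- TRUE
        }
        if (r$j == p) {
          H <- G[[r$i]] %*% S[[key]]              # n_i x r_p
          A <- A + t(r$R) %*% H
          B <- crossprod(H)
          Bpos <- Bpos + pmax(B, 0); Bneg <- Bneg + pmax(-B, 0)
          touched <- TRUE
        }
      }
      if (!touched) next
      Apos <- pmax(A, 0); Aneg <- pmax(-A, 0)
      num <- Apos + G[[p]] %*% Bneg
      den <- Aneg + G[[p]] %*% Bpos
      tau <- sys$tau[[p]]
      if (!is.null(tau)) {
        num <- num + pmax(-tau, 0) %*% G[[p]]
        den <- den + pmax(tau, 0) %*% G[[p]]
      }
      G[[p]] <- G[[p]] * sqrt((num + eps) / (den + eps))
    }
    S <- solve_S()
    obj <- .tri_objective(sys, G, S)
    prev <- trace[length(trace)]
    if (obj > prev * (1 + 1e-9) + 1e-12)
      stop("internal error: objective increased at sweep ", it,
           " (", prev, " -> ", obj, ")")
    trace <- c(trace, obj)
    if (prev > 0 && (prev - obj) / prev < tol) break
  }
  structure(list(G = G, S = S, ranks = ranks, objective_trace = trace,
                 sys_types = sizes, ids = sys$ids,
                 relations = lapply(sys$relations, function(r) r[c("i", "j", "shift")])),
            class = "tri_factorization")
}

#' @export
print.tri_factorization <- function(x, ...) {
  cat("<tri_factorization> ranks:",
      paste(names(x$ranks), x$ranks, sep = "=", collapse = ", "), "\n")
  tr <- x$objective_trace
  cat("  objective:", format(tr[1], digits = 6), "->",
      format(tr[length(tr)], digits = 6), "in", length(tr) - 1, "sweep(s)\n")
  invisible(x)
}

#' Reconstruct a relation block from the fitted factors
#'
#' Returns `G_i S_ij G_j'`; if only the opposite orientation was fitted, the
#' transpose of that reconstruction is returned.
#'
#' @param fac A `tri_factorization`.
#' @param i,j Object-type names.
#' @return Reconstructed matrix of shape `n_i` by `n_j` with identifier
#'   dimnames.
#' @export
reconstruct <- function(fac, i, j) {
  key <- rel_key(i, j)
  if (!is.null(fac$S[[key]])) {
    out <- fac$G[[i]] %*% fac$S[[key]] %*% t(fac$G[[j]])
  } else if (!is.null(fac$S[[rel_key(j, i)]])) {
    out <- t(reconstruct(fac, j, i))
  } else {
    stop("no fitted relation between '", i, "' and '", j, "'")
  }
  dimnames(out) <- list(fac$ids[[i]], fac$ids[[j]])
  out
}
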