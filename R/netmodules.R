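.module_palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                     "black", "pink", "magenta", "purple", "greenyellow",
                     "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                     "grey60", "lightgreen", "lightyellow", "royalblue",
                     "darkred", "darkgreen", "darkturquoise", "darkgrey",
                     "orange")

# scale-free topology fit R^2: regression of log10 p(k) on log10 k over
# connectivity bins
.scale_free_r2 <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(k) < n_breaks) return(0)
  if (diff(range(k)) < 1e-10 * max(k)) return(0)  # flat connectivity
  cuts <- cut(k, breaks = n_breaks)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Choose the soft-thresholding power for scale-free topology
#'
#' Returns the smallest candidate power whose scale-free fit R^2 (regression
#' of log p(k) on log k over connectivity bins) reaches `r2_target`; when no
#' candidate reaches it, the power with the maximal R^2 is returned.
#'
#' @param expr Gene-by-sample matrix.
#' @param powers Candidate powers (at least three).
#' @param r2_target Target fit; default 0.8.
#' @return Integer/numeric power, with attribute `fit_table` (power, r2,
#'   mean_k).
#' @export
pick_soft_power <- function(expr, powers = c(1:10, seq(12, 20, 2)),
                            r2_target = 0.8) {
  if (length(powers) < 3) stop("supply at least three candidate powers")
  if (nrow(expr) < 10) stop("need at least 10 genes to bin connectivities")
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    k <- rowSums(ac^b)
    data.frame(power = b, r2 = .scale_free_r2(k), mean_k = mean(k))
  }))
  hit <- which(tab$r2 >= r2_target)
  chosen <- if (length(hit)) tab$power[hit[1]] else tab$power[which.max(tab$r2)]
  structure(chosen, fit_table = tab)
}

#' Co-expression adjacency matrix
#'
#' Unsigned weighted adjacency `|cor|^power`, or its booleanization at a
#' hard threshold.
#'
#' @param expr Gene-by-sample matrix without constant rows.
#' @param power Soft-thresholding power.
#' @param mode `"weighted"` (default) or `"boolean"`.
#' @param threshold Hard threshold for boolean mode.
#' @return An `adjacency_matrix`: symmetric matrix in `[0, 1]`, unit
#'   diagonal, with attributes `power` and `mode`.
#' @export
adjacency_matrix <- function(expr, power = 1,
                             mode = c("weighted", "boolean"),
                             threshold = 0.5) {
  mode <- match.arg(mode)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene '", rownames(expr)[which(sds == 0)[1]], "'")
  X <- abs(stats::cor(t(expr)))^power
  if (mode == "boolean") X <- (X >= threshold) + 0
  diag(X) <- 1
  structure((X + t(X)) / 2, power = power, mode = mode,
            class = c("adjacency_matrix", "matrix", "array"))
}

#' Topological overlap matrix
#'
#' For `i != j`,
#' \deqn{TOM(i,j) = \frac{\sum_{v \ne i,j} X_{iv} X_{jv} + X_{ij}}
#'   {\min(\sum_{v \ne i} X_{iv}, \sum_{v \ne j} X_{jv}) - X_{ij} + 1},}
#' and `TOM(i,i) = 1`. Works for weighted adjacencies in `[0, 1]` with the
#' Boolean case as a special instance. Self-edges are excluded from all sums.
#'
#' @param X Adjacency matrix (values in `[0, 1]`).
#' @return A `tom_matrix` list with `T` (similarity) and `dissT = 1 - T`.
#' @export
tom_similarity <- function(X) {
  X <- unclass(as.matrix(X))
  A <- X
  diag(A) <- 0
  shared <- A %*% A                 # sum over v != i, j since diag(A) = 0
  k <- rowSums(A)
  num <- shared + A
  den <- outer(k, k, pmin) - A + 1
  T <- num / den
  diag(T) <- 1
  T <- (T + t(T)) / 2
  dimnames(T) <- dimnames(X)
  structure(list(T = T, dissT = 1 - T), class = "tom_matrix")
}

# walk the hclust merge tree: members and subtree heights per internal node
.hc_subtrees <- function(hc) {
  n <- nrow(hc$merge) + 1
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    row <- hc$merge[i, ]
    get1 <- function(v) if (v < 0) -v else members[[v]]
    members[[i]] <- c(get1(row[1]), get1(row[2]))
  }
  members
}

#' Cut a dissimilarity dendrogram into gene modules
#'
#' Average-linkage (UPGMA) clustering of `dissT` followed by a dynamic
#' tree-style cut: starting from the root, a branch is split at the largest
#' jump in its sorted merge heights whenever that jump exceeds `gap` times
#' the dendrogram's height range, recursing into the resulting components;
#' undersized components fall into the unassigned pool. Because average
#' linkage chains weakly connected genes onto dense branches, each accepted
#' module is then pruned by membership: genes whose mean topological overlap
#' with the other members is below half the module's median membership are
#' returned to the pool (the analogue of eigengene-based membership
#' filtering in weighted co-expression analysis). Modules are named by a
#' size-ordered colour palette with `grey` holding unassigned genes.
#'
#' @param dissT Symmetric dissimilarity matrix (e.g. `1 - TOM`).
#' @param min_module_size Minimum genes per accepted module.
#' @param gap Minimum height drop required to split a branch, as a fraction
#'   of the dendrogram's total height range (scale-free in the soft power).
#' @param prune Apply the membership pruning pass described above.
#' @return A `gene_modules` object: list of modules, each
#'   `list(module_id, genes)`, with attribute `unassigned`.
#' @export
cut_modules <- function(dissT, min_module_size = 20, gap = 0.2,
                        prune = TRUE) {
  if (inherits(dissT, "tom_matrix")) dissT <- dissT$dissT
  n <- nrow(dissT)
  if (n < 4) stop("too few genes to cluster (", n, ")")
  genes <- rownames(dissT)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  hc <- stats::hclust(stats::as.dist(dissT), method = "average")
  members <- .hc_subtrees(hc)
  heights <- hc$height
  hrange <- max(heights) - min(heights)
  gap_abs <- if (hrange > 0) gap * hrange else Inf
  node_members <- function(v) if (v < 0) -v else members[[v]]

  # internal nodes of the subtree rooted at v
  subtree_nodes <- function(v) {
    out <- integer()
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (u > 0) {
        out <- c(out, u)
        stack <- c(stack, hc$merge[u, ])
      }
    }
    out
  }
  # maximal subtrees strictly below the cut height (UPGMA heights are
  # monotone, so a simple descent suffices)
  components_below <- function(v, cut_h) {
    comps <- list()
    stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (u < 0 || heights[u] < cut_h) comps[[length(comps) + 1]] <- u
      else stack <- c(stack, hc$merge[u, ])
    }
    comps
  }

  modules <- list()
  pool <- integer()
  descend <- function(v) {
    mem <- node_members(v)
    if (length(mem) < min_module_size) {
      pool <<- c(pool, mem)
      return(invisible())
    }
    nodes <- subtree_nodes(v)
    h <- sort(heights[nodes])
    gaps <- diff(h)
    if (!length(gaps) || max(gaps) < gap_abs) {
      modules[[length(modules) + 1]] <<- mem
      return(invisible())
    }
    g <- which.max(gaps)
    cut_h <- (h[g] + h[g + 1]) / 2
    comps <- components_below(v, cut_h)
    sizes <- vapply(comps, function(u) length(node_members(u)), integer(1))
    if (!any(sizes >= min_module_size)) {
      # splitting would only make dust: keep the branch whole
      modules[[length(modules) + 1]] <<- mem
      return(invisible())
    }
    for (u in comps) descend(u)
  }
  descend(n - 1L)

  if (prune && length(modules)) {
    Tm <- 1 - dissT
    kept <- list()
    for (mem in modules) {
      for (pass in 1:2) {
        if (length(mem) < 3) break
        q <- rowMeans(Tm[mem, mem, drop = FALSE]) -
          diag(Tm)[mem] / length(mem)
        keep <- q >= stats::median(q) / 2
        if (all(keep)) break
        pool <- c(pool, mem[!keep])
        mem <- mem[keep]
      }
      if (length(mem) >= min_module_size) kept[[length(kept) + 1]] <- mem
      else pool <- c(pool, mem)
    }
    modules <- kept
  }

  ord <- order(-vapply(modules, length, integer(1)))
  modules <- modules[ord]
  cols <- rep_len(.module_palette, max(1, length(modules)))
  out <- lapply(seq_along(modules), function(i)
    list(module_id = cols[i], genes = sort(genes[modules[[i]]])))
  structure(out, unassigned = sort(genes[pool]), class = "gene_modules")
}

#' @export
print.gene_modules <- function(x, ...) {
  cat("<gene_modules> ", length(x), " module(s); ",
      length(attr(x, "unassigned")), " unassigned (grey)\n", sep = "")
  for (m in x)
    cat("  ", m$module_id, ": ", length(m$genes), " genes\n", sep = "")
  invisible(x)
}

#' Cluster-validity and network-concept indices
#'
#' Dunn index (minimum between-module dissimilarity over maximum
#' within-module diameter) and mean silhouette width are computed on
#' `dissT` for the assigned genes; density, centralization, heterogeneity,
#' average scaled connectivity, average clustering coefficient and average
#' maximum adjacency ratio are the standard weighted network concepts of the
#' full adjacency.
#'
#' @param X Adjacency matrix.
#' @param dissT Dissimilarity matrix (same genes).
#' @param modules A `gene_modules` object.
#' @return Named list of the eight indices.
#' @export
validity_indices <- function(X, dissT, modules) {
  if (inherits(dissT, "tom_matrix")) dissT <- dissT$dissT
  X <- unclass(as.matrix(X))
  if (!length(modules)) stop("at least one module is required")
  genes <- rownames(X)
  if (is.null(genes)) genes <- rownames(dissT)
  assign <- rep(NA_integer_, nrow(X))
  names(assign) <- genes
  for (i in seq_along(modules)) assign[modules[[i]]$genes] <- i
  inmod <- !is.na(assign)

  # Dunn on assigned genes
  dd <- dissT[inmod, inmod, drop = FALSE]
  cl <- assign[inmod]
  diam <- 0; sep <- Inf
  for (i in unique(cl)) {
    ii <- cl == i
    if (sum(ii) > 1) diam <- max(diam, max(dd[ii, ii]))
    else warning("module ", modules[[i]]$module_id,
                 " has a single gene; skipped in diameter")
    for (j in unique(cl)) if (j > i) sep <- min(sep, min(dd[ii, cl == j]))
  }
  dunn <- if (is.finite(sep) && diam > 0) sep / diam else NA_real_
  sil <- if (length(unique(cl)) > 1)
    mean(cluster::silhouette(as.integer(cl), dmatrix = dd)[, "sil_width"])
  else NA_real_

  # weighted network concepts on the full adjacency
  A <- X; diag(A) <- 0
  n <- nrow(A)
  k <- rowSums(A)
  kmax <- max(k)
  density <- sum(k) / (n * (n - 1))
  centralization <- if (n > 2) (n / (n - 2)) * (kmax / (n - 1) - density) else NA_real_
  heterogeneity <- if (mean(k) > 0)
    sqrt(mean(k^2) / mean(k)^2 - 1) else 0
  scaled_k <- if (kmax > 0) mean(k / kmax) else 0
  denom_cc <- k^2 - rowSums(A^2)
  numer_cc <- diag(A %*% A %*% A)
  cc <- ifelse(denom_cc > 0, numer_cc / denom_cc, 0)
  mar <- ifelse(k > 0, rowSums(A^2) / k, 0)

  list(dunn_index = dunn,
       avg_scaled_connectivity = scaled_k,
       silhouette_width = sil,
       avg_cluster_coefficient = mean(cc),
       avg_max_adjacency_ratio = mean(mar),
       density = density,
       centralization = centralization,
       heterogeneity = heterogeneity)
}
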