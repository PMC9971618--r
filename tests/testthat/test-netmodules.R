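test_that("soft-power selection honours the target and its fallbacks", {
  set.seed(81)
  x <- rbind(make_block(40, 60, 0.6, "a"), make_block(40, 60, 0.4, "b"))
  p0 <- pick_soft_power(x, powers = 1:6, r2_target = 0)
  expect_equal(as.numeric(p0), 1)          # vacuous target: smallest power
  p <- pick_soft_power(x, powers = 1:6, r2_target = 0.8)
  tab <- attr(p, "fit_table")
  expect_equal(nrow(tab), 6L)
  # chosen power is either the first to reach the target or the max-R2 one
  hit <- tab$power[tab$r2 >= 0.8]
  expected <- if (length(hit)) hit[1] else tab$power[which.max(tab$r2)]
  expect_equal(as.numeric(p), expected)
  expect_error(pick_soft_power(x[1:5, ], powers = 1:3), "at least 10")
  # degenerate input exercises the fallback branch without error
  xc <- matrix(rep(rnorm(30), each = 12), 12) + 1e-8 * rnorm(12 * 30)
  rownames(xc) <- sprintf("c%02d", 1:12)
  expect_no_error(pick_soft_power(xc, powers = 1:3, r2_target = 0.99))
})

test_that("adjacency matches the pairwise correlation oracle", {
  set.seed(82)
  x <- make_block(12, 25, 0.5)
  A <- adjacency_matrix(x, power = 1)
  oracle <- matrix(1, 12, 12)
  for (i in 1:12) for (j in 1:12)
    oracle[i, j] <- abs(cor(x[i, ], x[j, ]))
  diag(oracle) <- 1
  expect_equal(unclass(A), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  # perfectly correlated and anti-correlated pairs both give adjacency 1
  y <- rbind(a = 1:10, b = 2 * (1:10) + 3, c = -(1:10))
  colnames(y) <- sprintf("s%02d", 1:10)
  A2 <- adjacency_matrix(y + 1e-9 * matrix(rnorm(30), 3), power = 7)
  expect_gt(A2["a", "b"], 0.999)
  expect_gt(A2["a", "c"], 0.999)
  expect_error(adjacency_matrix(rbind(y, d = rep(1, 10)), 1), "constant")
  # boolean mode yields 0/1 entries
  Ab <- adjacency_matrix(x, power = 1, mode = "boolean", threshold = 0.3)
  expect_true(all(unclass(Ab) %in% c(0, 1)))
})

test_that("TOM equals the definition on hand cases and random fixtures", {
  # complete Boolean graph on 3 nodes: off-diagonal TOM = 1
  K3 <- matrix(1, 3, 3)
  T3 <- tom_similarity(K3)$T
  expect_equal(T3, matrix(1, 3, 3))
  # empty graph: TOM = identity
  E <- diag(3)
  expect_equal(tom_similarity(E)$T, diag(3))
  # random weighted and Boolean fixtures against the triple-loop oracle
  set.seed(83)
  for (i in 1:50) {
    n <- sample(5:15, 1)
    X <- matrix(runif(n * n), n)
    X <- (X + t(X)) / 2
    if (i %% 2 == 0) X <- (X > 0.5) + 0
    diag(X) <- 1
    tm <- tom_similarity(X)
    expect_equal(tm$T, tom_oracle(X), tolerance = 1e-12)
    expect_equal(tm$dissT, 1 - tm$T, tolerance = 1e-15)
    expect_true(all(tm$T >= -1e-12 & tm$T <= 1 + 1e-12))
    expect_equal(tm$T, t(tm$T), tolerance = 1e-15)
  }
})

test_that("planted blocks are recovered by the dynamic tree cut", {
  set.seed(84)
  x <- rbind(make_block(60, 100, 0.81, "a"), make_block(60, 100, 0.81, "b"))
  tm <- tom_similarity(adjacency_matrix(x, power = 1))
  mods <- cut_modules(tm$dissT, min_module_size = 20)
  expect_length(mods, 2L)
  truth <- rep(c(1, 2), each = 60)
  names(truth) <- rownames(x)
  found <- integer(120); names(found) <- rownames(x)
  for (i in seq_along(mods)) found[mods[[i]]$genes] <- i
  expect_gte(adjusted_rand(truth, found), 0.9)
  # single homogeneous block: one module with all genes
  x1 <- make_block(60, 100, 0.81, "h")
  m1 <- cut_modules(tom_similarity(adjacency_matrix(x1, 1))$dissT, 20)
  expect_length(m1, 1L)
  expect_length(m1[[1]]$genes, 60L)
  # oversized minimum: at most one accepted module
  mbig <- cut_modules(tm$dissT, min_module_size = 70)
  expect_lte(length(mbig), 1L)
})

test_that("module assignment is invariant under gene permutation", {
  set.seed(85)
  x <- rbind(make_block(30, 80, 0.8, "a"), make_block(30, 80, 0.8, "b"))
  tm <- tom_similarity(adjacency_matrix(x, power = 1))
  mods <- cut_modules(tm$dissT, min_module_size = 10)
  perm <- sample(60)
  mods_p <- cut_modules(tm$dissT[perm, perm], min_module_size = 10)
  sets <- function(m) lapply(m, `[[`, "genes")
  expect_setequal(vapply(sets(mods), paste, "", collapse = ","),
                  vapply(sets(mods_p), paste, "", collapse = ","))
})

test_that("validity indices behave on contrasting fixtures", {
  set.seed(86)
  sep <- rbind(make_block(30, 80, 0.85, "a"), make_block(30, 80, 0.85, "b"))
  tm_sep <- tom_similarity(adjacency_matrix(sep, 1))
  mods_sep <- cut_modules(tm_sep$dissT, 10)
  v_sep <- validity_indices(adjacency_matrix(sep, 1), tm_sep$dissT, mods_sep)
  # merged noise: same module count forced on incoherent data
  noise <- rbind(make_block(30, 80, 0.15, "a"), make_block(30, 80, 0.15, "b"))
  tm_no <- tom_similarity(adjacency_matrix(noise, 1))
  truth_split <- list(list(module_id = "turquoise",
                           genes = rownames(noise)[1:30]),
                      list(module_id = "blue",
                           genes = rownames(noise)[31:60]))
  v_no <- validity_indices(adjacency_matrix(noise, 1), tm_no$dissT,
                           structure(truth_split, class = "gene_modules"))
  expect_gt(v_sep$dunn_index, v_no$dunn_index)
  expect_gt(v_sep$silhouette_width, v_no$silhouette_width)
  expect_true(v_sep$silhouette_width >= -1 && v_sep$silhouette_width <= 1)
  expect_true(v_sep$density >= 0 && v_sep$density <= 1)
  expect_true(v_sep$centralization >= 0 && v_sep$centralization <= 1)
  # flat network: zero connectivity variance
  flat <- matrix(0.4, 20, 20); diag(flat) <- 1
  rownames(flat) <- colnames(flat) <- sprintf("f%02d", 1:20)
  v_flat <- validity_indices(flat, 1 - flat,
                             structure(list(list(module_id = "turquoise",
                                                 genes = rownames(flat))),
                                       class = "gene_modules"))
  expect_equal(v_flat$heterogeneity, 0, tolerance = 1e-12)
})
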