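test_that("zero-mean normalization standardizes rows and drops constants", {
  x <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-2, 0, 4))
  colnames(x) <- c("s1", "s2", "s3")
  ly <- omics_layer(x, "t")
  expect_warning(norm <- zero_mean_normalize(ly), "constant")
  expect_identical(norm$feature_ids, c("a", "c"))
  expect_equal(unname(rowMeans(norm$values)), c(0, 0), tolerance = 1e-12)
  # population sd = 1
  expect_equal(unname(sqrt(rowMeans(norm$values^2))), c(1, 1),
               tolerance = 1e-12)
  # idempotent on already-standardized rows
  again <- zero_mean_normalize(norm)
  expect_equal(again$values, norm$values, tolerance = 1e-12)
})

test_that("missing-value filtering removes exactly the incomplete features", {
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:4)))
  x[3, 2] <- NA
  ly <- omics_layer(x, "meth")
  kept <- drop_missing_features(ly)
  expect_equal(nrow(kept$values), 9L)
  expect_false("f03" %in% kept$feature_ids)
  expect_identical(drop_missing_features(kept)$values, kept$values)
  xall <- x; xall[, 1] <- NA
  expect_error(drop_missing_features(omics_layer(xall, "m")), "every feature")
})

test_that("moderated t reduces to the classical pooled t when d0 = 0", {
  set.seed(31)
  fx <- make_layer(n_features = 20, n1 = 6, n2 = 7)
  st <- fit_ebayes(fx$layer, fx$annot, d0 = 0)
  classical <- apply(fx$layer$values, 1, function(r)
    stats::t.test(r[1:6], r[7:13], var.equal = TRUE)$statistic)
  expect_equal(unname(st$t_mod), unname(classical), tolerance = 1e-10)
  expect_equal(st$s2_post, st$s2, tolerance = 1e-12)
})

test_that("posterior variance is the stated blend and matches limma", {
  skip_if_not_installed("limma")
  set.seed(32)
  fx <- make_layer(n_features = 300, n1 = 8, n2 = 7, shift = 1.5,
                   n_shifted = 30)
  # heterogeneous feature variances keep the prior degrees of freedom finite
  fx$layer$values <- fx$layer$values * exp(rnorm(300) / 2)
  st <- fit_ebayes(fx$layer, fx$annot)
  expect_lt(attr(st, "d0"), 1e6)
  d0 <- attr(st, "d0"); s0 <- attr(st, "s0_sq"); d <- attr(st, "d")
  expect_equal(st$s2_post, (d0 * s0 + d * st$s2) / (d0 + d), tolerance = 1e-12)
  # convex combination bounds
  expect_true(all(st$s2_post >= pmin(st$s2, s0) - 1e-12))
  expect_true(all(st$s2_post <= pmax(st$s2, s0) + 1e-12))

  grp <- factor(rep(c("case", "control"), c(8, 7)))
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  fit <- limma::contrasts.fit(limma::lmFit(fx$layer$values, design),
                              limma::makeContrasts(case - control,
                                                   levels = design))
  eb <- limma::eBayes(fit)
  expect_equal(attr(st, "d0"), eb$df.prior, tolerance = 1e-8)
  expect_equal(attr(st, "s0_sq"), eb$s2.prior, tolerance = 1e-8)
  expect_equal(unname(st$t_mod), unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(unname(st$p_value), unname(eb$p.value[, 1]), tolerance = 1e-10)
})

test_that("three-group moderated F matches the limma group-effect F", {
  skip_if_not_installed("limma")
  set.seed(33)
  x <- matrix(rnorm(200 * 15), 200,
              dimnames = list(sprintf("f%03d", 1:200), sprintf("s%02d", 1:15)))
  g <- rep(c("A", "B", "C"), each = 5)
  ly <- omics_layer(x, "t")
  st <- fit_ebayes(ly, sample_annotation(setNames(g, colnames(x))))
  fit <- limma::lmFit(x, stats::model.matrix(~ factor(g)))
  eb <- limma::eBayes(fit)
  tt <- limma::topTable(eb, coef = 2:3, number = Inf, sort.by = "none")
  expect_equal(unname(st$F_mod), unname(tt$F), tolerance = 1e-8)
  expect_equal(unname(st$p_value), unname(tt$P.Value), tolerance = 1e-8)
})

test_that("moderated t is antisymmetric under label swap, F and p invariant", {
  set.seed(34)
  fx <- make_layer(n_features = 40, n1 = 5, n2 = 7)
  st1 <- fit_ebayes(fx$layer, fx$annot)
  swapped <- sample_annotation(setNames(
    ifelse(as.character(fx$annot) == "case", "control", "case"),
    names(fx$annot)))
  st2 <- fit_ebayes(fx$layer, swapped)
  expect_equal(st1$t_mod, -st2$t_mod, tolerance = 1e-12)
  expect_equal(st1$F_mod, st2$F_mod, tolerance = 1e-12)
  expect_equal(st1$p_value, st2$p_value, tolerance = 1e-12)
})

test_that("null data give a calibrated type-I error rate", {
  set.seed(35)
  fx <- make_layer(n_features = 1000, n1 = 10, n2 = 10)
  st <- fit_ebayes(fx$layer, fx$annot)
  expect_true(all(st$p_value >= 0 & st$p_value <= 1))
  frac <- mean(st$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("significance selection collapses probes and is monotone in alpha", {
  p <- c(f1 = 0.01, f2 = 0.03, f3 = 0.2, f4 = 0.001, f5 = 0.03)
  st <- structure(data.frame(feature_id = names(p), beta_hat = 1, s2 = 1,
                             s2_post = 1, t_mod = 1, F_mod = 1, p_value = p,
                             stringsAsFactors = FALSE),
                  layer_name = "toy",
                  class = c("moderated_stats", "data.frame"))
  mapping <- c(f1 = "G1", f2 = "G1", f3 = "G2", f4 = "G3", f5 = "G4")
  sel <- select_significant(st, mapping, alpha = 0.05)
  expect_identical(sel$gene, c("G3", "G1", "G4"))   # sorted by p
  expect_identical(sel$feature_id[sel$gene == "G1"], "f1")  # min-p probe
  # tie at equal p: lexicographically smallest feature id wins
  mapping2 <- c(f1 = "G1", f2 = "G9", f3 = "G2", f4 = "G3", f5 = "G9")
  sel2 <- select_significant(st, mapping2, alpha = 0.05)
  expect_identical(sel2$feature_id[sel2$gene == "G9"], "f2")
  # monotone: smaller alpha yields a subset
  sel_small <- select_significant(st, mapping, alpha = 0.005)
  expect_true(all(sel_small$gene %in% sel$gene))
  expect_message(
    empty <- select_significant(st, mapping, alpha = 1e-6), "no significant")
  expect_equal(nrow(empty), 0L)
})

test_that("the cross-layer union is a sorted deduplicated gene list", {
  mk <- function(genes, layer) structure(
    data.frame(gene = genes, feature_id = genes,
               p_value = seq_along(genes) / 100, stringsAsFactors = FALSE),
    layer_name = layer, class = c("significant_features", "data.frame"))
  expect_identical(union_features(list(mk(c("B", "A"), "x"),
                                       mk(c("C", "B"), "y"))),
                   c("A", "B", "C"))
  expect_identical(union_features(list(mk(c("Z", "M"), "x"))), c("M", "Z"))
  expect_length(union_features(list(mk(c("A", "B", "C"), "x"),
                                    mk(c("D", "E", "F", "G"), "y"))), 7L)
})
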