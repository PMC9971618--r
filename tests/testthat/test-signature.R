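test_that("module mean correlation matches construction and the pair oracle", {
  # two perfectly correlated genes
  x <- rbind(g1 = 1:10, g2 = 2 * (1:10) + 1)
  colnames(x) <- sprintf("s%02d", 1:10)
  expect_equal(module_mean_pcc(x, c("g1", "g2")), 1.0)
  # three genes with prescribed pairwise correlations via Cholesky
  target <- matrix(c(1, 0.2, 0.4, 0.2, 1, 0.6, 0.4, 0.6, 1), 3, 3)
  set.seed(91)
  n <- 50
  z <- matrix(rnorm(3 * n), 3, n)
  zc <- z - rowMeans(z)
  zw <- solve(t(chol(cov(t(zc))))) %*% zc   # exactly whitened rows
  y_exact <- t(chol(target)) %*% zw          # exact sample correlation
  rownames(y_exact) <- c("g1", "g2", "g3")
  colnames(y_exact) <- sprintf("s%06d", seq_len(n))
  got <- module_mean_pcc(y_exact, c("g1", "g2", "g3"))
  pair_oracle <- mean(c(cor(y_exact[1, ], y_exact[2, ]),
                        cor(y_exact[1, ], y_exact[3, ]),
                        cor(y_exact[2, ], y_exact[3, ])))
  expect_equal(got, pair_oracle, tolerance = 1e-12)
  expect_equal(got, mean(c(0.2, 0.4, 0.6)), tolerance = 1e-10)
  # independent genes at large n: mean correlation near zero
  set.seed(92)
  indep <- matrix(rnorm(6 * 2000), 6, 2000,
                  dimnames = list(sprintf("i%d", 1:6), NULL))
  expect_lt(abs(module_mean_pcc(indep, rownames(indep))), 0.05)
  expect_error(module_mean_pcc(x, "g1"), "at least two")
})

test_that("the tightest module is elected with declared tie-breaks", {
  set.seed(93)
  x <- rbind(make_block(25, 120, 0.9, "t"), make_block(25, 120, 0.2, "l"))
  mods <- structure(list(list(module_id = "blue",
                              genes = rownames(x)[26:50]),
                         list(module_id = "turquoise",
                              genes = rownames(x)[1:25])),
                    class = "gene_modules")
  win <- elect_signature(x, mods)
  expect_identical(win$module_id, "turquoise")
  expect_gt(win$mean_pcc, 0.8)
  single <- elect_signature(x, mods[2])
  expect_identical(single$module_id, "turquoise")
  # exact tie: the larger module wins
  dup <- rbind(x[1:25, ], x[1:25, ] + 0)
  rownames(dup) <- c(rownames(x)[1:25], paste0("d", 1:25))
  tie_mods <- structure(list(list(module_id = "a", genes = rownames(dup)[1:20]),
                             list(module_id = "b", genes = rownames(dup)[1:25])),
                        class = "gene_modules")
  pa <- module_mean_pcc(dup, tie_mods[[1]]$genes)
  pb <- module_mean_pcc(dup, tie_mods[[2]]$genes)
  if (abs(pa - pb) < 1e-12)
    expect_identical(elect_signature(dup, tie_mods)$module_id, "b")
})

test_that("PAM at zero shrinkage equals the nearest-centroid oracle", {
  set.seed(94)
  x <- matrix(rnorm(2 * 6), 2, 6,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  fit <- pam_train(x, y, delta = 0)
  xtest <- matrix(rnorm(2 * 10), 2, 10,
                  dimnames = list(c("g1", "g2"), sprintf("t%d", 1:10)))
  pred <- pam_predict(fit, xtest)$class
  oracle <- nearest_centroid_oracle(x, y, xtest, fit$s0, fit$prior)
  expect_identical(as.character(pred), as.character(oracle))
})

test_that("shrinkage eliminates genes monotonically", {
  set.seed(95)
  x <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
  x[1:5, 1:10] <- x[1:5, 1:10] + 3
  y <- factor(rep(c("a", "b"), each = 10))
  fit0 <- pam_train(x, y, delta = 0)
  deltas <- seq(0, max(abs(fit0$d)), length.out = 10)
  active <- vapply(deltas, function(dl)
    length(fusemkl:::.pam_shrink(fit0, dl)$active_genes), integer(1))
  expect_true(all(diff(active) <= 0))
  expect_equal(active[1], 30L)
  expect_lt(active[10], 30L)
})

test_that("repeated PAM cross-validation separates planted classes", {
  set.seed(96)
  x <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40)))
  x[, 1:20] <- x[, 1:20] + 2          # strong mean shift on one class
  y <- factor(rep(c("case", "control"), each = 20),
              levels = c("case", "control"))
  names(y) <- colnames(x)
  rep_out <- pam_cv_evaluate(x, y, folds = 5, repeats = 3, seed = 4)
  summ <- rep_out$summary
  expect_gte(summ$mean[summ$metric == "accuracy"], 0.95)
  expect_gte(rep_out$mean_auc, 0.98)
  expect_true(all(summ$mean >= 0 & summ$mean <= 1))
  # metrics recomputed from pooled confusion: accuracy consistent with
  # sensitivity and specificity under equal class sizes
  expect_equal(summ$mean[summ$metric == "accuracy"],
               (summ$mean[summ$metric == "sensitivity"] +
                  summ$mean[summ$metric == "specificity"]) / 2,
               tolerance = 1e-10)

  # permuted labels: chance-level AUC
  set.seed(97)
  yper <- sample(y); names(yper) <- colnames(x)
  null_out <- pam_cv_evaluate(x, yper, folds = 5, repeats = 3, seed = 5)
  expect_gte(null_out$mean_auc, 0.4)
  expect_lte(null_out$mean_auc, 0.6)
})
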