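#' Fit the multi-omics fusion and signature-detection pipeline
#'
#' Runs the full cascade on a list of omics layers sharing samples:
#' per-layer empirical-Bayes screening ([fit_ebayes()], [select_significant()],
#' [union_features()]), penalized non-negative tri-factorization of the
#' relational block system ([build_relational_system()],
#' [fit_trifactorization()]), kernel construction from the reconstructed
#' relations ([kernel_from_reconstruction()], [normalize_and_smooth()]),
#' AUC-driven binary class-label combination search with the soft-margin MKL
#' classifier ([enumerate_combinations()], [score_combination()]),
#' TOM-based module discovery on the winning sub-data ([tom_similarity()],
#' [cut_modules()]) and mean-correlation signature election with repeated
#' PAM cross-validation ([elect_signature()], [pam_cv_evaluate()]).
#'
#' @param layers List of [omics_layer()] objects (the first, or
#'   `expr_layer`, is treated as the gene-expression layer feeding the
#'   co-expression network).
#' @param annot Sample annotation from [sample_annotation()].
#' @param alpha Per-layer significance cutoff.
#' @param adjust Multiple-testing adjustment (`"none"` by default).
#' @param ranks Optional named factorization ranks per object type.
#' @param max_iter,tol Tri-factorization iteration controls.
#' @param window Kernel smoothing window (odd; 1 disables).
#' @param pi,C MKL hyper-parameters.
#' @param folds Cross-validation folds for the label search and PAM.
#' @param repeats PAM evaluation repeats.
#' @param powers,r2_target Soft-threshold power candidates and target fit.
#' @param min_module_size Minimum module size for the tree cut.
#' @param expr_layer Index or name of the expression layer.
#' @param classifier Label-search backend, `"mkl"` or `"pam"`.
#' @param seed Integer seed driving every random component.
#' @return An object of class `fusemkl`; see [print.fusemkl()],
#'   [summary.fusemkl()], [predict.fusemkl()], [plot.fusemkl()] and
#'   [run_report()].
#' @export
fusemkl <- function(layers, annot, alpha = 0.05, adjust = "none",
                    ranks = NULL, max_iter = 300, tol = 1e-6, window = 3,
                    pi = 1, C = 1, folds = 10, repeats = 10,
                    powers = c(1:10, seq(12, 20, 2)), r2_target = 0.8,
                    min_module_size = 20, expr_layer = 1,
                    classifier = c("mkl", "pam"), seed = 1) {
  classifier <- match.arg(classifier)
  cl <- match.call()
  shared <- intersect_samples(layers, annot)
  layers <- shared$layers
  annot <- shared$annot
  if (nlevels(annot) < 2) stop("at least two annotated classes are required")

  # per-layer screening
  clean <- lapply(layers, function(ly)
    zero_mean_normalize(drop_missing_features(ly)))
  stats_list <- lapply(clean, fit_ebayes, annot = annot)
  sig_sets <- Map(function(st, ly) select_significant(st, ly$feature_to_gene,
                                                      alpha = alpha,
                                                      adjust = adjust),
                  stats_list, clean)
  uf <- union_features(sig_sets)
  if (length(uf) < 2) stop("the screened feature union is too small (",
                           length(uf), " gene(s))")

  # fusion
  sys <- build_relational_system(clean, annot, genes = uf)
  fac <- fit_trifactorization(sys, ranks = ranks, max_iter = max_iter,
                              tol = tol, seed = seed)

  # kernels from the reconstructed (feature-space, sample) relations
  data_rel <- Filter(function(r) r$j == "sample", fac$relations)
  kernels <- lapply(data_rel, function(r)
    normalize_and_smooth(kernel_from_reconstruction(t(reconstruct(fac, r$i, "sample"))),
                         window = window))
  names(kernels) <- vapply(data_rel, `[[`, character(1), "i")

  # class-label combination search
  expr_name <- if (is.character(expr_layer)) expr_layer else
    clean[[expr_layer]]$layer_name
  expr_idx <- which(vapply(clean, `[[`, character(1), "layer_name") == expr_name)
  if (!length(expr_idx)) stop("expression layer '", expr_name, "' not found")
  gene_expr <- collapse_to_genes(clean[[expr_idx]], stats_list[[expr_idx]])
  combos <- enumerate_combinations(levels(annot))
  scored <- lapply(combos, function(cb)
    score_combination(cb, kernels, annot, folds = folds, seed = seed,
                      classifier = classifier,
                      expr = gene_expr, pi = pi, C = C))
  best <- best_combination(scored)

  # module discovery on the winning two-group sub-data
  sub_samples <- names(best$labels)
  sub_genes <- intersect(uf, rownames(gene_expr))
  sub_expr <- gene_expr[sub_genes, sub_samples, drop = FALSE]
  sub_expr <- sub_expr[apply(sub_expr, 1, stats::sd) > 0, , drop = FALSE]
  power <- pick_soft_power(sub_expr, powers = powers, r2_target = r2_target)
  X <- adjacency_matrix(sub_expr, power = as.numeric(power))
  tomres <- tom_similarity(X)
  modules <- cut_modules(tomres$dissT, min_module_size = min_module_size)
  validity <- if (length(modules))
    validity_indices(X, tomres$dissT, modules) else NULL
  module_pcc <- vapply(modules, function(m) module_mean_pcc(sub_expr, m),
                       numeric(1))
  names(module_pcc) <- vapply(modules, `[[`, character(1), "module_id")

  # signature election and PAM evaluation
  signature <- elect_signature(sub_expr, modules)
  side <- factor(ifelse(best$labels > 0,
                        paste(best$left, collapse = "+"),
                        paste(best$right, collapse = "+")),
                 levels = c(paste(best$left, collapse = "+"),
                            paste(best$right, collapse = "+")))
  names(side) <- names(best$labels)
  sig_expr <- sub_expr[intersect(signature$genes, rownames(sub_expr)), ,
                       drop = FALSE]
  report <- pam_cv_evaluate(sig_expr, side, folds = folds, repeats = repeats,
                            seed = seed)
  final_pam <- pam_train(sig_expr, side, seed = seed)

  structure(list(call = cl, seed = seed, annot = annot,
                 stats = stats_list, sig_sets = sig_sets, uf = uf,
                 system = sys, factorization = fac, kernels = kernels,
                 combinations = scored, best_combination = best,
                 gene_expr = gene_expr,
                 soft_power = as.numeric(power),
                 power_fit = attr(power, "fit_table"),
                 adjacency = X, tom = tomres, modules = modules,
                 module_pcc = module_pcc, validity = validity,
                 signature = signature, signature_report = report,
                 pam_fit = final_pam, classifier = classifier),
            class = "fusemkl")
}

# collapse a multi-probe layer to one row per gene using the minimum-p
# feature from the moderated statistics (lexicographic tie-break)
collapse_to_genes <- function(layer, stats) {
  g <- layer$feature_to_gene[stats$feature_id]
  ord <- order(stats$p_value, stats$feature_id)
  pick <- ord[!duplicated(g[ord])]
  out <- layer$values[stats$feature_id[pick], , drop = FALSE]
  rownames(out) <- g[pick]
  out[order(rownames(out)), , drop = FALSE]
}

#' @export
print.fusemkl <- function(x, ...) {
  cat("Multi-omics fusion fit (fusemkl)\n")
  cat("  layers:", paste(vapply(x$stats, attr, "", "layer_name"),
                         collapse = ", "), "\n")
  cat("  screened gene union:", length(x$uf), "genes\n")
  cat("  best combination:", x$best_combination$name,
      sprintf("(AUC = %.4f)", x$best_combination$metrics[["auc"]]), "\n")
  cat("  modules:", length(x$modules),
      "| signature:", x$signature$module_id,
      sprintf("(%d genes, mean PCC = %.4f)", length(x$signature$genes),
              x$signature$mean_pcc), "\n")
  cat("  PAM mean AUC:", sprintf("%.4f", x$signature_report$mean_auc), "\n")
  invisible(x)
}

#' Summarize a fitted pipeline
#'
#' @param object A `fusemkl` fit.
#' @param ... Unused.
#' @return A `summary.fusemkl` list with the combination table, module
#'   table, validity indices and the signature evaluation summary.
#' @export
summary.fusemkl <- function(object, ...) {
  per_layer <- data.frame(
    layer = vapply(object$sig_sets, function(s) attr(s, "layer_name"), ""),
    significant_genes = vapply(object$sig_sets, nrow, integer(1)),
    row.names = NULL)
  modtab <- data.frame(
    module = names(object$module_pcc),
    size = vapply(object$modules, function(m) length(m$genes), integer(1)),
    mean_pcc = as.numeric(object$module_pcc), row.names = NULL)
  out <- list(per_layer = per_layer,
              combinations = combination_table(object$combinations),
              best = object$best_combination$name,
              soft_power = object$soft_power,
              modules = modtab,
              unassigned = length(attr(object$modules, "unassigned")),
              validity = object$validity,
              signature = list(module = object$signature$module_id,
                               n_genes = length(object$signature$genes),
                               genes = object$signature$genes,
                               mean_pcc = object$signature$mean_pcc),
              evaluation = object$signature_report$summary)
  class(out) <- "summary.fusemkl"
  out
}

#' @export
print.summary.fusemkl <- function(x, ...) {
  cat("Per-layer significant genes:\n")
  print(x$per_layer, row.names = FALSE)
  cat("\nClass-label combinations (cross-validated):\n")
  print(x$combinations, row.names = FALSE, digits = 4)
  cat("\nBest combination:", x$best, "\n")
  cat("Soft-threshold power:", x$soft_power, "\n\nModules:\n")
  print(x$modules, row.names = FALSE, digits = 4)
  cat("unassigned (grey):", x$unassigned, "genes\n")
  if (!is.null(x$validity)) {
    cat("\nCluster validity indices:\n")
    v <- unlist(x$validity)
    for (nm in names(v)) cat(sprintf("  %-24s %.4f\n", nm, v[nm]))
  }
  cat("\nSignature:", x$signature$module, "-", x$signature$n_genes,
      "genes, mean PCC", sprintf("%.4f", x$signature$mean_pcc), "\n")
  cat("\nPAM cross-validated evaluation:\n")
  print(x$evaluation, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict class membership for new samples from signature genes
#'
#' Applies the final nearest-shrunken-centroids classifier (trained on the
#' winning two-group sub-data) to new expression columns.
#'
#' @param object A `fusemkl` fit.
#' @param newdata Gene-by-sample matrix containing the signature genes.
#' @param type `"class"` or `"posterior"`.
#' @param ... Unused.
#' @return Factor of predicted groups, or the posterior matrix.
#' @export
predict.fusemkl <- function(object, newdata, type = c("class", "posterior"),
                            ...) {
  type <- match.arg(type)
  need <- names(object$pam_fit$xbar)
  missing_genes <- setdiff(need, rownames(newdata))
  if (length(missing_genes))
    stop("newdata lacks ", length(missing_genes), " signature gene(s), e.g. ",
         missing_genes[1])
  pr <- pam_predict(object$pam_fit, newdata[need, , drop = FALSE])
  if (type == "class") pr$class else pr$posterior
}

#' Diagnostic plots for a fitted pipeline
#'
#' Four panels: tri-factorization objective trace, scale-free fit across
#' candidate powers, module dendrogram heights with module sizes, and the
#' per-combination AUC bars.
#'
#' @param x A `fusemkl` fit.
#' @param ... Passed to [graphics::par()].
#' @export
plot.fusemkl <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1), ...)
  on.exit(graphics::par(op))
  tr <- x$factorization$objective_trace
  plot(seq_along(tr) - 1, tr, type = "l", log = "y", xlab = "sweep",
       ylab = "objective", main = "Tri-factorization")
  ft <- x$power_fit
  plot(ft$power, ft$r2, type = "b", xlab = "soft power",
       ylab = expression(R^2), main = "Scale-free fit",
       ylim = c(0, 1))
  graphics::abline(v = x$soft_power, lty = 2)
  sizes <- vapply(x$modules, function(m) length(m$genes), integer(1))
  graphics::barplot(sizes, names.arg = names(x$module_pcc), las = 2,
                    col = names(x$module_pcc), main = "Module sizes",
                    ylab = "genes")
  tab <- combination_table(x$combinations)
  graphics::barplot(tab$auc, names.arg = seq_len(nrow(tab)),
                    ylim = c(0, 1), main = "Combination AUC",
                    xlab = "combination", ylab = "AUC")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Machine-readable run report
#'
#' Collects the quantities a pipeline run prints - the per-combination
#' metric table, cluster validity indices, the signature gene list with its
#' average correlation, and the PAM evaluation means with standard
#' deviations - into one list, optionally written as JSON.
#'
#' @param fit A `fusemkl` fit.
#' @param path Optional JSON output path.
#' @return The report list, invisibly when `path` is given.
#' @export
run_report <- function(fit, path = NULL) {
  s <- summary(fit)
  rep <- list(
    per_layer_significant = s$per_layer,
    combinations = s$combinations,
    best_combination = s$best,
    soft_power = s$soft_power,
    modules = s$modules,
    validity_indices = fit$validity,
    signature = s$signature,
    evaluation = s$evaluation,
    seed = fit$seed)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
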