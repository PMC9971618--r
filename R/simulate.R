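#' Simulation configuration for synthetic multi-omics data
#'
#' Describes a latent gene-by-sample matrix with block-equicorrelated gene
#' modules (each module gene is sqrt(rho) * shared factor + sqrt(1 - rho) *
#' independent noise), a designated signature module whose genes receive a
#' per-class mean shift, and a set of observation layers that each view the
#' latent matrix through per-feature linear maps plus Gaussian noise.
#' Multi-probe genes arise when a layer has `features_per_gene > 1`; one layer
#' may carry missing values at a configured rate (methylation-array style).
#'
#' @param n_per_class Integer vector of samples per class; its length is the
#'   number of classes, its names (optional) the class labels.
#' @param n_genes Total number of genes (module genes plus independent
#'   background genes).
#' @param modules List of `list(size =, rho =)` planted modules, `rho` in
#'   `[0, 1)`.
#' @param signature_module Index into `modules` of the differential module.
#' @param delta Per-class mean shifts added to signature-module genes; a
#'   numeric vector of length `length(n_per_class)` (recycled scalar allowed:
#'   then only the last class is shifted by `delta`).
#' @param layers List of `list(name =, features_per_gene =, noise_sd =)`
#'   observation layers.
#' @param missing_layer Name of the layer receiving missing values (or `NULL`).
#' @param missing_rate Fraction of entries set missing in that layer.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_per_class = c(favorable = 40, intermediate = 40, poor = 40),
                       n_genes = 1000,
                       modules = list(list(size = 60, rho = 0.7),
                                      list(size = 60, rho = 0.5),
                                      list(size = 50, rho = 0.4)),
                       signature_module = 1,
                       delta = 2,
                       layers = list(
                         list(name = "expression", features_per_gene = 1, noise_sd = 0.5),
                         list(name = "methylation", features_per_gene = 2, noise_sd = 0.7)),
                       missing_layer = "methylation",
                       missing_rate = 0.002) {
  stopifnot(length(n_per_class) >= 2, all(n_per_class >= 2), n_genes >= 1)
  for (m in modules)
    if (m$size < 2 || m$rho < 0 || m$rho >= 1)
      stop("module sizes must be >= 2 and rho in [0, 1)")
  if (sum(vapply(modules, `[[`, numeric(1), "size")) > n_genes)
    stop("module sizes exceed n_genes")
  if (signature_module < 1 || signature_module > length(modules))
    stop("signature_module out of range")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (is.null(names(n_per_class)))
    names(n_per_class) <- paste0("class", seq_along(n_per_class))
  if (length(delta) == 1) {
    delta <- c(rep(0, length(n_per_class) - 1), delta)
  }
  if (length(delta) != length(n_per_class))
    stop("delta must have one shift per class")
  structure(list(n_per_class = n_per_class, n_genes = n_genes,
                 modules = modules, signature_module = signature_module,
                 delta = delta, layers = layers,
                 missing_layer = missing_layer, missing_rate = missing_rate),
            class = "sim_config")
}

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `layers` (list of [omics_layer()]), `annot` (sample
#'   annotation factor), and `truth` (list with `modules`: named list of gene
#'   vectors, `signature_genes`, `shifted_class`, `latent`: the gene-level
#'   matrix).
#' @export
simulate_multiomics <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- sum(cfg$n_per_class)
  classes <- rep(names(cfg$n_per_class), cfg$n_per_class)
  sample_ids <- sprintf("S%03d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  latent <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                   dimnames = list(genes, sample_ids))
  sizes <- vapply(cfg$modules, `[[`, numeric(1), "size")
  starts <- cumsum(c(1, utils::head(sizes, -1)))
  truth_modules <- list()
  for (k in seq_along(cfg$modules)) {
    rows <- seq(starts[k], length.out = sizes[k])
    rho <- cfg$modules[[k]]$rho
    fac <- stats::rnorm(n)
    latent[rows, ] <- sqrt(rho) * matrix(fac, sizes[k], n, byrow = TRUE) +
      sqrt(1 - rho) * latent[rows, ]
    truth_modules[[paste0("module", k)]] <- genes[rows]
  }
  sig_rows <- seq(starts[cfg$signature_module],
                  length.out = sizes[cfg$signature_module])
  for (cl in seq_along(cfg$n_per_class)) {
    if (cfg$delta[cl] != 0) {
      cols <- which(classes == names(cfg$n_per_class)[cl])
      latent[sig_rows, cols] <- latent[sig_rows, cols] + cfg$delta[cl]
    }
  }

  layers <- lapply(cfg$layers, function(ly) {
    fpg <- ly$features_per_gene
    feat_gene <- rep(genes, each = fpg)
    feature_ids <- if (fpg == 1) genes else
      paste0(feat_gene, "_", ly$name, rep(seq_len(fpg), times = cfg$n_genes))
    loading <- stats::runif(length(feature_ids), 0.5, 1.5)
    vals <- latent[feat_gene, , drop = FALSE] * loading +
      matrix(stats::rnorm(length(feature_ids) * n, sd = ly$noise_sd),
             length(feature_ids), n)
    rownames(vals) <- feature_ids
    if (!is.null(cfg$missing_layer) && identical(ly$name, cfg$missing_layer) &&
        cfg$missing_rate > 0) {
      nmiss <- round(cfg$missing_rate * length(vals))
      if (nmiss > 0) vals[sample(length(vals), nmiss)] <- NA_real_
    }
    omics_layer(vals, ly$name,
                feature_to_gene = stats::setNames(feat_gene, feature_ids))
  })
  names(layers) <- vapply(cfg$layers, `[[`, character(1), "name")

  shifted <- names(cfg$n_per_class)[which(cfg$delta != 0)]
  list(layers = layers,
       annot = sample_annotation(stats::setNames(classes, sample_ids)),
       truth = list(modules = truth_modules,
                    signature_genes = genes[sig_rows],
                    shifted_class = shifted,
                    latent = latent))
}
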