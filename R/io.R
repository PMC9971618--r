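#' Construct an omics layer
#'
#' An `omics_layer` holds one platform's features-by-samples matrix together
#' with its identifiers and an optional feature-to-gene map. Pathway-activity
#' and copy-number layers are typically already gene-keyed, in which case the
#' map defaults to the identity.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row and
#'   column names are used as identifiers when `feature_ids`/`sample_ids` are
#'   not given.
#' @param layer_name Single string naming the layer (e.g. `"expression"`).
#' @param feature_ids,sample_ids Character vectors of unique identifiers.
#' @param feature_to_gene Named character vector mapping feature id to gene
#'   symbol, or `NULL` for the identity map.
#' @return An object of class `omics_layer`.
#' @export
omics_layer <- function(values, layer_name,
                        feature_ids = rownames(values),
                        sample_ids = colnames(values),
                        feature_to_gene = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("layer '", layer_name, "': values must be numeric")
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("layer '", layer_name, "': feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids) || ncol(values) != length(sample_ids))
    stop("layer '", layer_name, "': matrix dimensions do not match identifier counts")
  if (anyDuplicated(feature_ids))
    stop("layer '", layer_name, "': duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("layer '", layer_name, "': duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  if (is.null(feature_to_gene)) {
    feature_to_gene <- stats::setNames(feature_ids, feature_ids)
  } else {
    feature_to_gene <- stats::setNames(as.character(feature_to_gene),
                                       names(feature_to_gene))
    missing_map <- setdiff(feature_ids, names(feature_to_gene))
    # unmapped features map to themselves
    if (length(missing_map))
      feature_to_gene <- c(feature_to_gene,
                           stats::setNames(missing_map, missing_map))
    feature_to_gene <- feature_to_gene[feature_ids]
  }
  structure(list(layer_name = layer_name,
                 values = values,
                 feature_ids = feature_ids,
                 sample_ids = sample_ids,
                 feature_to_gene = feature_to_gene),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat("<omics_layer> ", x$layer_name, ": ",
      length(x$feature_ids), " features x ", length(x$sample_ids), " samples",
      if (n_miss) paste0(" (", n_miss, " missing)"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

.detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited omics matrix
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' The delimiter is taken from the file extension (`.csv` is comma, anything
#' else tab) unless `sep` is given. Empty strings, `NA` and `NaN` tokens are
#' recorded as missing values; they are removed later by
#' [drop_missing_features()].
#'
#' @param path Path to the matrix file.
#' @param mapping_path Optional path to a two-column (feature_id, gene)
#'   delimited file; when absent, features map to themselves.
#' @param layer_name Layer name; defaults to the file name without extension.
#' @param sep Field delimiter override.
#' @return An [omics_layer()].
#' @export
read_omics_layer <- function(path, mapping_path = NULL, layer_name = NULL,
                             sep = NULL) {
  sep <- .detect_sep(path, sep)
  if (is.null(layer_name))
    layer_name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", "", "NaN"), quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) stop("file '", path, "': needs a feature-id column plus data")
  feature_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("file '", path, "': duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("file '", path, "': non-numeric value '", body[bad[1, 1], bad[1, 2]],
         "' at feature '", feature_ids[bad[1, 1]], "', sample '",
         sample_ids[bad[1, 2]], "'")
  }
  mapping <- if (!is.null(mapping_path)) read_feature_mapping(mapping_path) else NULL
  omics_layer(structure(num, dimnames = list(feature_ids, sample_ids)),
              layer_name = layer_name, feature_to_gene = mapping)
}

#' Write an omics layer as delimited text
#'
#' Full-precision round-trip companion of [read_omics_layer()].
#'
#' @param layer An [omics_layer()].
#' @param path Output path; extension picks the delimiter as in reading.
#' @param sep Delimiter override.
#' @export
write_omics_layer <- function(layer, path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  df <- data.frame(feature_id = layer$feature_ids,
                   format(layer$values, digits = 17, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("feature_id", layer$sample_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column feature-to-gene mapping table
#'
#' @param path Delimited file whose first two columns are feature id and gene
#'   symbol (header optional, detected by a non-duplicated first line).
#' @param sep Delimiter override.
#' @return Named character vector (names are feature ids).
#' @export
read_feature_mapping <- function(path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2) stop("mapping file '", path, "' needs two columns")
  stats::setNames(tab[[2]], tab[[1]])
}

#' Read a sample annotation (sample id to class label)
#'
#' @param path Delimited file whose first two columns are sample id and class
#'   label, with a header row.
#' @param sep Delimiter override.
#' @return Named factor of class labels, names are sample ids.
#' @export
read_sample_annotation <- function(path, sep = NULL) {
  sep <- .detect_sep(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2) stop("annotation file '", path, "' needs two columns")
  if (anyDuplicated(tab[[1]]))
    stop("annotation file '", path, "': duplicate sample id")
  sample_annotation(stats::setNames(tab[[2]], tab[[1]]))
}

#' Construct a sample annotation
#'
#' @param labels Named vector (names are sample ids) of class labels.
#' @return Named factor with at least one class level.
#' @export
sample_annotation <- function(labels) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("sample labels must be uniquely named by sample id")
  f <- factor(as.character(labels))
  names(f) <- names(labels)
  f
}

#' Restrict layers and annotation to their common samples
#'
#' All layers are subset to the lexicographically sorted intersection of every
#' layer's samples and the annotated samples, so downstream matrices share one
#' deterministic sample ordering.
#'
#' @param layers List of [omics_layer()] objects.
#' @param annot Named factor from [sample_annotation()].
#' @return List with elements `layers` (same length, common samples) and
#'   `annot` (restricted, ordered to match).
#' @export
intersect_samples <- function(layers, annot) {
  if (!length(layers)) stop("at least one layer is required")
  common <- Reduce(intersect, lapply(layers, `[[`, "sample_ids"),
                   names(annot))
  if (!length(common)) stop("no samples are shared across layers and annotation")
  common <- sort(common)
  layers <- lapply(layers, function(ly) {
    omics_layer(ly$values[, common, drop = FALSE], ly$layer_name,
                feature_to_gene = ly$feature_to_gene)
  })
  ann <- annot[common]
  ann <- factor(ann, levels = levels(annot)[levels(annot) %in% unique(as.character(ann))])
  names(ann) <- common
  list(layers = layers, annot = ann)
}
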