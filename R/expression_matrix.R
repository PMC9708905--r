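#' Construct a feature-by-sample expression matrix with sample metadata
#'
#' The container used by all statistical stages: a numeric matrix of
#' log-scale expression values (rows = features, columns = samples) plus a
#' per-sample metadata table. Validation enforces unique feature identifiers,
#' column/metadata agreement, and the presence of a concentration-0 (vehicle)
#' sample in every cell system.
#'
#' @param values Numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample_id`, `concentration` (micromolar, non-negative), `cell_system`
#'   (character/factor), and optionally `time` and `replicate`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `sample_meta`.
#' @export
expression_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(sample_meta))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("feature ids (rownames) must be present and unique")
  if (!all(c("sample_id", "concentration", "cell_system") %in% names(sample_meta)))
    stop("sample_meta needs columns sample_id, concentration, cell_system")
  if (ncol(values) != nrow(sample_meta))
    stop("column count (", ncol(values), ") != sample_meta rows (",
         nrow(sample_meta), ")")
  if (is.null(colnames(values))) colnames(values) <- sample_meta$sample_id
  if (!identical(colnames(values), as.character(sample_meta$sample_id)))
    stop("colnames(values) must match sample_meta$sample_id in order")
  if (any(sample_meta$concentration < 0))
    stop("concentrations must be non-negative")
  has_vehicle <- tapply(sample_meta$concentration, sample_meta$cell_system,
                        function(x) any(x == 0))
  if (!all(has_vehicle))
    stop("cell system(s) without a concentration-0 vehicle sample: ",
         paste(names(has_vehicle)[!has_vehicle], collapse = ", "))
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "features x", ncol(x$values),
      "samples\n")
  cat("  cell systems:", paste(unique(x$sample_meta$cell_system),
                               collapse = ", "), "\n")
  cat("  concentrations (uM):",
      paste(sort(unique(x$sample_meta$concentration)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
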