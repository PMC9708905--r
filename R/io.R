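#' Read and write the plain-text formats used by the pipeline
#'
#' All interchange is tab-separated text: expression matrices (features x
#' samples with an `feature_id` first column), sample metadata, GMT gene set
#' collections, SIF signed networks, regulon tables, and SMILES lists.
#'
#' @param path File path.
#' @name sysphar-io
NULL

#' @rdname sysphar-io
#' @param em An [expression_matrix()].
#' @param meta_path Path for the sample metadata TSV.
#' @export
write_expression_matrix <- function(em, path, meta_path) {
  dt <- data.table::data.table(feature_id = rownames(em$values))
  dt <- cbind(dt, data.table::as.data.table(em$values))
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(em$sample_meta, meta_path, sep = "\t")
  invisible(c(path, meta_path))
}

#' @rdname sysphar-io
#' @export
read_expression_matrix <- function(path, meta_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  values <- as.matrix(dt[, -1])
  rownames(values) <- dt[[1]]
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t", header = TRUE))
  expression_matrix(values, meta)
}

#' @rdname sysphar-io
#' @param collection Named list of character vectors (gene sets); an optional
#'   `description` attribute (named character) fills the GMT second column.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname sysphar-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "description") <- setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' @rdname sysphar-io
#' @param edges data.frame with columns `source`, `sign` (+1/-1), `target`.
#' @export
write_sif <- function(edges, path) {
  rel <- ifelse(edges$sign > 0, "activates", "inhibits")
  if (nrow(edges) == 0L) {
    writeLines(character(0), path)
  } else {
    data.table::fwrite(
      data.table::data.table(source = edges$source, relation = rel,
                             target = edges$target),
      path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' @rdname sysphar-io
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(source = character(0), sign = integer(0),
                      target = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("SIF lines must have 3 tab-separated fields")
  rel <- vapply(parts, `[[`, character(1), 2L)
  sgn <- ifelse(rel %in% c("activates", "+1", "1"), 1L,
                ifelse(rel %in% c("inhibits", "-1"), -1L, NA_integer_))
  if (anyNA(sgn)) stop("unknown SIF relation(s): ",
                       paste(unique(rel[is.na(sgn)]), collapse = ", "))
  data.frame(source = vapply(parts, `[[`, character(1), 1L),
             sign = sgn,
             target = vapply(parts, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' @rdname sysphar-io
#' @param regulons data.frame with columns `tf`, `target`, `mode` (+1/-1)
#'   and `weight` in (0, 1].
#' @export
write_regulons <- function(regulons, path) {
  data.table::fwrite(regulons, path, sep = "\t")
  invisible(path)
}

#' @rdname sysphar-io
#' @export
read_regulons <- function(path) {
  reg <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_regulons(reg)
}

validate_regulons <- function(reg) {
  stopifnot(all(c("tf", "target", "mode") %in% names(reg)))
  if (!all(reg$mode %in% c(-1L, 1L))) stop("regulon modes must be +1/-1")
  if (is.null(reg$weight)) reg$weight <- 1
  if (any(reg$weight <= 0 | reg$weight > 1)) stop("weights must be in (0, 1]")
  if (anyDuplicated(reg[, c("tf", "target")]))
    stop("duplicate (tf, target) pairs in regulons")
  reg
}

#' @rdname sysphar-io
#' @param smiles Named character vector of SMILES strings.
#' @export
write_smiles_file <- function(smiles, path) {
  nm <- names(smiles)
  if (is.null(nm)) nm <- paste0("mol", seq_along(smiles))
  writeLines(paste(smiles, nm, sep = "\t"), path)
  invisible(path)
}

#' @rdname sysphar-io
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1L)
  names(smi) <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else paste0("mol", i)
  }, character(1))
  smi
}

#' @rdname sysphar-io
#' @param library A `signature_library` (see [gen_signature_library()]).
#' @export
write_signature_library <- function(library, path, meta_path) {
  dt <- data.table::data.table(gene_id = library$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(library$values))
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(library$signature_meta, meta_path, sep = "\t")
  invisible(c(path, meta_path))
}

#' @rdname sysphar-io
#' @export
read_signature_library <- function(path, meta_path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  values <- as.matrix(dt[, -1])
  rownames(values) <- dt[[1]]
  meta <- as.data.frame(data.table::fread(meta_path, sep = "\t", header = TRUE))
  signature_library(values, meta)
}

#' Construct a perturbagen signature library
#'
#' @param values Numeric matrix, measured genes x signatures, with rownames
#'   (gene ids) and colnames (signature ids).
#' @param signature_meta data.frame with columns `signature_id`,
#'   `perturbagen_id`, `condition`, one row per column of `values`.
#' @return Object of class `signature_library`.
#' @export
signature_library <- function(values, signature_meta) {
  stopifnot(is.matrix(values), is.data.frame(signature_meta))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids (rownames) must be present and unique")
  need <- c("signature_id", "perturbagen_id", "condition")
  if (!all(need %in% names(signature_meta)))
    stop("signature_meta needs columns ", paste(need, collapse = ", "))
  if (ncol(values) != nrow(signature_meta))
    stop("signature count mismatch with metadata")
  if (is.null(colnames(values))) colnames(values) <- signature_meta$signature_id
  if (!identical(colnames(values), as.character(signature_meta$signature_id)))
    stop("colnames(values) must match signature_meta$signature_id")
  if (anyNA(signature_meta$perturbagen_id))
    stop("every signature needs a perturbagen_id")
  structure(list(values = values, gene_ids = rownames(values),
                 signature_meta = signature_meta),
            class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat("signature_library:", nrow(x$values), "genes x", ncol(x$values),
      "signatures,", length(unique(x$signature_meta$perturbagen_id)),
      "perturbagens\n")
  invisible(x)
}
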