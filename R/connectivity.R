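#' Restrict a query signature and a library to their common gene universe
#'
#' Genes are intersected and both sides are returned in the library's gene
#' order. Mirrors the matching of a microarray-derived query against a
#' library measuring a fixed gene panel.
#'
#' @param query Named numeric vector of per-gene scores (e.g. dose-response
#'   t-statistics).
#' @param library A [signature_library()].
#' @param min_common Minimum overlap before a warning is raised (default 100).
#' @return List with `query` (aligned vector), `values` (aligned library
#'   matrix), `n_common`.
#' @export
match_genes <- function(query, library, min_common = 100) {
  stopifnot(inherits(library, "signature_library"),
            is.numeric(query), !is.null(names(query)))
  common <- library$gene_ids[library$gene_ids %in% names(query)]
  if (length(common) == 0L) stop("empty gene intersection")
  if (length(common) < min_common)
    warning("only ", length(common), " genes in common (minimum ",
            min_common, ")")
  list(query = query[common],
       values = library$values[common, , drop = FALSE],
       n_common = length(common))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank). Constant input after ranking yields a flagged `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` with attribute `flagged = TRUE`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(structure(NA_real_, flagged = TRUE))
  cor(rx, ry)
}

#' Score every library signature against the query by Spearman correlation
#'
#' @param matched Output of [match_genes()] (gene-aligned query + library).
#' @return Named numeric vector, one rho per signature (`NA` for constant
#'   signatures, excluded downstream with a report).
#' @export
score_library <- function(matched) {
  rq <- rank(matched$query)
  rv <- apply(matched$values, 2L, rank)
  const <- apply(rv, 2L, function(r) all(r == r[1L]))
  rho <- suppressWarnings(drop(cor(rq, rv)))
  rho[const] <- NA_real_
  names(rho) <- colnames(matched$values)
  rho
}

#' Collapse per-signature scores to the best condition per perturbagen
#'
#' A perturbagen usually appears under several conditions; the comparison
#' with the highest Spearman correlation is retained. Ties are broken by the
#' lexicographically smallest condition label. `NA` scores are dropped with
#' a report (attribute `n_dropped`).
#'
#' @param rho Named numeric vector of per-signature scores.
#' @param signature_meta data.frame with `signature_id`, `perturbagen_id`,
#'   `condition`.
#' @return data.frame `perturbagen`, `best_rho`, `best_condition`.
#' @export
collapse_best <- function(rho, signature_meta) {
  m <- signature_meta[match(names(rho), signature_meta$signature_id), ]
  if (anyNA(m$perturbagen_id)) stop("signature(s) without a perturbagen_id")
  ok <- !is.na(rho)
  n_dropped <- sum(!ok)
  d <- data.frame(perturbagen = m$perturbagen_id[ok],
                  condition = m$condition[ok], rho = rho[ok],
                  stringsAsFactors = FALSE)
  d <- d[order(d$perturbagen, -d$rho, d$condition), ]
  best <- d[!duplicated(d$perturbagen), ]
  out <- data.frame(perturbagen = best$perturbagen, best_rho = best$rho,
                    best_condition = best$condition,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Empirical null pool of best-per-perturbagen connectivity scores
#'
#' Runs `n_random` random signatures through the full scoring pipeline
#' ([score_library()] + [collapse_best()]) and pools all resulting
#' best-per-perturbagen correlations. Random signatures are uniform
#' permutations of the actual query values (preserving its marginal
#' distribution); `method = "gaussian"` draws standard normal values instead.
#'
#' @param query Named numeric query vector (only its values and length drive
#'   the permutation null).
#' @param library A [signature_library()].
#' @param n_random Number of random signatures (default 100).
#' @param seed Integer seed.
#' @param method `"permute"` (default) or `"gaussian"`.
#' @return Numeric vector of length `n_random * n_perturbagens`.
#' @export
empirical_null <- function(query, library, n_random = 100, seed = 1,
                           method = c("permute", "gaussian")) {
  method <- match.arg(method)
  stopifnot(n_random >= 1)
  matched <- match_genes(query, library, min_common = 0)
  n <- length(matched$query)
  rq <- rank(matched$query)
  Q <- with_seed(child_seed(seed, "connectivity_null"), {
    if (method == "permute")
      vapply(seq_len(n_random), function(b) rq[sample.int(n)], numeric(n))
    else
      vapply(seq_len(n_random), function(b) rank(rnorm(n)), numeric(n))
  })
  rv <- apply(matched$values, 2L, rank)
  rho <- t(suppressWarnings(cor(rv, Q)))   # random queries x signatures
  pert <- library$signature_meta$perturbagen_id[
    match(colnames(matched$values), library$signature_meta$signature_id)]
  groups <- split(seq_len(ncol(rho)), pert)
  pool <- unlist(lapply(groups, function(ix) {
    if (length(ix) == 1L) rho[, ix]
    else do.call(pmax, as.data.frame(rho[, ix, drop = FALSE]))
  }), use.names = FALSE)
  pool[!is.na(pool)]
}

#' One-sided empirical p-value against a null pool
#'
#' `p = (1 + #\{pool >= best_rho\}) / (1 + pool size)`; a perturbagen is
#' retained when `p <= threshold`. With the +1 pseudocount, retention at the
#' default 0.001 requires a pool of at least 999 values; a smaller pool
#' triggers a warning.
#'
#' @param best_rho Numeric vector of observed best-per-perturbagen scores.
#' @param null_pool Numeric vector from [empirical_null()].
#' @param threshold Retention threshold (default 0.001).
#' @return data.frame `best_rho`, `empirical_p`, `retained`.
#' @export
empirical_p <- function(best_rho, null_pool, threshold = 0.001) {
  if (length(null_pool) == 0L) stop("empty null pool")
  if ((1 / (1 + length(null_pool))) > threshold)
    warning("null pool of ", length(null_pool),
            " cannot reach p <= ", threshold)
  pool <- sort(null_pool)
  n_ge <- length(pool) - findInterval(best_rho, pool, left.open = TRUE)
  p <- (1 + n_ge) / (1 + length(pool))
  data.frame(best_rho = best_rho, empirical_p = p,
             retained = p <= threshold)
}

#' Top connectivity hits
#'
#' Retained perturbagens sorted by decreasing best correlation, truncated to
#' `k` (ties broken by perturbagen id).
#'
#' @param results A connectivity result table (see [run_connectivity()]).
#' @param k Number of hits to keep (default 15).
#' @return The leading rows of `results`.
#' @export
top_hits <- function(results, k = 15) {
  stopifnot(nrow(results) >= 0)
  kept <- results[results$retained, , drop = FALSE]
  kept <- kept[order(-kept$best_rho, kept$perturbagen), , drop = FALSE]
  head(kept, k)
}

#' Full connectivity analysis of a query signature against a library
#'
#' Gene matching, per-signature Spearman scoring, best-condition collapse,
#' empirical permutation null, and one-sided empirical p-values.
#'
#' @inheritParams match_genes
#' @inheritParams empirical_null
#' @inheritParams empirical_p
#' @return data.frame of class `connectivity_result`: `perturbagen`,
#'   `best_rho`, `best_condition`, `empirical_p`, `retained`; attributes
#'   `n_common` and `null_pool`.
#' @export
run_connectivity <- function(query, library, n_random = 100, threshold = 0.001,
                             seed = 1, min_common = 100,
                             method = c("permute", "gaussian")) {
  matched <- match_genes(query, library, min_common = min_common)
  rho <- score_library(matched)
  best <- collapse_best(rho, library$signature_meta)
  pool <- empirical_null(query, library, n_random = n_random, seed = seed,
                         method = method)
  ep <- empirical_p(best$best_rho, pool, threshold = threshold)
  out <- cbind(best, ep[, c("empirical_p", "retained")])
  attr(out, "n_common") <- matched$n_common
  attr(out, "null_pool") <- pool
  class(out) <- c("connectivity_result", "data.frame")
  out
}
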