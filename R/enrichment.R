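#' Rank genes by their concentration-response t-statistic
#'
#' Produces the decreasing-t ranked list consumed by [gsea()] and
#' [score_library()]. Ties are broken lexicographically by gene id so the
#' ordering is deterministic across platforms. Features flagged `degenerate`
#' with a non-zero slope (perfect noiseless fits, see [fit_dose_response()])
#' have no finite t-statistic; they are placed beyond the finite extremes on
#' the side of their slope sign, ordered among themselves by `|beta1|`.
#'
#' @param stats A `dose_response_stats` data.frame.
#' @return data.frame of class `ranked_list` with columns `gene_id`, `score`
#'   (the ranking statistic, non-increasing).
#' @export
rank_genes <- function(stats) {
  stopifnot(is.data.frame(stats), all(c("feature", "t_stat") %in% names(stats)))
  if (anyDuplicated(stats$feature)) stop("duplicate gene ids")
  score <- stats$t_stat
  if (!is.null(stats$degenerate) && !is.null(stats$beta1)) {
    deg <- stats$degenerate & stats$beta1 != 0 & !is.na(stats$beta1)
    if (any(deg)) {
      finite_max <- if (all(deg)) 0 else max(abs(score[!deg]), na.rm = TRUE)
      b <- abs(stats$beta1[deg])
      bmax <- max(b)
      score[deg] <- sign(stats$beta1[deg]) *
        (finite_max + 1 + b / if (bmax > 0) bmax else 1)
    }
  }
  if (any(!is.finite(score))) stop("non-finite ranking statistics")
  o <- order(-score, stats$feature)
  out <- data.frame(gene_id = stats$feature[o], score = score[o],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom keeping a running sum that
#' increases by `|score|^weight_exponent / sum_hits |score|^weight_exponent`
#' at members of the gene set ("hits") and decreases by `1 / (N - |S|)` at
#' non-members. The enrichment score (ES) is the maximum-magnitude deviation
#' of this running sum from zero; when the positive and negative extremes
#' tie in magnitude (within 1e-9 relative) the positive one is taken. The
#' leading edge is the hits at or before (after, for negative ES) the
#' extreme.
#'
#' If every hit has score exactly 0 (so the hit weights sum to 0 under a
#' positive exponent), equal hit weights are used instead.
#'
#' @param ranked A `ranked_list` (or named numeric vector, decreasing).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Non-negative real; 0 gives the classic unweighted
#'   KS statistic, 1 (default) the standard weighted form.
#' @return List with `es`, `running_sum` (length N), `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  rl <- as_ranked(ranked)
  stopifnot(weight_exponent >= 0)
  hit <- rl$gene_id %in% gene_set
  k <- sum(hit)
  N <- nrow(rl)
  if (k == 0L) stop("gene set has empty intersection with the ranked universe")
  if (k == N) stop("gene set covers the whole ranked universe")
  w <- abs(rl$score)^weight_exponent
  w[!hit] <- 0
  tot <- sum(w[hit])
  if (tot == 0) { w[hit] <- 1; tot <- k }
  running <- cumsum(ifelse(hit, w / tot, -1 / (N - k)))
  es <- pick_extreme(max(running), min(running))
  i_max <- if (es >= 0) which.max(running) else which.min(running)
  leading <- if (es >= 0) rl$gene_id[seq_len(i_max)][hit[seq_len(i_max)]]
             else rl$gene_id[i_max:N][hit[i_max:N]]
  list(es = es, running_sum = running, leading_edge = leading)
}

as_ranked <- function(ranked) {
  if (inherits(ranked, "ranked_list")) return(ranked)
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    if (is.unsorted(rev(ranked))) stop("scores must be non-increasing")
    return(structure(data.frame(gene_id = names(ranked),
                                score = unname(ranked),
                                stringsAsFactors = FALSE),
                     class = c("ranked_list", "data.frame")))
  }
  stop("ranked must be a ranked_list or a named, non-increasing numeric vector")
}

# ES from sorted hit positions only: O(k) once the weight cumsums exist.
# pos must be sorted ascending; w = |score|^alpha over the whole list.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  hw <- w[pos]
  tot <- sum(hw)
  if (tot == 0) { hw <- rep(1, k); tot <- k }
  cum_hit <- cumsum(hw) / tot
  miss_at <- (pos - seq_len(k)) / (N - k)       # misses strictly before hit i
  top <- cum_hit - miss_at                      # running sum at each hit
  bottom <- c(0, cum_hit[-k]) - miss_at         # just before each hit
  # between consecutive hits the sum only drifts down linearly, so every
  # extreme is at a hit (top), just before a hit (bottom), or at the final
  # position, where the sum is exactly 0
  cand <- c(top, bottom, 0)
  pick_extreme(max(cand), min(cand))
}

# ES tie rule: the maximum-magnitude deviation; when the positive and
# negative extremes tie in magnitude (within 1e-9 relative, which also
# absorbs floating-point accumulation differences), the positive extreme is
# preferred. Documented so independent implementations can agree exactly.
pick_extreme <- function(mx, mn) {
  scale <- max(abs(mx), abs(mn), .Machine$double.xmin)
  if (abs(mx) >= abs(mn) - 1e-9 * scale) mx else mn
}

#' Gene set enrichment analysis with a gene-permutation null
#'
#' For every gene set of admissible size, computes the weighted KS enrichment
#' score on the ranked list, then a size-matched null from `n_permutations`
#' random same-size gene subsets (the null depends only on set size, so sets
#' of equal size share one null pool). The normalized enrichment score is
#' `NES = ES / mean(|null ES of the same sign|)`; the nominal p-value is
#' one-sided within the sign class with a +1 pseudocount; FDR follows the
#' sign-stratified ratio method (fraction of pooled null NES at least as
#' extreme over fraction of observed NES at least as extreme, capped at 1).
#'
#' @param ranked A `ranked_list`.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param n_permutations Integer >= 100.
#' @param weight_exponent Non-negative real, default 1.
#' @param seed Integer seed; fixed seed gives identical results.
#' @param min_size,max_size Admissible intersection sizes (defaults 5, 500).
#' @return data.frame of class `enrichment_result` with columns `set`,
#'   `size_used`, `es`, `nes`, `p_nominal`, `fdr` and a `leading_edge` list
#'   column; skipped sets are recorded in attribute `skipped`.
#' @export
gsea <- function(ranked, collection, n_permutations = 1000,
                 weight_exponent = 1, seed = 1, min_size = 5, max_size = 500) {
  rl <- as_ranked(ranked)
  stopifnot(n_permutations >= 100)
  N <- nrow(rl)
  w <- abs(rl$score)^weight_exponent
  idx <- seq_len(N)
  names(idx) <- rl$gene_id
  inter <- lapply(collection, function(s) unname(idx[names(idx) %in% s]))
  sizes <- lengths(inter)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  skipped <- names(collection)[!keep]
  if (!any(keep)) {
    warning("no gene sets within size bounds")
    out <- data.frame(set = character(0), size_used = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_nominal = numeric(0), fdr = numeric(0))
    out$leading_edge <- list()
    attr(out, "skipped") <- skipped
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  inter <- inter[keep]
  sizes <- sizes[keep]
  set_names <- names(collection)[keep]

  uniq_sizes <- sort(unique(sizes))
  nulls <- with_seed(seed, {
    lapply(setNames(uniq_sizes, uniq_sizes), function(k) {
      vapply(seq_len(n_permutations), function(b) {
        es_from_positions(sort.int(sample.int(N, k)), w, N)
      }, numeric(1))
    })
  })

  es <- vapply(inter, function(pos) es_from_positions(sort.int(pos), w, N),
               numeric(1))
  nes <- p_nom <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nl <- nulls[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) nl[nl >= 0] else nl[nl < 0]
    opp_mean_pos <- mean(abs(nl[nl >= 0]))
    opp_mean_neg <- mean(abs(nl[nl < 0]))
    denom <- if (es[i] >= 0) opp_mean_pos else opp_mean_neg
    nes[i] <- if (length(same) > 0 && denom > 0) es[i] / denom else NA_real_
    p_nom[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    nn <- nl
    nn[nl >= 0] <- nl[nl >= 0] / if (is.finite(opp_mean_pos) && opp_mean_pos > 0)
      opp_mean_pos else NA_real_
    nn[nl < 0] <- nl[nl < 0] / if (is.finite(opp_mean_neg) && opp_mean_neg > 0)
      opp_mean_neg else NA_real_
    null_nes[[i]] <- nn
  }
  pooled_null <- unlist(null_nes, use.names = FALSE)
  pooled_null <- pooled_null[is.finite(pooled_null)]
  fdr <- vapply(seq_along(nes), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pooled_null[pooled_null >= 0] >= nes[i])
      den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[i])
    } else {
      num <- mean(pooled_null[pooled_null < 0] <= nes[i])
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[i])
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  leading <- lapply(seq_along(inter), function(i) {
    enrichment_score(rl, rl$gene_id[inter[[i]]], weight_exponent)$leading_edge
  })
  out <- data.frame(set = set_names, size_used = as.integer(sizes),
                    es = es, nes = nes, p_nominal = p_nom, fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- leading
  out <- out[order(-out$nes, out$set), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @rdname sysphar-io
#' @param result An `enrichment_result`.
#' @export
write_enrichment <- function(result, path) {
  dt <- data.table::as.data.table(result[, setdiff(names(result), "leading_edge")])
  dt$leading_edge <- vapply(result$leading_edge, paste, character(1),
                            collapse = ",")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
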