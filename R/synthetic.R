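#' Configuration for the synthetic multi-omics world
#'
#' Defaults encode the study design the pipeline targets: four cell systems
#' treated at 0, 100, 200, 300, 400 micromolar with replicates, log2-scale
#' expression, a minority of genes responding linearly to concentration.
#' Slopes default to 0.002-0.008 log2 units per micromolar (a 0.8-3.2 log2
#' fold change at the 400 micromolar top dose) and residual noise to 0.25
#' log2 units, typical microarray scatter.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_cell_systems Number of cell systems (default 4).
#' @param concentrations Treatment concentrations in micromolar; must
#'   contain 0 (vehicle) and at least 2 distinct values (default
#'   `c(0, 100, 200, 300, 400)`).
#' @param replicates_per_condition Replicates per cell system x
#'   concentration (default 3).
#' @param n_responders Genes with a non-zero planted slope (default 50).
#' @param slope_range Interval the responder slopes are drawn from,
#'   expression units per micromolar (default `c(0.002, 0.008)`).
#' @param noise_sd Residual Gaussian noise SD (default 0.25).
#' @param seed Integer seed (default 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_cell_systems = 4,
                       concentrations = c(0, 100, 200, 300, 400),
                       replicates_per_condition = 3, n_responders = 50,
                       slope_range = c(0.002, 0.008), noise_sd = 0.25,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cell_systems = as.integer(n_cell_systems),
              concentrations = as.numeric(concentrations),
              replicates_per_condition = as.integer(replicates_per_condition),
              n_responders = as.integer(n_responders),
              slope_range = as.numeric(slope_range),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_cell_systems < 1 ||
      cfg$replicates_per_condition < 1)
    stop("configuration error: counts must be positive")
  if (length(cfg$concentrations) == 0L || any(cfg$concentrations < 0))
    stop("configuration error: concentrations must be non-negative")
  if (!0 %in% cfg$concentrations || length(unique(cfg$concentrations)) < 2L)
    stop("configuration error: concentrations must contain 0 and >= 2 ",
         "distinct values")
  if (cfg$n_responders < 0 || cfg$n_responders > cfg$n_genes)
    stop("configuration error: n_responders must be in [0, n_genes]")
  if (length(cfg$slope_range) != 2L || cfg$slope_range[1] > cfg$slope_range[2])
    stop("configuration error: slope_range must be an interval")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic expression matrix with planted dose-response genes
#'
#' Each gene's value is `beta0(gene, cell) + beta1(gene) * concentration +
#' eps`, with `eps ~ N(0, noise_sd)` i.i.d. Responder genes draw `beta1`
#' uniformly from `slope_range`; all other genes have slope 0. Baselines
#' `beta0` are drawn once per gene x cell system (uniform 4-12 log2 units),
#' so the cell-system covariate genuinely matters in the combined model.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `ground_truth`
#'   (list with `true_slopes`, `responder_set`).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  cells <- sprintf("cs%d", seq_len(config$n_cell_systems))
  with_seed(child_seed(config$seed, "expression"), {
    responders <- sort(sample(genes, config$n_responders))
    slopes <- setNames(rep(0, config$n_genes), genes)
    slopes[responders] <- runif(config$n_responders,
                                config$slope_range[1], config$slope_range[2])
    beta0 <- matrix(runif(config$n_genes * config$n_cell_systems, 4, 12),
                    nrow = config$n_genes,
                    dimnames = list(genes, cells))
    meta <- expand.grid(replicate = seq_len(config$replicates_per_condition),
                        concentration = config$concentrations,
                        cell_system = cells,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$time <- "6h"
    meta$sample_id <- sprintf("%s_c%g_r%d", meta$cell_system,
                              meta$concentration, meta$replicate)
    meta <- meta[, c("sample_id", "cell_system", "concentration", "time",
                     "replicate")]
    values <- beta0[, meta$cell_system, drop = FALSE] +
      outer(slopes, meta$concentration) +
      if (config$noise_sd > 0)
        matrix(rnorm(config$n_genes * nrow(meta), sd = config$noise_sd),
               nrow = config$n_genes) else 0
    colnames(values) <- meta$sample_id
    list(matrix = expression_matrix(values, meta),
         ground_truth = list(true_slopes = slopes,
                             responder_set = responders))
  })
}

#' Generate a gene set collection with planted enriched sets
#'
#' Planted sets draw at least 80% of their members from the responder set
#' (slope signs concordant: members come from responders whose planted
#' slope shares the majority sign), the remainder uniformly from the rest;
#' background sets draw uniformly from all genes.
#'
#' @param genes Character vector, the gene universe.
#' @param n_sets Number of sets.
#' @param set_size_range Integer interval for set sizes (default c(10, 30)).
#' @param planted_fraction Fraction of sets that are planted enriched, in
#'   `[0, 1]` (default 0.1).
#' @param ground_truth Ground-truth list from [gen_expression()] (needs
#'   `true_slopes` and `responder_set`).
#' @param seed Integer seed.
#' @param responder_share Minimum share of planted-set members drawn from
#'   responders (default 0.8).
#' @return Named list of gene sets (GMT-compatible) with attribute
#'   `ground_truth` (list with `planted_gene_sets`).
#' @export
gen_gene_sets <- function(genes, n_sets = 50, set_size_range = c(10, 30),
                          planted_fraction = 0.1, ground_truth = NULL,
                          seed = 1, responder_share = 0.8) {
  if (planted_fraction < 0 || planted_fraction > 1)
    stop("planted_fraction must be in [0, 1]")
  if (max(set_size_range) > length(genes))
    stop("set sizes cannot exceed the gene universe")
  n_planted <- round(planted_fraction * n_sets)
  responders <- ground_truth$responder_set
  slopes <- ground_truth$true_slopes
  if (n_planted > 0 && length(responders) == 0L)
    stop("cannot plant enriched sets without responders in ground_truth")
  with_seed(child_seed(seed, "gene_sets"), {
    if (n_planted > 0) {
      sgn <- sign(slopes[responders])
      major <- if (sum(sgn > 0) >= sum(sgn < 0)) 1 else -1
      pool <- responders[sgn == major]
    }
    size_pool <- seq(set_size_range[1], set_size_range[2])
    sets <- lapply(seq_len(n_sets), function(i) {
      k <- if (length(size_pool) == 1L) size_pool else sample(size_pool, 1L)
      if (i <= n_planted) {
        k_resp <- min(ceiling(responder_share * k), length(pool))
        members <- sample(pool, k_resp)
        extra <- sample(setdiff(genes, members), k - k_resp)
        sort(c(members, extra))
      } else {
        sort(sample(genes, k))
      }
    })
    names(sets) <- sprintf("GS_%04d", seq_len(n_sets))
    attr(sets, "ground_truth") <-
      list(planted_gene_sets = names(sets)[seq_len(n_planted)])
    sets
  })
}

#' Generate a perturbagen signature library with planted mimics
#'
#' Non-mimic signatures are independent standard-normal draws over the gene
#' universe. Each mimic perturbagen gets one signature built by blending the
#' query's rank order with independent noise; the mixing weight is
#' calibrated by bisection until the achieved Spearman correlation with the
#' query is within `tol` of the target (targets must lie in (-1, 1);
#' exactly 1 uses the query's own rank order).
#'
#' @param n_perturbagens Number of perturbagens.
#' @param conditions_per_perturbagen Conditions (signatures) each (default 2).
#' @param query_direction Named numeric query vector over the library's gene
#'   universe (its names define the library genes).
#' @param mimic_spec Named numeric vector: perturbagen id -> target Spearman
#'   rho (ids are assigned among the first perturbagens if not of the form
#'   `pert0001`...). Default none.
#' @param seed Integer seed.
#' @param tol Calibration tolerance on the achieved rho (default 0.01,
#'   well inside the contracted 0.05).
#' @return List with `library` (a [signature_library()]) and `ground_truth`
#'   (list `mimic_perturbagens`: named achieved rho).
#' @export
gen_signature_library <- function(n_perturbagens, conditions_per_perturbagen = 2,
                                  query_direction, mimic_spec = numeric(0),
                                  seed = 1, tol = 0.01) {
  stopifnot(is.numeric(query_direction), !is.null(names(query_direction)))
  if (length(mimic_spec) > 0) {
    if (any(mimic_spec <= -1 | mimic_spec > 1))
      stop("mimic target correlations must lie in (-1, 1] ")
    if (length(mimic_spec) > n_perturbagens)
      stop("more mimics than perturbagens")
  }
  genes <- names(query_direction)
  n_genes <- length(genes)
  perts <- sprintf("pert%04d", seq_len(n_perturbagens))
  if (length(mimic_spec) > 0 && is.null(names(mimic_spec)))
    names(mimic_spec) <- perts[seq_along(mimic_spec)]
  if (length(mimic_spec) > 0 && !all(names(mimic_spec) %in% perts))
    stop("mimic_spec names must be perturbagen ids (pertNNNN)")
  with_seed(child_seed(seed, "library"), {
    meta <- expand.grid(condition = sprintf("cond%d",
                                            seq_len(conditions_per_perturbagen)),
                        perturbagen_id = perts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$signature_id <- paste(meta$perturbagen_id, meta$condition, sep = ":")
    meta <- meta[, c("signature_id", "perturbagen_id", "condition")]
    values <- matrix(rnorm(n_genes * nrow(meta)), nrow = n_genes,
                     dimnames = list(genes, meta$signature_id))
    achieved <- setNames(numeric(length(mimic_spec)), names(mimic_spec))
    rq <- rank(query_direction)
    for (p in names(mimic_spec)) {
      target <- mimic_spec[[p]]
      col <- meta$signature_id[meta$perturbagen_id == p][1L]
      if (target == 1) {
        values[, col] <- rq          # monotone transform of the query
        achieved[p] <- 1
        next
      }
      noise <- rnorm(n_genes)
      blend_rho <- function(w) {
        v <- w * scale(rq)[, 1] + (1 - w) * scale(noise)[, 1]
        cor(rank(v), rq)
      }
      lo <- if (target >= 0) 0 else -1
      hi <- if (target >= 0) 1 else 0
      for (it in seq_len(60)) {
        mid <- (lo + hi) / 2
        r <- blend_rho(mid)
        if (abs(r - target) <= tol / 2) break
        if (r < target) lo <- mid else hi <- mid
      }
      w <- (lo + hi) / 2
      values[, col] <- w * scale(rq)[, 1] + (1 - w) * scale(noise)[, 1]
      achieved[p] <- cor(rank(values[, col]), rq)
      if (abs(achieved[p] - target) > 5 * tol)
        warning("mimic ", p, " calibrated to ", round(achieved[p], 3),
                " (target ", target, ")")
    }
    list(library = signature_library(values, meta),
         ground_truth = list(mimic_perturbagens = achieved))
  })
}

#' Generate a prior knowledge network with a planted signed causal path
#'
#' Builds a spine of `path_length` signed edges from the perturbation node
#' `PERT` through intermediates to a junction, attaches each of the `n_tfs`
#' TFs to the junction with a random signed edge, and fills the remaining
#' nodes with distractors wired at `edge_density`. Distractor edges never
#' point into planted-path or TF nodes, so the planted path is the unique
#' optimal explanation of the TF signs and an exact solver must recover it.
#' Each TF sign equals the product of edge signs along its path. Each TF
#' receives a regulon of at least `regulon_size` targets whose modes are
#' consistent with its sign (mode x TF sign = +1 for targets expected to go
#' up).
#'
#' @param n_nodes Total node count (>= path_length + n_tfs + 1).
#' @param edge_density Probability of each admissible distractor edge
#'   (default 0.15).
#' @param path_length Number of edges from the perturbation to each TF
#'   (>= 1, < n_nodes).
#' @param n_tfs Number of measured TFs (default 3).
#' @param genes Gene universe the regulons draw targets from.
#' @param seed Integer seed.
#' @param regulon_size Targets per TF (default 5).
#' @return List with `network` (a [pkn()]), `regulons` (data.frame), and
#'   `ground_truth` (`active_path`: ordered signed node list;
#'   `active_tfs`: named signs).
#' @export
gen_pkn <- function(n_nodes, edge_density = 0.15, path_length = 3, n_tfs = 3,
                    genes = sprintf("g%04d", 1:200), seed = 1,
                    regulon_size = 5) {
  stopifnot(path_length >= 1, path_length < n_nodes)
  n_inter <- path_length - 1L
  if (n_nodes < 1L + n_inter + n_tfs)
    stop("n_nodes too small for the requested path and TF count")
  with_seed(child_seed(seed, "pkn"), {
    pert <- "PERT"
    inters <- if (n_inter > 0) sprintf("I%02d", seq_len(n_inter)) else character(0)
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    n_distract <- n_nodes - 1L - n_inter - n_tfs
    distract <- if (n_distract > 0) sprintf("D%02d", seq_len(n_distract))
                else character(0)
    spine <- c(pert, inters)
    spine_signs <- sample(c(-1L, 1L), length(spine) - 1L + 0L, replace = TRUE)
    edges <- NULL
    if (length(spine) > 1L) {
      edges <- data.frame(source = spine[-length(spine)],
                          sign = spine_signs,
                          target = spine[-1L], stringsAsFactors = FALSE)
    }
    junction <- spine[length(spine)]
    spine_prod <- if (length(spine) > 1L) prod(spine_signs) else 1L
    tf_edge_signs <- sample(c(-1L, 1L), n_tfs, replace = TRUE)
    edges <- rbind(edges,
                   data.frame(source = junction, sign = tf_edge_signs,
                              target = tfs, stringsAsFactors = FALSE))
    tf_signs <- setNames(as.integer(spine_prod * tf_edge_signs), tfs)
    # distractor edges: any ordered pair whose target is a distractor, plus
    # path/TF -> distractor; never into the planted path or TFs
    protected <- c(spine, tfs)
    all_nodes <- c(protected, distract)
    if (length(distract) > 0) {
      cand <- expand.grid(source = all_nodes, target = distract,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      cand <- cand[cand$source != cand$target, ]
      pick <- runif(nrow(cand)) < edge_density
      if (any(pick)) {
        extra <- data.frame(source = cand$source[pick],
                            sign = sample(c(-1L, 1L), sum(pick), replace = TRUE),
                            target = cand$target[pick],
                            stringsAsFactors = FALSE)
        edges <- rbind(edges, extra)
      }
    }
    network <- pkn(edges)
    # nodes with no edges would be dropped by pkn(); keep isolated distractors
    network$nodes <- sort(unique(c(network$nodes, all_nodes)))
    # modes consistent with the TF sign: for positively-responding target
    # genes, mode = tf sign makes the mode-adjusted activity carry that sign
    regulons <- do.call(rbind, lapply(tfs, function(tf) {
      targets <- sample(genes, regulon_size)
      data.frame(tf = tf, target = targets,
                 mode = rep(tf_signs[[tf]], regulon_size),
                 weight = 1, stringsAsFactors = FALSE)
    }))
    path_nodes <- c(spine, tfs[1L])
    path_signs <- cumprod(c(1L, if (length(spine) > 1L) spine_signs else NULL,
                            tf_edge_signs[1L]))
    list(network = network,
         regulons = regulons,
         ground_truth = list(
           active_path = setNames(as.integer(path_signs), path_nodes),
           spine = spine,
           active_tfs = tf_signs))
  })
}

#' Built-in panel of small organic molecules
#'
#' A fixed set of valid SMILES spanning chains, rings, aromatics and
#' heteroatoms, including a tetrahydropyridine-pyridine bicyclic scaffold
#' (anatabine-like) and the closely related pyrrolidine-pyridine alkaloids
#' nicotine and nornicotine, which form the planted near-duplicate pair for
#' similarity tests.
#'
#' @return Named character vector of SMILES strings.
#' @export
gen_molecules <- function() {
  c(anatabine_like = "C1C=CC(NC1)c1cccnc1",
    nicotine_like = "CN1CCCC1c1cccnc1",
    nornicotine_like = "C1CCC(N1)c1cccnc1",
    pyridine = "c1ccncc1",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1",
    aniline = "Nc1ccccc1",
    piperidine = "C1CCNCC1",
    cyclohexane = "C1CCCCC1",
    hexane = "CCCCCC",
    ethanol = "CCO",
    acetic_acid = "CC(=O)O",
    acetamide = "CC(=O)N")
}
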