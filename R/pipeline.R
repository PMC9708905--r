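#' Default pipeline configuration
#'
#' Returns the full configuration list (versioned schema) used by
#' [run_pipeline()]. Stage toggles, stage parameters, input paths (ignored
#' for stages being simulated) and the global seed. Values can be
#' overridden by a JSON config file ([read_pipeline_config()]) or by
#' arguments.
#'
#' @param seed Global seed (default 1).
#' @param out_dir Output directory.
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1, out_dir = "sysphar_run") {
  structure(list(
    schema_version = 1L,
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, dose = TRUE, gsea = TRUE,
                  connect = TRUE, network = TRUE, chem = TRUE),
    simulate = list(n_genes = 400, n_cell_systems = 2,
                    concentrations = c(0, 100, 200, 300, 400),
                    replicates_per_condition = 3, n_responders = 40,
                    slope_range = c(0.002, 0.008), noise_sd = 0.25,
                    n_sets = 40, set_size_range = c(10, 25),
                    planted_fraction = 0.1,
                    n_perturbagens = 60, conditions_per_perturbagen = 2,
                    mimic_rhos = c(0.6, 0.49, 0.4),
                    pkn_nodes = 12, pkn_density = 0.15, path_length = 3,
                    n_tfs = 3, regulon_size = 5),
    dose = list(adjust_for_cell_system = TRUE),
    gsea = list(n_permutations = 500, weight_exponent = 1,
                min_size = 5, max_size = 500),
    connect = list(n_random = 100, threshold = 0.001, min_common = 100),
    network = list(n_permutations = 500, k_top = 10, beta = NULL,
                   perturbation_sign = 1),
    chem = list(reference = "anatabine_like",
                descriptors = c("PathFp", "SphereFp", "FragFP"))
  ), class = "pipeline_config")
}

#' @rdname default_pipeline_config
#' @param path JSON config file; missing fields fall back to defaults.
#' @export
read_pipeline_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  cfg <- utils::modifyList(cfg, user)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order (simulate, dose,
#' \{gsea, connect\} in either order, network; chem independent), writing
#' every intermediate as TSV/GMT/SIF/JSON under `out_dir` plus a manifest
#' with the package version, all child seeds and per-file MD5 checksums.
#' Identical config + seed reproduces byte-identical outputs.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]).
#' @param seed Optional override of `config$seed`.
#' @param out_dir Optional override of `config$out_dir`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)
  st <- config$stages
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (isTRUE(st$simulate)) run_stage("simulate", {
    sp <- config$simulate
    cfg <- sim_config(n_genes = sp$n_genes, n_cell_systems = sp$n_cell_systems,
                      concentrations = sp$concentrations,
                      replicates_per_condition = sp$replicates_per_condition,
                      n_responders = sp$n_responders,
                      slope_range = sp$slope_range, noise_sd = sp$noise_sd,
                      seed = config$seed)
    sim <- gen_expression(cfg)
    write_expression_matrix(sim$matrix, od("expression.tsv"),
                            od("sample_meta.tsv"))
    genes <- rownames(sim$matrix$values)
    sets <- gen_gene_sets(genes, n_sets = sp$n_sets,
                          set_size_range = sp$set_size_range,
                          planted_fraction = sp$planted_fraction,
                          ground_truth = sim$ground_truth, seed = config$seed)
    write_gmt(sets, od("gene_sets.gmt"))
    # query for the library: true slopes as a noiseless direction
    stats0 <- fit_dose_response(sim$matrix,
                                adjust_for_cell_system = sp$n_cell_systems > 1)
    query <- setNames(stats0$t_stat, stats0$feature)
    mimics <- setNames(sp$mimic_rhos,
                       sprintf("pert%04d", seq_along(sp$mimic_rhos)))
    lib <- gen_signature_library(sp$n_perturbagens,
                                 sp$conditions_per_perturbagen,
                                 query_direction = query, mimic_spec = mimics,
                                 seed = config$seed)
    write_signature_library(lib$library, od("library.tsv"),
                            od("library_meta.tsv"))
    net <- gen_pkn(sp$pkn_nodes, sp$pkn_density, sp$path_length, sp$n_tfs,
                   genes = sim$ground_truth$responder_set, seed = config$seed,
                   regulon_size = sp$regulon_size)
    write_sif(net$network$edges, od("pkn.sif"))
    write_regulons(net$regulons, od("regulons.tsv"))
    write_smiles_file(gen_molecules(), od("molecules.smi"))
    # named vectors become JSON objects (not bare arrays) via as.list
    truth <- list(true_slopes = as.list(sim$ground_truth$true_slopes),
                  responder_set = sim$ground_truth$responder_set,
                  planted_gene_sets =
                    attr(sets, "ground_truth")$planted_gene_sets,
                  mimic_perturbagens =
                    as.list(lib$ground_truth$mimic_perturbagens),
                  active_path = as.list(net$ground_truth$active_path),
                  active_tfs = as.list(net$ground_truth$active_tfs))
    jsonlite::write_json(truth, od("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  if (isTRUE(st$dose)) run_stage("dose", {
    em <- read_expression_matrix(od("expression.tsv"), od("sample_meta.tsv"))
    stats <- fit_dose_response(
      em, adjust_for_cell_system = isTRUE(config$dose$adjust_for_cell_system) &&
        length(unique(em$sample_meta$cell_system)) > 1)
    data.table::fwrite(stats, od("dose_response.tsv"), sep = "\t")
  })

  if (isTRUE(st$gsea)) run_stage("gsea", {
    stats <- as.data.frame(data.table::fread(od("dose_response.tsv")))
    sets <- read_gmt(od("gene_sets.gmt"))
    res <- gsea(rank_genes(stats), sets,
                n_permutations = config$gsea$n_permutations,
                weight_exponent = config$gsea$weight_exponent,
                seed = child_seed(config$seed, "gsea"),
                min_size = config$gsea$min_size,
                max_size = config$gsea$max_size)
    write_enrichment(res, od("enrichment.tsv"))
  })

  if (isTRUE(st$connect)) run_stage("connect", {
    stats <- as.data.frame(data.table::fread(od("dose_response.tsv")))
    lib <- read_signature_library(od("library.tsv"), od("library_meta.tsv"))
    query <- setNames(stats$t_stat, stats$feature)
    res <- run_connectivity(query, lib,
                            n_random = config$connect$n_random,
                            threshold = config$connect$threshold,
                            seed = child_seed(config$seed, "connect"),
                            min_common = config$connect$min_common)
    data.table::fwrite(res, od("connectivity.tsv"), sep = "\t")
    data.table::fwrite(top_hits(res), od("top_hits.tsv"), sep = "\t")
  })

  if (isTRUE(st$network)) run_stage("network", {
    stats <- as.data.frame(data.table::fread(od("dose_response.tsv")))
    network <- pkn(read_sif(od("pkn.sif")))
    regulons <- read_regulons(od("regulons.tsv"))
    act <- tf_activity(stats, regulons,
                       n_permutations = config$network$n_permutations,
                       seed = child_seed(config$seed, "network"),
                       k_top = config$network$k_top)
    data.table::fwrite(act, od("tf_activity.tsv"), sep = "\t")
    sel <- act[act$selected, ]
    sel <- sel[sel$tf %in% network$nodes, ]
    inst <- build_ilp(network, "PERT",
                      perturbation_sign = config$network$perturbation_sign,
                      tf_measurements = setNames(sel$sign, sel$tf),
                      mismatch_weights = setNames(abs(sel$z_score), sel$tf),
                      node_penalty = config$network$beta)
    sols <- solve_ilp(inst)
    inferred <- aggregate_solutions(sols)
    export_network(inferred, od("network.sif"), od("network_nodes.tsv"))
    jsonlite::write_json(list(objective = inferred$objective,
                              n_solutions = inferred$n_solutions,
                              solutions = lapply(sols$solutions, as.list)),
                         od("network_solutions.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  if (isTRUE(st$chem)) run_stage("chem", {
    smi <- read_smiles_file(od("molecules.smi"))
    mols <- lapply(smi, parse_smiles)
    ref <- config$chem$reference
    if (!ref %in% names(mols))
      stop("reference molecule '", ref, "' not in panel")
    dist <- similarity_matrix(mols, mols[[ref]],
                              descriptors = config$chem$descriptors)
    data.table::fwrite(dist, od("chem_distances.tsv"), sep = "\t")
  })

  files <- sort(list.files(config$out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "sysphar",
    version = as.character(utils::packageVersion("sysphar")),
    seed = config$seed,
    child_seeds = list(
      expression = child_seed(config$seed, "expression"),
      gene_sets = child_seed(config$seed, "gene_sets"),
      library = child_seed(config$seed, "library"),
      pkn = child_seed(config$seed, "pkn"),
      gsea = child_seed(config$seed, "gsea"),
      connect = child_seed(config$seed, "connect"),
      network = child_seed(config$seed, "network")),
    files = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' One-command synthetic demonstration run
#'
#' Runs the full pipeline on synthetic data with planted ground truth:
#' planted gene sets should top the enrichment table, planted mimics the
#' connectivity table, and the planted signed path should be recovered by
#' the network stage.
#'
#' @param out_dir Output directory (default `"sysphar_demo"`).
#' @param seed Global seed (default 1).
#' @return Invisibly, the run manifest.
#' @export
pipeline_demo <- function(out_dir = "sysphar_demo", seed = 1) {
  run_pipeline(default_pipeline_config(seed = seed, out_dir = out_dir))
}
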