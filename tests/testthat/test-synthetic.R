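test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(concentrations = numeric(0)), "configuration error")
  expect_error(sim_config(concentrations = c(100, 200)), "contain 0")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_responders = 50, n_genes = 10), "n_responders")
  expect_error(sim_config(slope_range = c(2, 1)), "interval")
})

test_that("zero-noise expression lies exactly on its line and refits exactly", {
  cfg <- sim_config(n_genes = 20, n_cell_systems = 2, n_responders = 1,
                    slope_range = c(0.005, 0.005), noise_sd = 0,
                    replicates_per_condition = 2, seed = 4)
  sim <- gen_expression(cfg)
  truth <- sim$ground_truth
  g <- truth$responder_set
  expect_equal(unname(truth$true_slopes[g]), 0.005)
  st <- fit_dose_response(sim$matrix)
  expect_equal(st$beta1[st$feature == g], 0.005, tolerance = 1e-9)
  expect_equal(max(abs(st$beta1[st$feature != g])), 0, tolerance = 1e-9)
  # every sample value sits exactly on its cell-system line
  meta <- sim$matrix$sample_meta
  v <- sim$matrix$values[g, ]
  for (cs in unique(meta$cell_system)) {
    sel <- meta$cell_system == cs
    fit <- lm(v[sel] ~ meta$concentration[sel])
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
})

test_that("n_responders = 0 gives all-zero true slopes", {
  cfg <- sim_config(n_genes = 15, n_responders = 0, seed = 6,
                    replicates_per_condition = 1, n_cell_systems = 1)
  sim <- gen_expression(cfg)
  expect_true(all(sim$ground_truth$true_slopes == 0))
  expect_equal(sim$ground_truth$responder_set, character(0))
})

test_that("fixed seed reproduces bit-identical outputs", {
  cfg <- sim_config(n_genes = 30, n_responders = 10, seed = 12)
  expect_identical(gen_expression(cfg), gen_expression(cfg))
  g1 <- gen_pkn(10, seed = 3, genes = paste0("g", 1:20))
  g2 <- gen_pkn(10, seed = 3, genes = paste0("g", 1:20))
  expect_identical(g1, g2)
  q <- setNames(rnorm(50), paste0("g", 1:50))
  expect_identical(gen_signature_library(5, 2, q, seed = 2),
                   gen_signature_library(5, 2, q, seed = 2))
})

test_that("fitted slopes are unbiased over Monte-Carlo responders", {
  # 200 planted responders, heavy noise, few replicates: the mean fitted
  # slope must sit within 2 Monte-Carlo SEs of the planted mean
  cfg <- sim_config(n_genes = 200, n_cell_systems = 1, n_responders = 200,
                    replicates_per_condition = 2, noise_sd = 1, seed = 7)
  sim <- gen_expression(cfg)
  st <- fit_dose_response(sim$matrix, adjust_for_cell_system = FALSE)
  truth <- sim$ground_truth$true_slopes[st$feature]
  err <- st$beta1 - truth
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 2 * se + 1e-12)
})

test_that("gen_gene_sets: planted membership, sizes, and validation", {
  cfg <- sim_config(n_genes = 100, n_responders = 40, seed = 9)
  sim <- gen_expression(cfg)
  genes <- names(sim$ground_truth$true_slopes)
  sets <- gen_gene_sets(genes, n_sets = 10, set_size_range = c(5, 5),
                        planted_fraction = 0.3,
                        ground_truth = sim$ground_truth, seed = 9)
  expect_true(all(lengths(sets) == 5))
  planted <- attr(sets, "ground_truth")$planted_gene_sets
  expect_length(planted, 3)
  for (nm in planted) {
    share <- mean(sets[[nm]] %in% sim$ground_truth$responder_set)
    expect_gte(share, 0.8)
  }
  none <- gen_gene_sets(genes, n_sets = 5, planted_fraction = 0,
                        ground_truth = sim$ground_truth, seed = 9)
  expect_length(attr(none, "ground_truth")$planted_gene_sets, 0)
  expect_error(gen_gene_sets(genes, planted_fraction = 2,
                             ground_truth = sim$ground_truth), "\\[0, 1\\]")
  expect_error(gen_gene_sets(genes[1:3], set_size_range = c(5, 5),
                             ground_truth = sim$ground_truth), "universe")
})

test_that("mimic calibration hits its targets within tolerance", {
  q <- withr::with_seed(14, setNames(rnorm(400), paste0("g", 1:400)))
  lib <- gen_signature_library(10, 2, q,
                               mimic_spec = c(pert0001 = 1.0,
                                              pert0002 = 0.49,
                                              pert0003 = -0.3),
                               seed = 15)
  ach <- lib$ground_truth$mimic_perturbagens
  expect_equal(unname(ach["pert0001"]), 1)
  # exact-1 mimic is a monotone transform of the query
  col <- lib$library$values[, "pert0001:cond1"]
  expect_equal(cor(rank(col), rank(q)), 1)
  expect_equal(unname(ach["pert0002"]), 0.49, tolerance = 0.05)
  expect_equal(unname(ach["pert0003"]), -0.3, tolerance = 0.05)
  expect_error(gen_signature_library(2, 1, q, mimic_spec = c(a = 1.5)),
               "target correlations")
  q_bad <- setNames(rnorm(10), paste0("h", 1:10))
  r <- gen_signature_library(3, 1, q_bad, seed = 1)
  expect_equal(nrow(r$library$values), 10)
})

test_that("non-mimic best scores match the null pool distribution", {
  q <- withr::with_seed(31, setNames(rnorm(300), paste0("g", 1:300)))
  lib <- gen_signature_library(250, 2, q, seed = 32)   # zero mimics
  observed <- collapse_best(
    score_library(match_genes(q, lib$library, min_common = 10)),
    lib$library$signature_meta)$best_rho
  pool <- empirical_null(q, lib$library, n_random = 2, seed = 33)
  ks <- suppressWarnings(ks.test(observed, pool))
  expect_gt(ks$p.value, 0.01)
})

test_that("gen_molecules panel is valid and has aromatic ring systems", {
  panel <- gen_molecules()
  expect_gte(length(panel), 10)
  mols <- lapply(panel, parse_smiles)
  expect_true(any(vapply(mols, function(m)
    sum(m$atoms$aromatic & m$atoms$in_ring) >= 6, logical(1))))
})

test_that("child_seed is deterministic, component-sensitive, in range", {
  expect_identical(child_seed(1, "expression"), child_seed(1, "expression"))
  expect_false(child_seed(1, "expression") == child_seed(1, "library"))
  expect_false(child_seed(1, "pkn") == child_seed(2, "pkn"))
  for (s in c(0, 1, 7, 2^30, 123456789))
    expect_true(child_seed(s, "x") > 0 && child_seed(s, "x") < 2^31)
})
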