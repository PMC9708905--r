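chain_pkn <- function(signs) {
  # P -> A -> T chain with the given edge signs
  nodes <- c("P", if (length(signs) > 1) paste0("A", seq_len(length(signs) - 1)),
             "T")
  pkn(data.frame(source = nodes[-length(nodes)], sign = signs,
                 target = nodes[-1], stringsAsFactors = FALSE))
}

test_that("tf_activity: mode-adjusted means and planted TF ranking", {
  st <- data.frame(feature = c("g1", "g2", "g3"), t_stat = c(2, -2, 0.5))
  reg1 <- data.frame(tf = "T1", target = "g1", mode = 1L, weight = 1)
  act1 <- tf_activity(st, reg1, n_permutations = 200, seed = 1, k_top = 1)
  expect_equal(act1$raw_score, 2)
  reg2 <- data.frame(tf = "T1", target = c("g1", "g2"), mode = c(1L, -1L),
                     weight = 1)
  act2 <- tf_activity(st, reg2, n_permutations = 200, seed = 1, k_top = 1)
  expect_equal(act2$raw_score, 2)

  # planted: one TF with strongly concordant targets among noise genes
  set.seed(30)
  stats <- data.frame(feature = paste0("g", 1:100),
                      t_stat = c(rep(8, 5), rnorm(95)))
  regs <- rbind(
    data.frame(tf = "ACTIVE", target = paste0("g", 1:5), mode = 1L, weight = 1),
    data.frame(tf = "IDLE", target = paste0("g", 50:54), mode = 1L, weight = 1))
  act <- tf_activity(stats, regs, n_permutations = 500, seed = 2, k_top = 1)
  expect_equal(act$tf[1], "ACTIVE")
  expect_true(act$selected[act$tf == "ACTIVE"])
  expect_equal(attr(act, "skipped"), character(0))
  reg_missing <- rbind(regs, data.frame(tf = "GHOST", target = "nope",
                                        mode = 1L, weight = 1))
  act3 <- tf_activity(stats, reg_missing, n_permutations = 200, seed = 2)
  expect_equal(attr(act3, "skipped"), "GHOST")
})

test_that("sign composition along planted chains", {
  net_pp <- chain_pkn(c(1L, 1L))
  inst <- build_ilp(net_pp, "P", 1, tf_measurements = c(T = 1))
  sols <- solve_ilp(inst)
  st <- sols$solutions[[1]]
  expect_equal(unname(st["T"]), 1L)
  net_pm <- chain_pkn(c(1L, -1L))
  sols2 <- solve_ilp(build_ilp(net_pm, "P", 1, tf_measurements = c(T = -1)))
  expect_equal(unname(sols2$solutions[[1]]["T"]), -1L)
})

test_that("3-node activating chain: all up, zero mismatch, objective 3*beta", {
  net <- chain_pkn(c(1L, 1L))
  inst <- build_ilp(net, "P", 1, tf_measurements = c(T = 1),
                    mismatch_weights = c(T = 1), node_penalty = 0.1)
  sols <- solve_ilp(inst)
  expect_length(sols$solutions, 1)
  expect_equal(sols$objective, 0.3, tolerance = 1e-12)
  expect_equal(sols$solutions[[1]], c(A1 = 1L, P = 1L, T = 1L)[names(sols$solutions[[1]])])
})

test_that("inhibiting edge with fixed-up perturbation costs the mismatch", {
  net <- pkn(data.frame(source = "P", sign = -1L, target = "T"))
  inst <- build_ilp(net, "P", 1, tf_measurements = c(T = 1),
                    mismatch_weights = c(T = 2), node_penalty = 0.1)
  sols <- solve_ilp(inst)
  expect_equal(sols$objective, 2 + 0.1, tolerance = 1e-12)
  expect_equal(unname(sols$solutions[[1]]["T"]), 0L)
  # free perturbation sign resolves it by going down
  inst_f <- build_ilp(net, "P", "free", tf_measurements = c(T = 1),
                      mismatch_weights = c(T = 2), node_penalty = 0.1)
  sols_f <- solve_ilp(inst_f)
  expect_equal(sols_f$objective, 0.2, tolerance = 1e-12)
  expect_equal(unname(sols_f$solutions[[1]]["P"]), -1L)
  expect_equal(unname(sols_f$solutions[[1]]["T"]), 1L)
})

test_that("two symmetric parallel paths give two optimal solutions", {
  net <- pkn(data.frame(source = c("P", "P", "A", "B"),
                        sign = 1L,
                        target = c("A", "B", "T", "T")))
  inst <- build_ilp(net, "P", 1, tf_measurements = c(T = 1),
                    mismatch_weights = c(T = 1), node_penalty = 0.1)
  sols <- solve_ilp(inst)
  expect_length(sols$solutions, 2)
  expect_length(solve_ilp(inst, enumerate_cap = 1)$solutions, 1)
  agg <- aggregate_solutions(sols)
  vals <- setNames(agg$nodes$value, agg$nodes$id)
  expect_equal(unname(vals[c("P", "T")]), c(100L, 100L))
  expect_equal(unname(vals[c("A", "B")]), c(50L, 50L))
})

test_that("aggregate_solutions: single solution, partial use, cancellation", {
  net <- chain_pkn(1L)   # P -> T
  inst <- build_ilp(net, "P", 1, tf_measurements = c(T = 1))
  agg1 <- aggregate_solutions(solve_ilp(inst))
  expect_equal(agg1$nodes$value[agg1$nodes$id == "T"], 100L)
  # cancellation: fake two opposite solutions through the internal structure
  sols <- solve_ilp(inst)
  sols$solutions <- list(c(P = 1L, T = 1L), c(P = 1L, T = -1L))
  agg2 <- aggregate_solutions(sols)
  expect_equal(agg2$nodes$value[agg2$nodes$id == "T"], 0L)
})

test_that("build_ilp validates inputs and warns on unreachable TFs", {
  net <- pkn(data.frame(source = c("P", "X"), sign = 1L,
                        target = c("A", "T")))
  expect_error(build_ilp(net, "ZZ", 1, tf_measurements = c(T = 1)),
               "perturbation node")
  expect_error(build_ilp(net, "P", 1, tf_measurements = c(QQ = 1)),
               "not in network")
  expect_warning(build_ilp(net, "P", 1, tf_measurements = c(T = 1)),
                 "unfittable")
  expect_error(build_ilp(net, "P", 1, tf_measurements = c(A = 1),
                         node_penalty = 0), "node_penalty")
})

test_that("solver equals the exhaustive oracle on random small networks", {
  withr::with_seed(55, {
    for (i in 1:40) {
      inst_data <- random_pkn_instance(sample(5:8, 1), edge_prob = 0.25)
      inst <- suppressWarnings(
        build_ilp(inst_data$network, inst_data$pert, 1,
                  tf_measurements = inst_data$tf_signs))
      got <- solve_ilp(inst, enumerate_cap = 1000)
      want <- oracle_solve(inst_data$network, inst_data$pert, 1L,
                           inst_data$tf_signs)
      expect_equal(got$objective, want$objective, tolerance = 1e-9)
      for (st in got$solutions)
        expect_true(solution_respects_constraints(st, inst))
      # same optimal state sets
      key <- function(s) paste(names(s), s, sep = ":", collapse = ",")
      expect_setequal(vapply(got$solutions, key, character(1)),
                      vapply(want$solutions, key, character(1)))
    }
  })
})

test_that("gen_pkn plants a recoverable path and consistent regulons", {
  g <- gen_pkn(14, edge_density = 0.2, path_length = 3, n_tfs = 2,
               genes = paste0("g", 1:50), seed = 77)
  truth <- g$ground_truth
  # sign composition along the planted path matches the TF signs
  expect_equal(unname(truth$active_path[["PERT"]]), 1L)
  inst <- build_ilp(g$network, "PERT", 1, tf_measurements = truth$active_tfs,
                    node_penalty = 0.01)
  agg <- aggregate_solutions(solve_ilp(inst))
  vals <- setNames(agg$nodes$value, agg$nodes$id)
  on_path <- union(names(truth$active_path), names(truth$active_tfs))
  expect_true(all(abs(vals[on_path]) == 100))
  expect_true(all(vals[setdiff(names(vals), on_path)] == 0))
  expect_true(all(table(g$regulons$tf) >= 5))
  expect_true(all(g$regulons$mode %in% c(-1L, 1L)))
})

test_that("export_network round trips and handles the empty case", {
  net <- chain_pkn(c(1L, -1L))
  inst <- build_ilp(net, "P", 1, tf_measurements = c(T = -1))
  agg <- aggregate_solutions(solve_ilp(inst))
  sif <- withr::local_tempfile(fileext = ".sif")
  attrs <- withr::local_tempfile(fileext = ".tsv")
  export_network(agg, sif, attrs)
  back <- read_sif(sif)
  expect_equal(back[order(back$source), c("source", "sign", "target")],
               agg$edges[order(agg$edges$source),
                         c("source", "sign", "target")],
               ignore_attr = TRUE)
  expect_equal(nrow(back), 2)
  empty <- agg; empty$edges <- agg$edges[0, ]
  export_network(empty, sif, attrs)
  expect_equal(nrow(read_sif(sif)), 0)
})
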