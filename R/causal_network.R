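#' Infer transcription-factor activities from regulons
#'
#' The raw activity of a TF is the weighted, mode-adjusted mean of the
#' dose-response t-statistics of its measured targets:
#' `raw = sum(w * mode * t) / sum(w)`. Significance comes from a gene-label
#' permutation null: the t vector is permuted `n_permutations` times, raw
#' scores recomputed, and `z = (raw - mean(null)) / sd(null)`. The top K TFs
#' by `|z|` are marked selected (ties broken by TF id). Regulons with no
#' measured target are skipped and reported in attribute `skipped`.
#'
#' @param stats A `dose_response_stats` data.frame (from
#'   [fit_dose_response()]).
#' @param regulons data.frame `tf`, `target`, `mode` (+1/-1), `weight`.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param k_top Number of TFs to select (default 10).
#' @return data.frame of class `tf_activity`: `tf`, `raw_score`, `z_score`,
#'   `sign`, `selected`.
#' @export
tf_activity <- function(stats, regulons, n_permutations = 1000, seed = 1,
                        k_top = 10) {
  regulons <- validate_regulons(regulons)
  t_vec <- setNames(stats$t_stat, stats$feature)
  t_vec <- t_vec[is.finite(t_vec)]
  measured <- regulons$target %in% names(t_vec)
  skipped <- setdiff(unique(regulons$tf), unique(regulons$tf[measured]))
  regulons <- regulons[measured, , drop = FALSE]
  if (nrow(regulons) == 0L) stop("no regulon target present in stats")
  tfs <- sort(unique(regulons$tf))
  genes <- names(t_vec)
  # weight matrix: genes x TFs, entries w*mode / sum(w) per TF
  W <- matrix(0, nrow = length(genes), ncol = length(tfs),
              dimnames = list(genes, tfs))
  wsum <- tapply(regulons$weight, regulons$tf, sum)
  W[cbind(match(regulons$target, genes), match(regulons$tf, tfs))] <-
    regulons$weight * regulons$mode / wsum[regulons$tf]
  raw <- drop(t_vec %*% W)
  null_raw <- with_seed(child_seed(seed, "tf_activity"), {
    P <- vapply(seq_len(n_permutations), function(b) t_vec[sample.int(length(t_vec))],
                numeric(length(t_vec)))
    crossprod(P, W)    # n_permutations x TFs
  })
  mu <- colMeans(null_raw)
  sdev <- apply(null_raw, 2L, sd)
  z <- ifelse(sdev > 0, (raw - mu) / sdev, 0)
  out <- data.frame(tf = tfs, raw_score = raw, z_score = z,
                    sign = ifelse(z >= 0, 1L, -1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$z_score), out$tf), ]
  out$selected <- seq_len(nrow(out)) <= min(k_top, nrow(out))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("tf_activity", "data.frame")
  out
}

#' Construct a prior knowledge network object
#'
#' @param edges data.frame with columns `source`, `sign` (+1/-1), `target`.
#'   Self loops and exact duplicate signed edges are rejected; parallel
#'   edges of opposite sign are allowed.
#' @return Object of class `pkn`.
#' @export
pkn <- function(edges) {
  stopifnot(all(c("source", "sign", "target") %in% names(edges)))
  if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1/-1")
  if (any(edges$source == edges$target)) stop("self loops not allowed")
  if (anyDuplicated(edges[, c("source", "sign", "target")]))
    stop("duplicate signed edges")
  nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges[, c("source", "sign", "target")]),
            class = "pkn")
}

#' @export
print.pkn <- function(x, ...) {
  cat("pkn:", length(x$nodes), "nodes,", nrow(x$edges), "signed edges\n")
  invisible(x)
}

#' Build a CARNIVAL-style ILP instance
#'
#' Encodes the causal-inference problem: every node takes a state in
#' \{-1, 0, +1\}; a non-perturbation node may be active (+1) only if some used
#' incoming edge carries activating signal (source +1 through a +1 edge, or
#' source -1 through a -1 edge), symmetrically for -1; used edges must form
#' a DAG rooted at the perturbation. The objective is
#' `sum_TF mismatch_weight(T) * [state(T) != measured sign(T)] +
#' beta * #\{nodes in non-zero state\}`.
#'
#' The perturbation node always carries its fixed sign (and then counts
#' toward the node penalty); `"free"` sign solves both fixings and keeps the
#' better objective (ties keep both solution sets).
#'
#' @param network A [pkn()].
#' @param perturbation_node Node id of the perturbation.
#' @param perturbation_sign `+1`, `-1` or `"free"`.
#' @param tf_measurements Named vector of measured TF signs (+1/-1).
#' @param mismatch_weights Named positive weights per TF; default all 1
#'   (use `|z_score|` from [tf_activity()] in the pipeline).
#' @param node_penalty Positive beta; default `0.1 * mean(mismatch_weights)`.
#' @return Object of class `ilp_instance`.
#' @export
build_ilp <- function(network, perturbation_node, perturbation_sign = "free",
                      tf_measurements, mismatch_weights = NULL,
                      node_penalty = NULL) {
  stopifnot(inherits(network, "pkn"))
  if (!perturbation_node %in% network$nodes)
    stop("perturbation node not in network")
  if (!all(names(tf_measurements) %in% network$nodes))
    stop("measured TF(s) not in network: ",
         paste(setdiff(names(tf_measurements), network$nodes), collapse = ", "))
  if (!all(tf_measurements %in% c(-1, 1))) stop("TF measurements must be +1/-1")
  if (length(tf_measurements) == 0L) stop("no TF measurements")
  if (is.null(mismatch_weights))
    mismatch_weights <- setNames(rep(1, length(tf_measurements)),
                                 names(tf_measurements))
  mismatch_weights <- mismatch_weights[names(tf_measurements)]
  if (anyNA(mismatch_weights) || any(mismatch_weights <= 0))
    stop("mismatch weights must be positive for every measured TF")
  if (is.null(node_penalty)) node_penalty <- 0.1 * mean(mismatch_weights)
  if (node_penalty <= 0) stop("node_penalty must be > 0")
  ps <- perturbation_sign
  if (!(identical(ps, "free") || ps %in% c(-1, 1)))
    stop("perturbation_sign must be +1, -1 or \"free\"")
  # reachability in the unsigned graph: TFs the perturbation cannot touch
  reach <- reachable_from(network, perturbation_node)
  unfittable <- setdiff(names(tf_measurements), reach)
  if (length(unfittable) > 0L)
    warning("structurally unfittable TF(s), unreachable from the ",
            "perturbation: ", paste(unfittable, collapse = ", "))
  structure(list(network = network, perturbation = perturbation_node,
                 perturbation_sign = ps,
                 tf_signs = tf_measurements,
                 weights = mismatch_weights, beta = node_penalty,
                 unfittable = unfittable),
            class = "ilp_instance")
}

reachable_from <- function(network, start) {
  adj <- split(network$edges$target, network$edges$source)
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# Signed ("doubled") graph reachability: which (node, sign) states are
# reachable from (start, start_sign) along sign-composing edges?
signed_reachable <- function(edges, start, start_sign) {
  key <- function(node, s) paste0(node, "/", s)
  seen <- setNames(TRUE, key(start, start_sign))
  frontier <- list(c(start, start_sign))
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      node <- st[1]; s <- as.integer(st[2])
      out <- edges[edges$source == node, , drop = FALSE]
      for (r in seq_len(nrow(out))) {
        s2 <- s * out$sign[r]
        k <- key(out$target[r], s2)
        if (is.na(seen[k])) {
          seen[k] <- TRUE
          nxt[[length(nxt) + 1L]] <- c(out$target[r], s2)
        }
      }
    }
    frontier <- nxt
  }
  names(seen)
}

#' Solve an ILP instance, enumerating all optimal solutions
#'
#' Pure branch-and-bound over node states (no external solver needed).
#' Domains are first reduced with signed-reachability arguments: a node can
#' hold a non-zero state only if that state is reachable from the
#' perturbation through sign-composing edges and can itself reach some
#' measured TF in its measured sign (otherwise the state costs `beta`
#' without ever reducing mismatch, so it cannot occur in an optimum).
#' Depth-first search with cost pruning then enumerates every
#' minimum-objective assignment up to `enumerate_cap`; feasibility (signal
#' propagation + acyclicity, equivalently reachability of every non-zero
#' node from the perturbation through sign-consistent edges within the
#' non-zero set) is verified at the leaves.
#'
#' @param instance An `ilp_instance` from [build_ilp()].
#' @param enumerate_cap Maximum number of optimal solutions returned
#'   (default 100).
#' @return Object of class `ilp_solutions`: list with `objective` and
#'   `solutions` (list of named state vectors over all network nodes).
#' @export
solve_ilp <- function(instance, enumerate_cap = 100) {
  stopifnot(inherits(instance, "ilp_instance"), enumerate_cap >= 1)
  if (identical(instance$perturbation_sign, "free")) {
    a <- solve_fixed(instance, 1L, enumerate_cap)
    b <- solve_fixed(instance, -1L, enumerate_cap)
    eps <- 1e-9
    res <- if (a$objective < b$objective - eps) a
           else if (b$objective < a$objective - eps) b
           else list(objective = min(a$objective, b$objective),
                     solutions = c(a$solutions, b$solutions))
    res$solutions <- unique(res$solutions)
    res$solutions <- res$solutions[seq_len(min(length(res$solutions),
                                               enumerate_cap))]
  } else {
    res <- solve_fixed(instance, as.integer(instance$perturbation_sign),
                       enumerate_cap)
  }
  structure(c(res, list(instance = instance)), class = "ilp_solutions")
}

solve_fixed <- function(instance, pert_sign, enumerate_cap) {
  net <- instance$network
  nodes <- net$nodes
  edges <- net$edges
  pert <- instance$perturbation
  tf_signs <- instance$tf_signs
  weights <- instance$weights
  beta <- instance$beta

  # domain reduction via the doubled graph
  reach_states <- signed_reachable(edges, pert, pert_sign)
  # backward usefulness: states that can reach some (TF, measured sign);
  # traverse reversed edges from the TF goal states
  redges <- data.frame(source = edges$target, sign = edges$sign,
                       target = edges$source, stringsAsFactors = FALSE)
  useful <- character(0)
  for (tf in names(tf_signs)) {
    useful <- c(useful, signed_reachable(redges, tf, tf_signs[[tf]]))
  }
  useful <- unique(useful)
  domain <- lapply(setNames(nodes, nodes), function(v) {
    if (v == pert) return(pert_sign)
    s <- c(0L)
    for (sg in c(1L, -1L)) {
      k <- paste0(v, "/", sg)
      if (k %in% reach_states && k %in% useful) s <- c(s, sg)
    }
    s
  })
  cand <- setdiff(names(domain)[lengths(domain) > 1L], pert)
  if (length(cand) > 24L)
    stop("instance too large for the exact solver (", length(cand),
         " undetermined nodes); reduce the network first")
  # order candidates by BFS distance from the perturbation for better pruning
  dist <- bfs_order(edges, pert)
  cand <- cand[order(match(cand, dist), cand)]

  # edge list indexed for the feasibility check
  e_src <- edges$source; e_tgt <- edges$target; e_sgn <- edges$sign

  states <- setNames(rep(0L, length(nodes)), nodes)
  states[pert] <- pert_sign
  # mismatch contributed by measured TFs whose state is already fixed
  fixed_tfs <- setdiff(names(tf_signs), cand)
  base_mismatch <- sum(weights[fixed_tfs][states[fixed_tfs] !=
                                            tf_signs[fixed_tfs]])
  best <- list(objective = Inf, solutions = list())

  feasible <- function(st) {
    nz <- names(st)[st != 0L]
    if (length(nz) == 1L) return(TRUE)
    ok_edge <- st[e_src] != 0L & st[e_tgt] != 0L &
      st[e_tgt] == st[e_src] * e_sgn
    adj <- split(e_tgt[ok_edge], e_src[ok_edge])
    seen <- pert
    frontier <- pert
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    all(nz %in% seen)
  }

  record <- function(cost, st) {
    if (cost < best$objective - 1e-9) {
      best$objective <<- cost
      best$solutions <<- list(st)
    } else if (abs(cost - best$objective) <= 1e-9 &&
               length(best$solutions) < enumerate_cap) {
      best$solutions <<- c(best$solutions, list(st))
    }
  }

  # initial incumbent: everything but the perturbation at 0 (always feasible)
  record(base_mismatch + sum(weights[intersect(cand, names(tf_signs))]) + beta,
         states)

  dfs <- function(k, st, cost) {
    if (cost > best$objective + 1e-9) return()
    if (k > length(cand)) {
      if (feasible(st)) record(cost, st)
      return()
    }
    v <- cand[k]
    for (s in domain[[v]]) {
      st[v] <- s
      dc <- 0
      if (s != 0L) dc <- dc + beta
      if (v %in% names(tf_signs)) dc <- dc + if (s == tf_signs[[v]]) 0 else
        weights[[v]]
      dfs(k + 1L, st, cost + dc)
    }
  }
  dfs(1L, states, base_mismatch + beta)  # beta: the perturbation node itself
  # drop the provisional incumbent if it was superseded but kept by ties
  best$solutions <- unique(best$solutions)
  best
}

bfs_order <- function(edges, start) {
  adj <- split(edges$target, edges$source)
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Aggregate optimal solutions into an inferred network
#'
#' Node value = `100 * (n_up - n_down) / n_solutions`, rounded to the
#' nearest integer (signed; the unsigned magnitude `value_abs` is also
#' reported for parity with the 0-100 activation convention). An edge is
#' included if it is used in at least one optimal solution, annotated with
#' its use frequency; a used edge is a sign-consistent edge between non-zero
#' nodes lying on a directed path from the perturbation to a measured TF.
#'
#' @param solutions An `ilp_solutions` from [solve_ilp()].
#' @return Object of class `inferred_network`: list with `nodes` (id, value,
#'   value_abs, role), `edges` (source, sign, target, frequency),
#'   `objective`, `n_solutions`.
#' @export
aggregate_solutions <- function(solutions) {
  stopifnot(inherits(solutions, "ilp_solutions"),
            length(solutions$solutions) >= 1L)
  inst <- solutions$instance
  net <- inst$network
  sols <- solutions$solutions
  S <- do.call(rbind, sols)    # solutions x nodes
  n_up <- colSums(S > 0)
  n_down <- colSums(S < 0)
  value <- setNames(as.integer(round(100 * (n_up - n_down) / length(sols))),
                    colnames(S))
  role <- ifelse(net$nodes == inst$perturbation, "perturbation",
                 ifelse(net$nodes %in% names(inst$tf_signs), "tf",
                        "intermediate"))
  nodes <- data.frame(id = net$nodes, value = value[net$nodes],
                      value_abs = abs(value[net$nodes]),
                      role = role, stringsAsFactors = FALSE, row.names = NULL)

  edges <- net$edges
  use_count <- rep(0L, nrow(edges))
  for (st in sols) {
    used <- used_edges(st, inst)
    use_count <- use_count + used
  }
  keep <- use_count > 0L
  edges_out <- edges[keep, , drop = FALSE]
  edges_out$frequency <- use_count[keep] / length(sols)
  rownames(edges_out) <- NULL
  structure(list(nodes = nodes, edges = edges_out,
                 objective = solutions$objective,
                 n_solutions = length(sols)),
            class = "inferred_network")
}

# logical vector over instance network edges: used in this solution?
used_edges <- function(st, inst) {
  edges <- inst$network$edges
  consistent <- st[edges$source] != 0L & st[edges$target] != 0L &
    st[edges$target] == st[edges$source] * edges$sign
  if (!any(consistent)) return(rep(FALSE, nrow(edges)))
  sub <- edges[consistent, , drop = FALSE]
  fwd <- bfs_order(sub, inst$perturbation)
  # co-reachability to a matched, non-zero measured TF
  targets <- names(inst$tf_signs)[st[names(inst$tf_signs)] != 0L]
  rsub <- data.frame(source = sub$target, target = sub$source)
  bwd <- unique(unlist(lapply(targets, function(tf) bfs_order(rsub, tf))))
  consistent[consistent] <- sub$source %in% fwd & sub$target %in% bwd
  consistent
}

#' @export
print.inferred_network <- function(x, ...) {
  cat("inferred_network:", sum(x$nodes$value != 0), "active of",
      nrow(x$nodes), "nodes,", nrow(x$edges), "edges, objective",
      format(x$objective), "over", x$n_solutions, "optimal solution(s)\n")
  invisible(x)
}

#' Export an inferred network to SIF plus node attributes
#'
#' @param net An `inferred_network`.
#' @param sif_path Path for the SIF file (source, activates/inhibits,
#'   target).
#' @param attr_path Path for the node attribute TSV (id, value, value_abs,
#'   role).
#' @export
export_network <- function(net, sif_path, attr_path) {
  stopifnot(inherits(net, "inferred_network"))
  write_sif(net$edges, sif_path)
  data.table::fwrite(net$nodes, attr_path, sep = "\t")
  invisible(c(sif_path, attr_path))
}
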