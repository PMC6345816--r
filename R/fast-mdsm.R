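# Two-layer degree-1 preprocessing: fixes a subset V_M of some optimal
# multilayer dominating set before the ILP solve, by repeatedly locating
# pendant (degree-1) nodes whose unique neighbour must enter the solution.
# A node is "observed" in a layer once it has a neighbour in V_M there.

#' Degree-1 preprocessing for two-layer minimum dominating sets
#'
#' Works on mutable copies of both layers. In each pass, every candidate
#' node `v_i` (in lexicographic order) is tested against three rules:
#' a pendant neighbour `v_j` of `v_i` in layer 1 that is absent from layer 2
#' (rule one), the symmetric rule for layer 2, and a joint rule for a node
#' that is pendant on `v_i` in both layers. A firing rule deletes the
#' pendant edge, adds `v_i` to `V_M` and marks `v_j` observed. After each
#' pass, observation propagates to all unobserved non-`V_M` neighbours of
#' `V_M` in each layer. Passes repeat until no rule fires. Every addition is
#' sound: `V_M` is a subset of some optimal multilayer dominating set.
#'
#' @param net A `multilayer` object with exactly two layers.
#' @return An object of class `preprocess_state`: list with `v_m`,
#'   `observed_1`, `observed_2` (character vectors) and the working
#'   adjacency lists `adj_1`, `adj_2` after edge deletions.
#' @export
fast_mdsm_preprocess <- function(net) {
  net <- as_multilayer(net)
  if (n_layers(net) != 2L) {
    abort("Preprocessing is defined for exactly two layers.", class = "multidom_arity_error")
  }
  g1 <- net$layers[[1]]; g2 <- net$layers[[2]]
  v1 <- node_names(g1); v2 <- node_names(g2)
  all_nodes <- net$universe

  adj_of <- function(g) {
    al <- igraph::as_adj_list(g)
    nm <- node_names(g)
    setNames(lapply(al, function(ix) nm[as.integer(ix)]), nm)
  }
  adj1 <- adj_of(g1); adj2 <- adj_of(g2)
  obs1 <- setNames(rep(FALSE, length(all_nodes)), all_nodes)
  obs2 <- obs1
  vm <- character(0)

  del_edge <- function(adj, a, b) {
    adj[[a]] <- setdiff(adj[[a]], b)
    adj[[b]] <- setdiff(adj[[b]], a)
    adj
  }

  repeat {
    fired <- FALSE
    for (vi in all_nodes) {
      # rule: pendant neighbour in layer 1, absent from layer 2
      if (vi %in% v1) {
        cand <- adj1[[vi]]
        cand <- cand[!obs1[cand] & !(cand %in% vm) &
                       lengths(adj1[cand]) == 1L & !(cand %in% v2)]
        if (length(cand) > 0L) {
          vj <- sort_nodes(cand)[[1]]
          adj1 <- del_edge(adj1, vi, vj)
          vm <- union(vm, vi)
          obs1[vj] <- TRUE
          fired <- TRUE
        }
      }
      # symmetric rule for layer 2
      if (vi %in% v2) {
        cand <- adj2[[vi]]
        cand <- cand[!obs2[cand] & !(cand %in% vm) &
                       lengths(adj2[cand]) == 1L & !(cand %in% v1)]
        if (length(cand) > 0L) {
          vj <- sort_nodes(cand)[[1]]
          adj2 <- del_edge(adj2, vi, vj)
          vm <- union(vm, vi)
          obs2[vj] <- TRUE
          fired <- TRUE
        }
      }
      # joint rule: pendant on vi in both layers
      if (vi %in% v1 && vi %in% v2) {
        cand <- intersect(adj1[[vi]], adj2[[vi]])
        cand <- cand[!obs1[cand] & !obs2[cand] & !(cand %in% vm) &
                       lengths(adj1[cand]) == 1L & lengths(adj2[cand]) == 1L]
        if (length(cand) > 0L) {
          vj <- sort_nodes(cand)[[1]]
          adj1 <- del_edge(adj1, vi, vj)
          adj2 <- del_edge(adj2, vi, vj)
          vm <- union(vm, vi)
          obs1[vj] <- TRUE; obs2[vj] <- TRUE
          fired <- TRUE
        }
      }
    }
    # propagate observation to neighbours of V_M in each layer
    for (u in names(obs1)[!obs1 & !(all_nodes %in% vm)]) {
      if (u %in% v1 && any(adj1[[u]] %in% vm)) obs1[u] <- TRUE
    }
    for (u in names(obs2)[!obs2 & !(all_nodes %in% vm)]) {
      if (u %in% v2 && any(adj2[[u]] %in% vm)) obs2[u] <- TRUE
    }
    if (!fired) break
  }

  structure(
    list(v_m = sort_nodes(vm),
         observed_1 = sort_nodes(names(obs1)[obs1]),
         observed_2 = sort_nodes(names(obs2)[obs2]),
         adj_1 = adj1, adj_2 = adj2),
    class = "preprocess_state"
  )
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat(sprintf("<preprocess state: |V_M| = %d, observed %d (layer 1) / %d (layer 2)>\n",
              length(x$v_m), length(x$observed_1), length(x$observed_2)))
  invisible(x)
}

#' Fast multilayer minimum dominating set
#'
#' For two-layer networks, runs [fast_mdsm_preprocess()] and then solves the
#' reduced ILP in which every node of `V_M` is fixed to 1 and covering
#' constraints are kept only for nodes not yet observed in their layer.
#' For other layer counts (or `preprocess = FALSE`) it solves the plain
#' multilayer ILP. The optimal size is identical to [ilp_mdsm()] on the same
#' input; only the work per solve differs.
#'
#' @inheritParams ilp_mdsm
#' @param preprocess Apply the degree-1 preprocessing for two-layer inputs?
#' @return A `domset_result`; `forced_subset` holds `V_M` when
#'   preprocessing ran.
#' @export
fast_mdsm <- function(net, include_isolated = TRUE, preprocess = TRUE,
                      canonical = FALSE, time_limit = 600) {
  net <- as_multilayer(net)
  if (n_layers(net) != 2L || !preprocess) {
    return(ilp_mdsm(net, include_isolated = include_isolated,
                    canonical = canonical, time_limit = time_limit))
  }
  pp <- fast_mdsm_preprocess(net)
  nm <- net$universe
  rows <- list()
  for (k in 1:2) {
    g <- net$layers[[k]]
    adj <- if (k == 1L) pp$adj_1 else pp$adj_2
    observed <- if (k == 1L) pp$observed_1 else pp$observed_2
    cov <- covered_names(g, include_isolated)
    cov <- setdiff(cov, union(pp$v_m, observed))
    rows <- c(rows, lapply(cov, function(v) match(c(v, adj[[v]]), nm)))
  }
  sol <- solve_domination(nm, rows, forced_idx = match(pp$v_m, nm),
                          canonical = canonical, time_limit = time_limit)
  new_domset_result(sol$members, forced = pp$v_m,
                    include_isolated = include_isolated, wall_time = sol$wall_time)
}

#' Intersection of canonical per-layer minimum dominating sets (MDSI)
#'
#' Restricts both graphs to their common nodes, computes one MDS of each
#' induced layer (canonical by default, so the result is reproducible), and
#' returns the intersection. The MDSI is a similarity baseline: unlike the
#' multilayer MDS it carries no controllability guarantee.
#'
#' @param g1,g2 Named undirected igraph objects.
#' @inheritParams ilp_mds
#' @return A `domset_result` whose members are the intersection.
#' @export
mdsi <- function(g1, g2, include_isolated = TRUE, canonical = TRUE, time_limit = 600) {
  v <- common_nodes(g1, g2)
  m1 <- ilp_mds(induced_graph(g1, v), include_isolated = include_isolated,
                canonical = canonical, time_limit = time_limit)
  m2 <- ilp_mds(induced_graph(g2, v), include_isolated = include_isolated,
                canonical = canonical, time_limit = time_limit)
  new_domset_result(intersect(m1$members, m2$members),
                    include_isolated = include_isolated,
                    wall_time = m1$wall_time + m2$wall_time)
}
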