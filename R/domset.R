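# Dominating-set computations. A node set U dominates a layer G if every
# covered node of G is in U or adjacent to a member of U. "Covered" is every
# node when include_isolated = TRUE (the original definition: an isolated
# node can only dominate itself, so it is forced into any solution) and
# every node of degree >= 1 otherwise.

new_domset_result <- function(members, forced = character(), status = "optimal",
                              include_isolated = TRUE, wall_time = NA_real_) {
  members <- sort_nodes(members)
  structure(
    list(members = members,
         size = length(members),
         forced_subset = sort_nodes(forced),
         solver_status = status,
         include_isolated = include_isolated,
         wall_time = wall_time),
    class = "domset_result"
  )
}

#' @export
print.domset_result <- function(x, ...) {
  cat(sprintf("<dominating set: size %d, status %s%s>\n",
              x$size, x$solver_status,
              if (length(x$forced_subset)) sprintf(", %d forced by preprocessing", length(x$forced_subset)) else ""))
  shown <- head(x$members, 10L)
  cat("  members:", paste(shown, collapse = ", "),
      if (x$size > 10L) sprintf("... (+%d)", x$size - 10L) else "", "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.domset_result <- function(x, ...) {
  tibble(node = x$members, forced = x$members %in% x$forced_subset)
}

#' @exportS3Method generics::glance
glance.domset_result <- function(x, ...) {
  tibble(size = x$size,
         n_forced = length(x$forced_subset),
         solver_status = x$solver_status,
         include_isolated = x$include_isolated,
         wall_time = x$wall_time)
}

covered_names <- function(g, include_isolated) {
  nm <- node_names(g)
  if (include_isolated) nm else nm[igraph::degree(g) > 0L]
}

#' Check the domination certificate of a node set
#'
#' Verifies by direct neighbourhood scan that `members` dominates every
#' covered node in every layer of `net`.
#'
#' @param net A `multilayer` object or a single graph.
#' @param members Character vector of node identifiers.
#' @param include_isolated Should isolated nodes require domination
#'   (i.e. membership)? Default `TRUE`.
#' @return `TRUE` or `FALSE`.
#' @export
is_dominating_set <- function(net, members, include_isolated = TRUE) {
  net <- as_multilayer(net)
  members <- as.character(members)
  for (g in net$layers) {
    nm <- node_names(g)
    in_set <- nm %in% members
    cov <- covered_names(g, include_isolated)
    adj <- igraph::adjacent_vertices(g, v = cov)
    ok <- vapply(seq_along(cov), function(i) {
      cov[[i]] %in% members || any(nm[as.integer(adj[[i]])] %in% members)
    }, logical(1))
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

# ---- brute-force oracles ----------------------------------------------------

# Bitmask search over subsets in increasing size; combn() enumerates index
# combinations lexicographically, so the first hit is the canonical
# (lexicographically smallest) minimum solution.
bitmask_search <- function(n, cons_masks) {
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  if (length(cons_masks) == 0L) return(integer(0))
  for (s in seq_len(n)) {
    combos <- combn(n, s)
    for (j in seq_len(ncol(combos))) {
      mask <- sum(bit[combos[, j]])
      if (all(bitwAnd(cons_masks, mask) != 0L)) return(combos[, j])
    }
  }
  abort("No dominating set exists (internal error).", class = "multidom_solver_error")
}

#' Exhaustive minimum dominating set (test oracle)
#'
#' Enumerates node subsets in increasing size and returns the first
#' dominating set found, which is the lexicographically smallest
#' minimum-size solution. Intended as an independent oracle for small
#' graphs.
#'
#' @param g A named undirected igraph with at most 25 nodes.
#' @inheritParams is_dominating_set
#' @return A `domset_result`.
#' @export
brute_force_mds <- function(g, include_isolated = TRUE) {
  assert_ugraph(g)
  nm <- sort_nodes(node_names(g))
  n <- length(nm)
  if (n > 25L) abort("brute_force_mds is guarded to 25 nodes.", class = "multidom_size_error")
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  cov <- covered_names(g, include_isolated)
  masks <- vapply(cov, function(v) {
    nbrs <- node_names(g)[as.integer(igraph::neighbors(g, v))]
    sum(bit[match(c(v, nbrs), nm)])
  }, integer(1))
  idx <- bitmask_search(n, unname(masks))
  new_domset_result(nm[idx], include_isolated = include_isolated)
}

#' Exhaustive minimum dominating set for a multilayer network (test oracle)
#'
#' @param net A `multilayer` object (or list of graphs) whose universe has
#'   at most 20 nodes.
#' @inheritParams is_dominating_set
#' @return A `domset_result`.
#' @export
brute_force_mdsm <- function(net, include_isolated = TRUE) {
  net <- as_multilayer(net)
  nm <- net$universe
  n <- length(nm)
  if (n > 20L) abort("brute_force_mdsm is guarded to 20 universe nodes.", class = "multidom_size_error")
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  masks <- integer(0)
  for (g in net$layers) {
    cov <- covered_names(g, include_isolated)
    masks <- c(masks, vapply(cov, function(v) {
      nbrs <- node_names(g)[as.integer(igraph::neighbors(g, v))]
      sum(bit[match(c(v, nbrs), nm)])
    }, integer(1)))
  }
  idx <- bitmask_search(n, unname(masks))
  new_domset_result(nm[idx], include_isolated = include_isolated)
}

# ---- ILP solves -------------------------------------------------------------

# Build covering rows for one layer in the index space of `nm`.
layer_rows <- function(g, nm, include_isolated) {
  cov <- covered_names(g, include_isolated)
  lapply(cov, function(v) {
    nbrs <- node_names(g)[as.integer(igraph::neighbors(g, v))]
    match(c(v, nbrs), nm)
  })
}

solve_domination <- function(nm, rows, forced_idx = integer(), canonical = FALSE,
                             time_limit = 600) {
  t0 <- proc.time()[["elapsed"]]
  res <- glpk_solve_cover(length(nm), rows, forced = forced_idx, time_limit = time_limit)
  if (res$status != "optimal") {
    abort(sprintf("ILP solve did not reach optimality (status: %s)", res$status),
          class = "multidom_solver_error", status = res$status)
  }
  size <- sum(res$x)
  if (canonical && length(nm) > 0L) {
    # second stage: among optimal-size solutions, minimise the sum of
    # lexicographic node ranks for a reproducible canonical solution
    res2 <- glpk_solve_cover(length(nm), rows, obj = seq_along(nm),
                             forced = forced_idx, pin_size = size,
                             time_limit = time_limit)
    if (res2$status != "optimal") {
      abort(sprintf("Canonicalization solve did not reach optimality (status: %s)", res2$status),
            class = "multidom_solver_error", status = res2$status)
    }
    res <- res2
  }
  list(members = nm[res$x == 1L],
       wall_time = proc.time()[["elapsed"]] - t0)
}

#' Minimum dominating set of one graph via integer linear programming
#'
#' Minimises \eqn{\sum_i x_i} subject to \eqn{x_i + \sum_{j: \{v_j,v_i\} \in E} x_j \ge 1}
#' for every covered node \eqn{v_i}, with binary \eqn{x}.
#'
#' @param g A named undirected igraph object.
#' @inheritParams is_dominating_set
#' @param canonical If `TRUE`, a second solve pins the optimal size and
#'   minimises the sum of lexicographic node ranks, making the returned
#'   membership deterministic across runs (sizes are always well defined;
#'   memberships of an MDS are not unique).
#' @param time_limit Solver time limit in seconds. A timeout raises a
#'   `multidom_solver_error` carrying the solver status rather than
#'   returning a possibly suboptimal set.
#' @return A `domset_result`.
#' @export
ilp_mds <- function(g, include_isolated = TRUE, canonical = FALSE, time_limit = 600) {
  assert_ugraph(g)
  nm <- sort_nodes(node_names(g))
  sol <- solve_domination(nm, layer_rows(g, nm, include_isolated),
                          canonical = canonical, time_limit = time_limit)
  new_domset_result(sol$members, include_isolated = include_isolated,
                    wall_time = sol$wall_time)
}

#' Minimum dominating set of a multilayer network via ILP
#'
#' One set must dominate every layer simultaneously: the covering
#' constraints of all layers share the same binary variables. Nodes absent
#' from a layer contribute no constraint for that layer.
#'
#' @param net A `multilayer` object or list of graphs.
#' @inheritParams ilp_mds
#' @param forced Character vector of node identifiers fixed into the
#'   solution (`x_i = 1`), e.g. a preprocessing subset known to belong to
#'   some optimal solution.
#' @return A `domset_result`.
#' @export
ilp_mdsm <- function(net, include_isolated = TRUE, forced = character(),
                     canonical = FALSE, time_limit = 600) {
  net <- as_multilayer(net)
  nm <- net$universe
  if (!all(forced %in% nm)) {
    abort("`forced` must be a subset of the node universe.", class = "multidom_validation_error")
  }
  rows <- unlist(lapply(net$layers, layer_rows, nm = nm,
                        include_isolated = include_isolated),
                 recursive = FALSE)
  sol <- solve_domination(nm, rows, forced_idx = match(forced, nm),
                          canonical = canonical, time_limit = time_limit)
  new_domset_result(sol$members, forced = forced,
                    include_isolated = include_isolated, wall_time = sol$wall_time)
}

#' Proposition-style size bounds for the multilayer MDS
#'
#' The multilayer minimum dominating set is at least as large as the
#' largest per-layer MDS (it dominates each layer) and no larger than the
#' union of per-layer MDSs: \eqn{\max_i S_i \le S_{multi} \le \sum_i S_i}.
#' Both bounds are tight (identical layers; disjoint node sets).
#'
#' @inheritParams ilp_mdsm
#' @return A list with `lower`, `upper` and the per-layer sizes.
#' @export
prop1_bounds <- function(net, include_isolated = TRUE, time_limit = 600) {
  net <- as_multilayer(net)
  sizes <- vapply(net$layers, function(g) {
    ilp_mds(g, include_isolated = include_isolated, time_limit = time_limit)$size
  }, numeric(1))
  list(lower = max(sizes), upper = sum(sizes), per_layer = sizes)
}
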