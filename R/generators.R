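# Random-graph generators used as fixtures for the simulation experiments.
# All generators take an explicit integer seed and are reproducible.

make_node_names <- function(n) sprintf("v%0*d", nchar(as.character(n)), seq_len(n))

name_vertices <- function(g) {
  igraph::V(g)$name <- make_node_names(igraph::vcount(g))
  g
}

#' Random k-regular graph
#'
#' Uniform-style random simple graph in which every node has degree exactly
#' `k` (pairing construction with rejection of self-loops and multi-edges).
#'
#' @param n Number of nodes; `n * k` must be even and `k < n`.
#' @param k Common degree.
#' @param seed Integer seed; identical seeds give identical graphs.
#' @return A simple undirected named igraph object.
#' @export
gen_k_regular <- function(n, k, seed) {
  if (k >= n || (n * k) %% 2L != 0L) {
    abort("A k-regular graph needs k < n and n*k even.", class = "multidom_infeasible_error")
  }
  g <- withr::with_seed(seed, igraph::sample_k_regular(n, k))
  name_vertices(g)
}

#' Random power-law (scale-free) graph
#'
#' Draws a degree sequence i.i.d. from \eqn{P(k) \propto k^{-\gamma}}
#' (support \eqn{1 \le k \le n-1}), pairs stubs with the configuration
#' model, and discards self-loops and multi-edges, yielding a simple graph
#' with a power-law degree tail. Node count is exactly `n`; a node whose
#' only stubs were discarded may end up isolated.
#'
#' @param n Number of nodes (at least 10).
#' @param gamma Power-law exponent, greater than 1.
#' @param seed Integer seed.
#' @return A simple undirected named igraph object.
#' @export
gen_powerlaw <- function(n, gamma, seed) {
  if (!is.numeric(gamma) || gamma <= 1) {
    abort("`gamma` must exceed 1.", class = "multidom_parameter_error")
  }
  if (n < 10L) abort("`n` must be at least 10.", class = "multidom_parameter_error")
  g <- withr::with_seed(seed, {
    ks <- seq_len(n - 1L)
    d <- sample(ks, n, replace = TRUE, prob = ks^(-gamma))
    if (sum(d) %% 2L == 1L) {
      i <- which(d < n - 1L)[[1]]
      d[i] <- d[i] + 1L
    }
    igraph::simplify(igraph::sample_degseq(d, method = "configuration"))
  })
  name_vertices(g)
}

#' Maximally assortative scale-free graph
#'
#' A maximally assortative network (no edge swap increases the
#' assortativity coefficient) is, to a good approximation, a disjoint
#' collection of k-regular blocks. This generator realises that limiting
#' structure directly: the number of nodes of degree `k` is proportional to
#' \eqn{k^{-\gamma}}, each degree class forms its own k-regular random
#' block, blocks that would have fewer than `k + 1` nodes are truncated,
#' and odd-parity blocks drop one node.
#'
#' @inheritParams gen_powerlaw
#' @return A simple undirected named igraph object in which every node's
#'   degree equals its block parameter.
#' @export
gen_max_assortative <- function(n, gamma, seed) {
  if (!is.numeric(gamma) || gamma <= 1) {
    abort("`gamma` must exceed 1.", class = "multidom_parameter_error")
  }
  g <- withr::with_seed(seed, {
    ks <- seq_len(max(2L, n - 1L))
    w <- ks^(-gamma)
    counts <- round(n * w / sum(w))
    blocks <- list()
    for (k in ks) {
      ck <- counts[[k]]
      if ((k * ck) %% 2L == 1L) ck <- ck - 1L
      if (ck < k + 1L) next
      blocks[[length(blocks) + 1L]] <- igraph::sample_k_regular(ck, k)
    }
    if (length(blocks) == 0L) {
      abort("No feasible degree block at these parameters.", class = "multidom_parameter_error")
    }
    Reduce(igraph::disjoint_union, blocks)
  })
  name_vertices(g)
}
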