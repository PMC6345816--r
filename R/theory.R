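# Analytic estimators: layer recursions for the dominating-set fraction,
# the virtual layer-by-layer construction they model, and the
# perturbation-theory probabilities for rewiring and insertion/deletion.

new_estimate_series <- function(values, model, parameter, truncation = NA_integer_,
                                tol = NA_real_) {
  out <- tibble(i = seq_along(values), value = values)
  class(out) <- c("estimate_series", class(out))
  attr(out, "model") <- model
  attr(out, "parameter") <- parameter
  attr(out, "truncation") <- truncation
  attr(out, "tol") <- tol
  out
}

#' Dominating-set fraction recursion for k-regular multilayers
#'
#' Evaluates the layer recursion
#' \deqn{\alpha_1 = 1/(k+1), \qquad
#'   \alpha_{i+1} = \alpha_i + \frac{1}{k+1}(1-\alpha_i)^{k+1},}
#' the estimated fraction of nodes in the dominating set built by the
#' virtual layer-by-layer procedure on `N` independent k-regular random
#' layers. The series is strictly increasing and bounded above by 1.
#'
#' @param k Common degree (at least 1).
#' @param N Number of layers (at least 1).
#' @return An `estimate_series` tibble with columns `i` and `value`.
#' @export
alpha_series <- function(k, N) {
  if (!is.numeric(k) || k < 1) abort("`k` must be at least 1.", class = "multidom_parameter_error")
  if (!is.numeric(N) || N < 1) abort("`N` must be at least 1.", class = "multidom_parameter_error")
  vals <- numeric(N)
  vals[[1]] <- 1 / (k + 1)
  if (N > 1) {
    for (i in seq_len(N - 1)) {
      vals[[i + 1]] <- vals[[i]] + (1 / (k + 1)) * (1 - vals[[i]])^(k + 1)
    }
  }
  new_estimate_series(vals, model = "kregular", parameter = k)
}

#' Dominating-set fraction recursion for maximally assortative scale-free
#' multilayers
#'
#' Evaluates
#' \deqn{\beta_1 = \frac{\sum_k \frac{1}{k+1} k^{-\gamma}}{\sum_k k^{-\gamma}},
#'  \qquad \beta_{i+1} = \beta_i +
#'  \frac{\sum_k \frac{1}{k+1} (1-\beta_i)^{k+1} k^{-\gamma}}{\sum_k k^{-\gamma}},}
#' where the sums run over degrees \eqn{k \ge 1}. The two static zeta-like
#' sums are truncated at `k_max` (or earlier, once the running term drops
#' below `tol`) and completed with a midpoint-integral tail correction; the
#' increment sums decay geometrically through the \eqn{(1-\beta)^{k+1}}
#' factor and need no correction.
#'
#' @param gamma Power-law exponent, greater than 1 (series convergence).
#' @param N Number of layers.
#' @param k_max Truncation point of the degree sums.
#' @param tol Running-term cut-off.
#' @return An `estimate_series` tibble; the truncation used is stored in
#'   the `truncation` attribute.
#' @export
beta_series <- function(gamma, N, k_max = 1e5, tol = 1e-12) {
  if (!is.numeric(gamma) || gamma <= 1) {
    abort("`gamma` must exceed 1 for the degree sums to converge.",
          class = "multidom_divergence_error")
  }
  if (!is.numeric(N) || N < 1) abort("`N` must be at least 1.", class = "multidom_parameter_error")
  ks <- seq_len(k_max)
  w <- ks^(-gamma)
  keep <- w >= tol
  M <- if (any(!keep)) which(!keep)[[1]] - 1L else as.integer(k_max)
  ks <- ks[seq_len(M)]
  w <- w[seq_len(M)]
  # midpoint-integral tails:  sum_{k>M} k^-g  ~  (M+1/2)^(1-g)/(g-1)
  #                           sum_{k>M} k^-g/(k+1)  ~  (M+1/2)^(-g)/g
  z <- sum(w) + (M + 0.5)^(1 - gamma) / (gamma - 1)
  num1 <- sum(w / (ks + 1)) + (M + 0.5)^(-gamma) / gamma
  vals <- numeric(N)
  vals[[1]] <- num1 / z
  if (N > 1) {
    for (i in seq_len(N - 1)) {
      b <- vals[[i]]
      vals[[i + 1]] <- b + sum((1 / (ks + 1)) * (1 - b)^(ks + 1) * w) / z
    }
  }
  new_estimate_series(vals, model = "assortative", parameter = gamma,
                      truncation = M, tol = tol)
}

#' Virtual layer-by-layer dominating-set construction
#'
#' Builds a valid (not necessarily minimum) multilayer dominating set the
#' way the layer recursions model it: take an MDS of layer 1; for each
#' further layer i, collect the nodes not yet dominated in that layer by
#' the union of previous stage sets, and add an MDS of the subgraph of
#' layer i induced by those residual nodes. The output dominates every
#' layer.
#'
#' @param net A `multilayer` object whose layers share one node universe.
#' @inheritParams ilp_mds
#' @return A `domset_result` for the union of the stage sets.
#' @export
virtual_dsm <- function(net, include_isolated = TRUE, time_limit = 600) {
  net <- as_multilayer(net)
  members <- ilp_mds(net$layers[[1]], include_isolated = include_isolated,
                     time_limit = time_limit)$members
  if (n_layers(net) > 1L) {
    for (i in 2:n_layers(net)) {
      g <- net$layers[[i]]
      present <- intersect(members, node_names(g))
      nbr <- if (length(present)) {
        unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                             function(ix) node_names(g)[as.integer(ix)])))
      } else character(0)
      residual <- setdiff(covered_names(g, include_isolated), c(members, nbr))
      if (length(residual) > 0L) {
        ds_i <- ilp_mds(induced_graph(g, residual), include_isolated = TRUE,
                        time_limit = time_limit)$members
        members <- union(members, ds_i)
      }
    }
  }
  new_domset_result(members, include_isolated = include_isolated)
}

#' Probability that a random edge endpoint lies in the dominating set
#'
#' Estimated as the degree-mass fraction of the set:
#' \eqn{p \approx \sum_{v \in U} d(v) / \sum_{v \in V} d(v)}.
#'
#' @param g A named undirected igraph with at least one edge.
#' @param mds Character vector: a dominating set of `g` (typically an MDS).
#' @return A probability in \[0, 1\].
#' @export
estimate_p <- function(g, mds) {
  assert_ugraph(g)
  if (igraph::ecount(g) == 0L) {
    abort("`p` is undefined on an edgeless graph.", class = "multidom_undefined_error")
  }
  mds <- intersect(as.character(mds), node_names(g))
  if (length(mds) == 0L) return(0)
  sum(igraph::degree(g, mds)) / (2 * igraph::ecount(g))
}

#' Probability that a non-member node has two or more neighbours in the set
#'
#' The fraction of nodes outside `mds` with at least two neighbours inside
#' it; such nodes stay dominated when one incident edge to the set is lost.
#'
#' @inheritParams estimate_p
#' @return A probability in \[0, 1\].
#' @export
estimate_q <- function(g, mds) {
  assert_ugraph(g)
  mds <- as.character(mds)
  outside <- setdiff(node_names(g), mds)
  if (length(outside) == 0L) {
    abort("`q` is undefined when the set contains every node.", class = "multidom_undefined_error")
  }
  nhits <- vapply(igraph::adjacent_vertices(g, outside), function(ix) {
    sum(node_names(g)[as.integer(ix)] %in% mds)
  }, numeric(1))
  mean(nhits >= 2)
}

check_prob <- function(x, nm) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", nm), class = "multidom_parameter_error")
  }
}

#' Per-step probability of needing one extra driver node under rewiring
#'
#' Evaluates \eqn{P_{+1} \approx 4(1-q)\,p\,(1-p)^3 + 2(1-q)^2 p^2 (1-p)^2}:
#' the estimated probability that one degree-preserving rewiring step
#' forces one node to be added to the dominating set.
#'
#' @param p Probability that a random edge endpoint is in the set
#'   ([estimate_p()]).
#' @param q Probability that a non-member has two or more set neighbours
#'   ([estimate_q()]).
#' @return A probability.
#' @export
p_plus1_rewire <- function(p, q) {
  check_prob(p, "p"); check_prob(q, "q")
  4 * (1 - q) * p * (1 - p)^3 + 2 * (1 - q)^2 * p^2 * (1 - p)^2
}

#' Per-step probability of needing one extra driver node under random
#' insertion/deletion
#'
#' Evaluates \eqn{P_{+1} \approx 2 p_d (1-q)\, p\,(1-p)}: only deletions
#' contribute, hence the `p_d` factor.
#'
#' @inheritParams p_plus1_rewire
#' @param p_d Per-step deletion probability.
#' @return A probability.
#' @export
p_plus1_indel <- function(p, q, p_d) {
  check_prob(p, "p"); check_prob(q, "q"); check_prob(p_d, "p_d")
  2 * p_d * (1 - q) * p * (1 - p)
}

#' Theoretical size ratio after K perturbation steps
#'
#' The linear-growth estimate of the two-layer dominating-set size relative
#' to the base MDS: \eqn{(S_0 + K \cdot P_{+1}) / S_0}, reading
#' \eqn{K \cdot P_{+1}} as the estimated increase over the base size.
#'
#' @param base_size MDS size of the unperturbed graph (at least 1).
#' @param K Number of perturbation steps.
#' @param P_plus1 Per-step extra-node probability.
#' @return The predicted ratio (1 when `K = 0`, affine in `K`).
#' @export
predicted_ratio <- function(base_size, K, P_plus1) {
  if (base_size < 1) abort("`base_size` must be at least 1.", class = "multidom_parameter_error")
  (base_size + K * P_plus1) / base_size
}

#' Empirical perturbation estimate for a graph and its dominating set
#'
#' Convenience wrapper assembling `p`, `q` and \eqn{P_{+1}} into one row.
#'
#' @inheritParams estimate_p
#' @param model `"rewire"` or `"indel"`.
#' @param p_d Deletion probability (indel model only).
#' @return A one-row tibble with columns `model`, `p`, `q`, `p_d`,
#'   `p_plus1`.
#' @export
perturbation_estimate <- function(g, mds, model = c("rewire", "indel"), p_d = NA_real_) {
  model <- match.arg(model)
  p <- estimate_p(g, mds)
  q <- estimate_q(g, mds)
  p1 <- switch(model,
               rewire = p_plus1_rewire(p, q),
               indel = p_plus1_indel(p, q, p_d))
  tibble(model = model, p = p, q = q, p_d = p_d, p_plus1 = p1)
}
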