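# Simulation pipelines: perturbation experiments on scale-free layers,
# the k-regular multilayer comparison against the layer recursion, and the
# pairwise / N-layer comparative workflows.

draw_seeds <- function(n, seed) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

new_ratio_table <- function(df, detail, seeds) {
  class(df) <- c("ratio_table", class(df))
  attr(df, "detail") <- detail
  attr(df, "seeds") <- seeds
  df
}

perturbation_ratio_experiment <- function(kind, gamma, n, p_d, K_values, trials,
                                          seed, include_isolated, time_limit) {
  if (is.unsorted(K_values)) {
    abort("Perturbation step counts must be sorted ascending.", class = "multidom_parameter_error")
  }
  seeds <- draw_seeds(trials * (1L + length(K_values)), seed)
  si <- 0L
  rows <- list()
  for (t in seq_len(trials)) {
    si <- si + 1L
    g0 <- gen_powerlaw(n, gamma, seeds[[si]])
    base <- ilp_mds(g0, include_isolated = include_isolated, time_limit = time_limit)
    p <- estimate_p(g0, base$members)
    q <- estimate_q(g0, base$members)
    p1 <- if (kind == "rewire") p_plus1_rewire(p, q) else p_plus1_indel(p, q, p_d)
    g_prev <- g0
    k_prev <- 0L
    for (K in K_values) {
      si <- si + 1L
      if (K > k_prev) {
        g_prev <- if (kind == "rewire") {
          rewire_degree_preserving(g_prev, K - k_prev, seeds[[si]])$graph
        } else {
          perturb_insert_delete(g_prev, K - k_prev, p_d, seeds[[si]])
        }
        k_prev <- K
      }
      s <- fast_mdsm(multilayer(g0, g_prev), include_isolated = include_isolated,
                     time_limit = time_limit)
      rows[[length(rows) + 1L]] <- tibble(
        trial = t, gamma = gamma, p_d = if (kind == "rewire") NA_real_ else p_d,
        K = K, base_size = base$size, mdsm_size = s$size,
        observed_ratio = s$size / base$size,
        predicted_ratio = predicted_ratio(base$size, K, p1),
        p = p, q = q, p_plus1 = p1)
    }
  }
  detail <- dplyr::bind_rows(rows)
  summary <- detail |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("gamma", "p_d", "K")))) |>
    dplyr::summarise(observed_ratio = mean(.data$observed_ratio),
                     predicted_ratio = mean(.data$predicted_ratio),
                     trials = dplyr::n(), .groups = "drop")
  new_ratio_table(summary, detail, seeds)
}

#' Rewiring experiment: multilayer MDS growth under degree-preserving swaps
#'
#' For each trial, generates a scale-free graph `G0`, computes its MDS, and
#' for each `K` pairs `G0` with the graph obtained after `K` cumulative
#' degree-preserving rewirings, computing the two-layer minimum dominating
#' set. Reports the trial-averaged observed size ratio against the
#' linear-theory prediction built from `p`, `q` and the rewiring
#' \eqn{P_{+1}} formula evaluated once on `G0`.
#'
#' @param gamma Power-law exponent of the generated layers.
#' @param n Nodes per layer (default 5000, the published scale).
#' @param K_values Ascending rewiring counts (may start at 0).
#' @param trials Number of independent trials (default 10).
#' @param seed Integer seed for the whole experiment.
#' @inheritParams ilp_mds
#' @return A `ratio_table` tibble with one row per `K`; per-trial rows are
#'   in the `detail` attribute and the derived seeds in `seeds`.
#' @export
rewiring_experiment <- function(gamma, n = 5000, K_values = c(0, 50, 100, 200),
                                trials = 10, seed = 1, include_isolated = TRUE,
                                time_limit = 600) {
  perturbation_ratio_experiment("rewire", gamma, n, NA_real_, K_values, trials,
                                seed, include_isolated, time_limit)
}

#' Insertion/deletion experiment: multilayer MDS growth without degree
#' preservation
#'
#' Same protocol as [rewiring_experiment()], with random edge
#' insertion/deletion steps and the insertion/deletion \eqn{P_{+1}}
#' formula.
#'
#' @inheritParams rewiring_experiment
#' @param p_d Per-step deletion probability.
#' @param step_values Ascending perturbation step counts.
#' @return A `ratio_table` tibble.
#' @export
indel_experiment <- function(gamma, n = 5000, p_d = 0.5,
                             step_values = c(0, 50, 100, 200), trials = 10,
                             seed = 1, include_isolated = TRUE, time_limit = 600) {
  perturbation_ratio_experiment("indel", gamma, n, p_d, step_values, trials,
                                seed, include_isolated, time_limit)
}

#' k-regular multilayer experiment against the layer recursion
#'
#' Per trial, generates `N` independent k-regular layers on one node
#' universe, runs the virtual layer-by-layer construction and the exact
#' multilayer solve, and reports both dominating-set fractions next to the
#' recursion value \eqn{\alpha_N}.
#'
#' @param k Common degree (`n * k` must be even).
#' @param n Nodes per layer.
#' @param N Number of layers.
#' @param trials Number of independent trials.
#' @param seed Integer seed.
#' @inheritParams ilp_mds
#' @return A tibble with one row per trial: sizes, fractions and
#'   `alpha_N`.
#' @export
multilayer_regular_experiment <- function(k, n, N, trials, seed = 1,
                                          include_isolated = TRUE, time_limit = 600) {
  seeds <- draw_seeds(trials * N, seed)
  alpha_n <- alpha_series(k, N)$value[[N]]
  rows <- purrr::map(seq_len(trials), function(t) {
    layers <- lapply(seq_len(N), function(i) gen_k_regular(n, k, seeds[[(t - 1L) * N + i]]))
    net <- multilayer(layers)
    vd <- virtual_dsm(net, include_isolated = include_isolated, time_limit = time_limit)
    md <- fast_mdsm(net, include_isolated = include_isolated, time_limit = time_limit)
    tibble(trial = t, k = k, n = n, N = N,
           virtual_size = vd$size, virtual_fraction = vd$size / n,
           mdsm_size = md$size, mdsm_fraction = md$size / n,
           alpha_N = alpha_n)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seeds") <- seeds
  out
}

#' Pairwise comparative workflow on the common node set
#'
#' Restricts both graphs to their common nodes, then computes the per-layer
#' MDSs (canonical), the two-layer minimum dominating set, the MDSI
#' intersection baseline, and the MDS of the union graph.
#'
#' @param g1,g2 Named undirected igraph objects with a non-empty common
#'   node set.
#' @inheritParams ilp_mds
#' @return A one-row tibble (`pairwise_report`) with counts, sizes,
#'   fractions, wall time, and list-columns of the MDSM/MDSI members.
#' @export
pairwise_workflow <- function(g1, g2, include_isolated = TRUE, time_limit = 600) {
  v <- common_nodes(g1, g2)
  if (length(v) == 0L) {
    abort("The two graphs share no nodes.", class = "multidom_workflow_error")
  }
  t0 <- proc.time()[["elapsed"]]
  i1 <- induced_graph(g1, v); i2 <- induced_graph(g2, v)
  m1 <- ilp_mds(i1, include_isolated = include_isolated, canonical = TRUE,
                time_limit = time_limit)
  m2 <- ilp_mds(i2, include_isolated = include_isolated, canonical = TRUE,
                time_limit = time_limit)
  mm <- fast_mdsm(multilayer(i1, i2), include_isolated = include_isolated,
                  time_limit = time_limit)
  mi <- sort_nodes(intersect(m1$members, m2$members))
  mu <- ilp_mds(union_graph(i1, i2), include_isolated = include_isolated,
                time_limit = time_limit)
  out <- tibble(
    n_common = length(v),
    mds1_size = m1$size, mds2_size = m2$size,
    mdsm_size = mm$size, mdsi_size = length(mi),
    union_mds_size = mu$size,
    mdsm_fraction = mm$size / length(v),
    mdsi_fraction = length(mi) / length(v),
    wall_time = proc.time()[["elapsed"]] - t0,
    mdsm_members = list(mm$members),
    mdsi_members = list(mi))
  class(out) <- c("pairwise_report", class(out))
  out
}

#' N-layer comparative workflow on the common node set
#'
#' Generalises [pairwise_workflow()]: restricts all graphs to the N-way
#' intersection of their node sets, computes each induced layer's MDS
#' (canonical), the N-layer minimum dominating set, and the N-way MDS
#' intersection.
#'
#' @param graphs List of named undirected igraph objects.
#' @inheritParams ilp_mds
#' @param max_layers Soft guard on the number of layers (default 6).
#' @return A one-row tibble with counts, sizes, fractions and member
#'   list-columns.
#' @export
nlayer_workflow <- function(graphs, include_isolated = TRUE, time_limit = 600,
                            max_layers = 6L) {
  if (length(graphs) < 2L || length(graphs) > max_layers) {
    abort(sprintf("Expected between 2 and %d layers.", max_layers),
          class = "multidom_workflow_error")
  }
  v <- sort_nodes(Reduce(intersect, lapply(graphs, node_names)))
  if (length(v) == 0L) {
    abort("The layers share no common nodes.", class = "multidom_workflow_error")
  }
  t0 <- proc.time()[["elapsed"]]
  induced <- lapply(graphs, induced_graph, keep = v)
  mds_list <- lapply(induced, ilp_mds, include_isolated = include_isolated,
                     canonical = TRUE, time_limit = time_limit)
  mm <- ilp_mdsm(multilayer(induced), include_isolated = include_isolated,
                 time_limit = time_limit)
  inter <- sort_nodes(Reduce(intersect, lapply(mds_list, function(m) m$members)))
  tibble(
    n_layers = length(graphs),
    n_common = length(v),
    mds_sizes = list(vapply(mds_list, function(m) m$size, numeric(1))),
    mdsm_size = mm$size,
    intersection_size = length(inter),
    mdsm_fraction = mm$size / length(v),
    intersection_fraction = length(inter) / length(v),
    wall_time = proc.time()[["elapsed"]] - t0,
    mdsm_members = list(mm$members),
    intersection_members = list(inter))
}
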