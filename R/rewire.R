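# Perturbation operators: degree-preserving rewiring (two-edge swaps) and
# random insertion/deletion of edges. Both leave the input graph unchanged
# and are reproducible from the seed.

#' Degree-preserving rewiring
#'
#' Performs `K` rewiring steps. Each step samples two distinct edges
#' \{v_i, v_j\} and \{v_h, v_k\} with four distinct endpoints, uniformly
#' over edge pairs and pairing orientation, such that the replacement edges
#' \{v_i, v_k\} and \{v_h, v_j\} are absent; the sampled edges are deleted
#' and the replacements added. Every node keeps its degree, so the degree
#' distribution is preserved exactly. A candidate draw that violates the
#' constraints is resampled (not counted towards `K`); if no valid pair is
#' found within `max_attempts_per_step`, an error reports the step index.
#'
#' @param g A named undirected igraph object with at least two edges.
#' @param K Number of rewiring steps.
#' @param seed Integer seed.
#' @param max_attempts_per_step Resampling budget per step (default 1000).
#' @return A list with `graph` (the rewired graph) and `record`, a one-row
#'   tibble with `steps_applied`, `failed_attempts` and `seed`.
#' @export
rewire_degree_preserving <- function(g, K, seed, max_attempts_per_step = 1000L) {
  assert_ugraph(g)
  if (igraph::ecount(g) < 2L) {
    abort("Rewiring needs at least two edges.", class = "multidom_infeasible_error")
  }
  em <- igraph::as_edgelist(g)
  m <- nrow(em)
  has <- new.env(parent = emptyenv(), hash = TRUE)
  for (r in seq_len(m)) assign(edge_key(em[r, 1], em[r, 2]), TRUE, envir = has)
  failed <- 0L

  if (K > 0L) {
    withr::with_seed(seed, {
      for (step in seq_len(K)) {
        done <- FALSE
        for (attempt in seq_len(max_attempts_per_step)) {
          ij <- sample.int(m, 2L)
          e1 <- em[ij[[1]], ]; e2 <- em[ij[[2]], ]
          if (runif(1) < 0.5) e2 <- rev(e2)
          vi <- e1[[1]]; vj <- e1[[2]]; vh <- e2[[1]]; vk <- e2[[2]]
          if (length(unique(c(vi, vj, vh, vk))) < 4L ||
              exists(edge_key(vi, vk), envir = has) ||
              exists(edge_key(vh, vj), envir = has)) {
            failed <- failed + 1L
            next
          }
          rm(list = c(edge_key(vi, vj), edge_key(vh, vk)), envir = has)
          assign(edge_key(vi, vk), TRUE, envir = has)
          assign(edge_key(vh, vj), TRUE, envir = has)
          em[ij[[1]], ] <- c(vi, vk)
          em[ij[[2]], ] <- c(vh, vj)
          done <- TRUE
          break
        }
        if (!done) {
          abort(sprintf("No valid rewiring found at step %d within %d attempts.",
                        step, max_attempts_per_step),
                class = "multidom_rewire_error", step = step)
        }
      }
    })
  }
  list(graph = ugraph(edges = em, nodes = node_names(g)),
       record = tibble(steps_applied = as.integer(K),
                       failed_attempts = failed,
                       seed = as.integer(seed)))
}

#' Random insertion and deletion of edges
#'
#' Applies `steps` sequential modifications: each step deletes a uniformly
#' random existing edge with probability `p_d`, and otherwise connects a
#' uniformly random currently non-adjacent node pair.
#'
#' @param g A named undirected igraph object.
#' @param steps Number of modification steps.
#' @param p_d Per-step deletion probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The perturbed graph (the input is not mutated).
#' @export
perturb_insert_delete <- function(g, steps, p_d, seed) {
  assert_ugraph(g)
  if (!is.numeric(p_d) || p_d < 0 || p_d > 1) {
    abort("`p_d` must lie in [0, 1].", class = "multidom_parameter_error")
  }
  nm <- node_names(g)
  n <- length(nm)
  em <- igraph::as_edgelist(g)
  edges <- if (nrow(em)) lapply(seq_len(nrow(em)), function(r) c(em[r, 1], em[r, 2])) else list()
  has <- new.env(parent = emptyenv(), hash = TRUE)
  for (e in edges) assign(edge_key(e[[1]], e[[2]]), TRUE, envir = has)

  if (steps > 0L) {
    withr::with_seed(seed, {
      for (step in seq_len(steps)) {
        m <- length(edges)
        if (runif(1) < p_d) {
          if (m == 0L) {
            abort(sprintf("Deletion requested on an edgeless graph at step %d.", step),
                  class = "multidom_step_error", step = step)
          }
          i <- sample.int(m, 1L)
          e <- edges[[i]]
          rm(list = edge_key(e[[1]], e[[2]]), envir = has)
          edges[[i]] <- edges[[m]]
          edges[[m]] <- NULL
        } else {
          if (m >= n * (n - 1) / 2) {
            abort(sprintf("Insertion requested on a complete graph at step %d.", step),
                  class = "multidom_step_error", step = step)
          }
          repeat {
            uv <- nm[sample.int(n, 2L)]
            if (!exists(edge_key(uv[[1]], uv[[2]]), envir = has)) break
          }
          assign(edge_key(uv[[1]], uv[[2]]), TRUE, envir = has)
          edges[[m + 1L]] <- uv
        }
      }
    })
  }
  edge_mat <- if (length(edges)) do.call(rbind, edges) else NULL
  ugraph(edges = edge_mat, nodes = nm)
}
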