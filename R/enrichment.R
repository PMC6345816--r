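# Functional-class enrichment of a control set against its background:
#   E^C(F) = ln[ (N_p^C(F) / N_p^C) / (N_p(F) / N_p) ]
# where N_p is the background size, N_p(F) the background members of class
# F, N_p^C the control-set size and N_p^C(F) the control-set members of F.

#' Enrichment of a control set in one functional class
#'
#' Natural-log ratio of the control-set fraction of a class to its
#' background fraction. Zero means no bias; a class entirely absent from
#' the control set yields `-Inf` with `depleted = TRUE` (the formula has no
#' pseudocount).
#'
#' @param n_p Background size (total common nodes), at least 1.
#' @param n_p_f Background members of the class, at least 1.
#' @param n_p_c Control-set size, at least 1.
#' @param n_p_c_f Control-set members of the class.
#' @param control Label of the control-set kind (e.g. `"MDSM"` or
#'   `"MDSI"`).
#' @param class_label Functional-class label.
#' @return A one-row tibble with the four counts, `score` and `depleted`.
#' @examples
#' enrichment(100, 20, 10, 4)$score  # log(2)
#' @export
enrichment <- function(n_p, n_p_f, n_p_c, n_p_c_f, control = "MDSM",
                       class_label = NA_character_) {
  counts <- c(n_p = n_p, n_p_f = n_p_f, n_p_c = n_p_c, n_p_c_f = n_p_c_f)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("Counts must be non-negative integers.", class = "multidom_validation_error")
  }
  if (n_p < 1 || n_p_f < 1 || n_p_c < 1) {
    abort("`n_p`, `n_p_f` and `n_p_c` must be at least 1.", class = "multidom_validation_error")
  }
  if (n_p_c_f > n_p_c || n_p_c > n_p || n_p_c_f > n_p_f || n_p_f > n_p) {
    abort("Count invariants violated: need n_p_c_f <= n_p_c <= n_p and n_p_c_f <= n_p_f <= n_p.",
          class = "multidom_validation_error")
  }
  score <- if (n_p_c_f == 0) -Inf else log((n_p_c_f / n_p_c) / (n_p_f / n_p))
  tibble(control = control, class = class_label,
         n_p = as.integer(n_p), n_p_f = as.integer(n_p_f),
         n_p_c = as.integer(n_p_c), n_p_c_f = as.integer(n_p_c_f),
         score = score, depleted = n_p_c_f == 0)
}

#' Enrichment of control sets across all annotated functional classes
#'
#' Assembles the enrichment counts from a node-to-class annotation table
#' for each (control set, class) combination. A node carrying several
#' class labels contributes to every one of its classes; the background
#' count `n_p` counts nodes once. Classes with no background members are
#' skipped with a message.
#'
#' @param annotation A data frame whose first two columns are node
#'   identifier and class label (one row per node-class pair).
#' @param control_sets Named list of character vectors (e.g.
#'   `list(MDSM = ..., MDSI = ...)`), each a subset of `background`.
#' @param background Character vector of background node identifiers (the
#'   common node set).
#' @return A tibble with one row per control set and class.
#' @export
enrichment_batch <- function(annotation, control_sets, background) {
  annotation <- as.data.frame(annotation)
  if (ncol(annotation) < 2L) {
    abort("`annotation` needs node and class columns.", class = "multidom_validation_error")
  }
  ann <- unique(data.frame(node = as.character(annotation[[1]]),
                           class = as.character(annotation[[2]])))
  background <- sort_nodes(background)
  if (is.null(names(control_sets)) || any(!nzchar(names(control_sets)))) {
    abort("`control_sets` must be a named list.", class = "multidom_validation_error")
  }
  for (nmset in names(control_sets)) {
    if (!all(control_sets[[nmset]] %in% background)) {
      abort(sprintf("Control set '%s' is not contained in the background.", nmset),
            class = "multidom_validation_error")
    }
  }
  ann <- ann[ann$node %in% background, , drop = FALSE]
  n_p <- length(background)
  rows <- list()
  for (cl in sort(unique(as.character(annotation[[2]])), method = "radix")) {
    members_f <- unique(ann$node[ann$class == cl])
    if (length(members_f) == 0L) {
      message(sprintf("Class '%s' has no background members; skipped.", cl))
      next
    }
    for (nmset in names(control_sets)) {
      cs <- unique(as.character(control_sets[[nmset]]))
      rows[[length(rows) + 1L]] <- enrichment(
        n_p = n_p, n_p_f = length(members_f),
        n_p_c = length(cs), n_p_c_f = sum(cs %in% members_f),
        control = nmset, class_label = cl)
    }
  }
  dplyr::bind_rows(rows)
}

#' Read a node-to-class annotation table
#'
#' Tab-separated, two columns (`node_id`, `class_label`), one row per
#' node-class pair, no header; `#` lines are comments.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `node` and `class`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "multidom_io_error")
  }
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character")
  tibble(node = df[[1]], class = df[[2]])
}

#' Compare enrichment scores between two groups of network pairs
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of per-pair
#' enrichment scores; a pragmatic significance screen for contrasting
#' lineage groups, reported as metadata rather than as a replication claim.
#'
#' @param scores_a,scores_b Numeric vectors of finite enrichment scores.
#' @return A one-row tibble with group sizes, medians, `statistic` and
#'   `p_value`.
#' @export
compare_enrichment_groups <- function(scores_a, scores_b) {
  scores_a <- scores_a[is.finite(scores_a)]
  scores_b <- scores_b[is.finite(scores_b)]
  ht <- stats::wilcox.test(scores_a, scores_b, exact = FALSE)
  tibble(n_a = length(scores_a), n_b = length(scores_b),
         median_a = stats::median(scores_a), median_b = stats::median(scores_b),
         statistic = unname(ht$statistic), p_value = ht$p.value)
}
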