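# Graph model: simple undirected igraph objects with character vertex names.
# All deterministic iteration is in byte-wise lexicographic order of names.

sort_nodes <- function(x) sort(unique(as.character(x)), method = "radix")

edge_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")

#' Construct a simple undirected graph from an edge table
#'
#' Builds the package's working graph representation: a simple undirected
#' [igraph][igraph::igraph-package] graph whose vertices carry character
#' names. Duplicate edges (in either orientation) collapse to one edge;
#' self-loops are rejected. Vertices are stored in lexicographic name order
#' so that all downstream tie-breaking is reproducible.
#'
#' @param edges A two-column matrix or data frame of edge endpoints
#'   (coerced to character), or `NULL` for an edgeless graph.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @return An undirected, simple, named igraph object.
#' @examples
#' g <- ugraph(rbind(c("a", "b"), c("b", "c")), nodes = "d")
#' igraph::vcount(g)
#' @export
ugraph <- function(edges = NULL, nodes = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (length(edges) == 0L) {
      edges <- NULL
    } else {
      if (ncol(edges) < 2L) abort("`edges` must have two columns.", class = "multidom_validation_error")
      edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
      if (any(edges[, 1] == edges[, 2])) {
        abort("Self-loops are not allowed.", class = "multidom_validation_error")
      }
      edges <- edges[!duplicated(edge_key(edges[, 1], edges[, 2])), , drop = FALSE]
    }
  }
  all_nodes <- sort_nodes(c(as.character(nodes %||% character()), as.vector(edges %||% character())))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  g
}

node_names <- function(g) igraph::V(g)$name

assert_ugraph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g) || igraph::is_directed(g) ||
      is.null(igraph::V(g)$name)) {
    abort(sprintf("`%s` must be an undirected igraph with named vertices.", arg),
          class = "multidom_validation_error")
  }
  invisible(g)
}

#' Read a graph from a plain-text edge list
#'
#' One edge per line as two whitespace-separated node identifiers. A line
#' with a single token declares an isolated node; lines starting with `#`
#' are comments. Duplicate lines (in either orientation) collapse to a
#' single edge.
#'
#' @param path Path to an edge-list file.
#' @return A simple undirected named igraph object.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "multidom_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  from <- character(); to <- character(); singles <- character()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (nchar(line) == 0L || startsWith(line, "#")) next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) {
      abort(sprintf("Malformed line %d in %s", i, path), class = "multidom_parse_error")
    } else if (length(toks) == 1L) {
      singles <- c(singles, toks[[1]])
    } else {
      if (toks[[1]] == toks[[2]]) {
        abort(sprintf("Self-loop '%s' on line %d of %s", toks[[1]], i, path),
              class = "multidom_validation_error")
      }
      from <- c(from, toks[[1]]); to <- c(to, toks[[2]])
    }
  }
  ugraph(edges = if (length(from)) cbind(from, to), nodes = singles)
}

#' Write a graph as a plain-text edge list
#'
#' Emits one line per edge (`u<TAB>v`, endpoints in lexicographic order) and
#' one single-token line per isolated node, so that
#' `read_edge_list(write_edge_list(g))` reproduces `g` exactly.
#'
#' @param g A named undirected igraph object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(g, path) {
  assert_ugraph(g)
  em <- igraph::as_edgelist(g)
  lines <- character()
  if (nrow(em) > 0L) {
    a <- pmin(em[, 1], em[, 2]); b <- pmax(em[, 1], em[, 2])
    ord <- order(a, b, method = "radix")
    lines <- paste(a[ord], b[ord], sep = "\t")
  }
  iso <- node_names(g)[igraph::degree(g) == 0L]
  lines <- c(lines, sort_nodes(iso))
  tryCatch(writeLines(lines, path),
           error = function(e) abort(sprintf("Cannot write %s: %s", path, conditionMessage(e)),
                                     class = "multidom_io_error"))
  invisible(path)
}

#' Induced subgraph on a set of node identifiers
#'
#' Restricts `g` to `keep`: the result has node set `V(g)` intersected with
#' `keep` and every edge of `g` whose two endpoints survive. Identifiers in
#' `keep` that are absent from `g` are ignored.
#'
#' @param g A named undirected igraph object.
#' @param keep Character vector of node identifiers to retain.
#' @return The induced subgraph.
#' @export
induced_graph <- function(g, keep) {
  assert_ugraph(g)
  keep <- intersect(node_names(g), as.character(keep))
  igraph::induced_subgraph(g, vids = keep)
}

#' Common nodes of two graphs
#'
#' @param g1,g2 Named undirected igraph objects.
#' @return Sorted character vector: the intersection of the two node sets.
#' @export
common_nodes <- function(g1, g2) {
  assert_ugraph(g1, "g1"); assert_ugraph(g2, "g2")
  sort_nodes(intersect(node_names(g1), node_names(g2)))
}

#' Union of two graphs
#'
#' Node set is the union of the node sets, edge set the union of the edge
#' sets (an edge present in both layers appears once).
#'
#' @param g1,g2 Named undirected igraph objects.
#' @return A simple undirected named igraph object.
#' @export
union_graph <- function(g1, g2) {
  assert_ugraph(g1, "g1"); assert_ugraph(g2, "g2")
  em <- rbind(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  ugraph(edges = if (nrow(em)) em, nodes = c(node_names(g1), node_names(g2)))
}

#' Degree of a node
#'
#' @param g A named undirected igraph object.
#' @param v A node identifier present in `g`.
#' @return Integer count of incident edges.
#' @export
node_degree <- function(g, v) {
  assert_ugraph(g)
  if (!v %in% node_names(g)) {
    abort(sprintf("Unknown node '%s'", v), class = "multidom_lookup_error")
  }
  unname(igraph::degree(g, v))
}
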