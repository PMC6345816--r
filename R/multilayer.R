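# Multilayer container: an ordered list of undirected layers over a shared
# universe of node identifiers. Layers are never physically coupled.

#' Assemble a multilayer network
#'
#' A multilayer network here is an ordered collection of simple undirected
#' graphs ("layers") whose node sets may overlap partially or completely;
#' there are no inter-layer edges. The universe is the union of the layer
#' node sets.
#'
#' @param ... Named undirected igraph objects, or a single list of them.
#' @return An object of class `multilayer`: a list with elements `layers`
#'   (list of igraphs) and `universe` (sorted character vector).
#' @examples
#' net <- multilayer(ugraph(rbind(c("a", "b"))), ugraph(rbind(c("b", "c"))))
#' universe(net)
#' @export
multilayer <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && !igraph::is_igraph(layers[[1]])) {
    layers <- layers[[1]]
  }
  if (length(layers) < 1L) {
    abort("A multilayer network needs at least one layer.", class = "multidom_validation_error")
  }
  for (i in seq_along(layers)) assert_ugraph(layers[[i]], sprintf("layer %d", i))
  structure(
    list(layers = layers,
         universe = sort_nodes(unlist(lapply(layers, node_names)))),
    class = "multilayer"
  )
}

as_multilayer <- function(x) {
  if (inherits(x, "multilayer")) return(x)
  if (igraph::is_igraph(x)) return(multilayer(x))
  multilayer(x)
}

#' @export
print.multilayer <- function(x, ...) {
  cat(sprintf("<multilayer network: %d layer(s), %d nodes in universe>\n",
              length(x$layers), length(x$universe)))
  for (i in seq_along(x$layers)) {
    g <- x$layers[[i]]
    cat(sprintf("  layer %d: %d nodes, %d edges\n", i, igraph::vcount(g), igraph::ecount(g)))
  }
  invisible(x)
}

#' Number of layers
#' @param net A `multilayer` object.
#' @return Integer layer count.
#' @export
n_layers <- function(net) length(as_multilayer(net)$layers)

#' Node universe of a multilayer network
#' @param net A `multilayer` object.
#' @return Sorted character vector of all node identifiers.
#' @export
universe <- function(net) as_multilayer(net)$universe
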