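# Shared fixture builders: everything is generated in code at test time.

# Erdos-Renyi-style random graph with sortable node names
er_graph <- function(n, p, seed, prefix = "v") {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
  g
}

path_graph <- function(nodes) {
  ugraph(edges = cbind(nodes[-length(nodes)], nodes[-1]))
}

star_graph <- function(center, leaves) {
  ugraph(edges = cbind(center, leaves))
}

cycle_graph <- function(nodes) {
  ugraph(edges = cbind(nodes, c(nodes[-1], nodes[[1]])))
}

# discrete power-law exponent, maximum-likelihood (Clauset-style) estimate
mle_gamma <- function(d, kmin = 2) {
  d <- d[d >= kmin]
  1 + length(d) / sum(log(d / (kmin - 0.5)))
}

degree_sorted <- function(g) sort(as.integer(igraph::degree(g)))
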