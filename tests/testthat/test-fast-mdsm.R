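test_that("degree-1 preprocessing fires the pendant rules as hand-traced", {
  # layer 1: star x-(p,q); layer 2: edge x-y. p, q are absent from layer 2,
  # so the layer-1 pendant rule forces x and observes p and q.
  net <- multilayer(star_graph("x", c("p", "q")), ugraph(rbind(c("x", "y"))))
  pp <- fast_mdsm_preprocess(net)
  expect_identical(pp$v_m, "x")
  expect_true(all(c("p", "q") %in% pp$observed_1))
  expect_true("y" %in% pp$observed_2)
  r <- fast_mdsm(net)
  expect_identical(r$members, "x")
  expect_identical(r$forced_subset, "x")

  # both layers one shared pendant edge: the joint rule fires, and the
  # lexicographic scan reaches a first
  net2 <- multilayer(ugraph(rbind(c("a", "b"))), ugraph(rbind(c("a", "b"))))
  pp2 <- fast_mdsm_preprocess(net2)
  expect_identical(pp2$v_m, "a")
  expect_true("b" %in% pp2$observed_1 && "b" %in% pp2$observed_2)

  # no degree-1 nodes anywhere: nothing can fire
  net3 <- multilayer(gen_k_regular(8, 3, 1), gen_k_regular(8, 3, 2))
  expect_length(fast_mdsm_preprocess(net3)$v_m, 0)

  expect_error(fast_mdsm_preprocess(multilayer(gen_k_regular(6, 2, 1))),
               class = "multidom_arity_error")
})

test_that("preprocessing never changes the optimal size", {
  # scale-free pairs related by rewiring, the regime the preprocessing targets
  for (s in 1:10) {
    g0 <- gen_powerlaw(100, 2.5, 3000 + s)
    gk <- rewire_degree_preserving(g0, 30, 4000 + s)$graph
    net <- multilayer(g0, gk)
    f <- fast_mdsm(net)
    p <- ilp_mdsm(net)
    expect_equal(f$size, p$size)
    expect_true(is_dominating_set(net, f$members))
    expect_true(all(f$forced_subset %in% f$members))
  }
  # and on loosely related random layers with partial node overlap
  for (s in 1:10) {
    g1 <- er_graph(12, 0.25, 5000 + s)
    g2 <- er_graph(12, 0.25, 6000 + s, prefix = "w")
    # overlap half the nodes by renaming
    nm <- igraph::V(g2)$name
    igraph::V(g2)$name <- c(igraph::V(g1)$name[1:6], nm[7:12])
    net <- multilayer(g1, g2)
    expect_equal(fast_mdsm(net)$size, brute_force_mdsm(net)$size)
  }
})

test_that("degenerate multilayer families reach their exact sizes", {
  g <- gen_powerlaw(60, 2.5, 77)
  expect_equal(fast_mdsm(multilayer(g, g))$size, ilp_mds(g)$size)

  d1 <- er_graph(8, 0.3, 1, prefix = "a")
  d2 <- er_graph(8, 0.3, 2, prefix = "b")
  expect_equal(fast_mdsm(multilayer(d1, d2))$size,
               ilp_mds(d1)$size + ilp_mds(d2)$size)

  expect_equal(fast_mdsm(multilayer(g))$size, ilp_mds(g)$size)
})

test_that("the MDS intersection baseline is contained in both optima", {
  g <- gen_powerlaw(50, 2.5, 5)
  r <- mdsi(g, g)
  expect_equal(r$size, ilp_mds(g, canonical = TRUE)$size)

  for (s in 1:5) {
    g1 <- er_graph(12, 0.25, 7000 + s)
    g2 <- er_graph(12, 0.25, 7100 + s)
    r <- mdsi(g1, g2)
    m1 <- ilp_mds(g1, canonical = TRUE)
    m2 <- ilp_mds(g2, canonical = TRUE)
    expect_lte(r$size, min(m1$size, m2$size))
    expect_true(all(r$members %in% m1$members))
    expect_true(all(r$members %in% m2$members))
  }

  # constructed pair whose canonical per-layer optima share exactly one node
  g1 <- star_graph("a", c("b", "c", "d", "e"))
  g2 <- ugraph(rbind(c("a", "b"), c("c", "d"), c("c", "e")))
  expect_equal(brute_force_mds(g1)$size, 1)
  expect_equal(brute_force_mds(g2)$size, 2)
  r <- mdsi(g1, g2)
  expect_identical(r$members, "a")
})
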