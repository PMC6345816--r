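test_that("k-regular layer recursion matches hand-evaluated values", {
  expect_equal(alpha_series(4, 1)$value, 0.2)
  for (k in 1:20) expect_equal(alpha_series(k, 1)$value, 1 / (k + 1))
  expect_equal(alpha_series(2, 2)$value[[2]], 35 / 81, tolerance = 1e-12)

  s <- alpha_series(3, 10)$value
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
  expect_error(alpha_series(0, 1), class = "multidom_parameter_error")
})

test_that("assortative layer recursion matches its closed form and limits", {
  z2 <- pi^2 / 6
  b <- beta_series(2, 1)
  expect_equal(b$value, (z2 - 1) / z2, tolerance = 1e-6)

  # heavy truncation: k = 1 dominates, so beta_1 -> 1/2
  expect_equal(beta_series(50, 1)$value, 0.5, tolerance = 1e-9)

  s <- beta_series(2.5, 6)$value
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))

  # truncation refinement: doubling k_max leaves beta_1 unchanged within tol
  expect_lt(abs(beta_series(2.5, 1)$value - beta_series(2.5, 1, k_max = 2e5)$value),
            1e-12)
  expect_lt(abs(beta_series(2, 1)$value - beta_series(2, 1, k_max = 2e5)$value),
            1e-12)

  expect_error(beta_series(1, 1), class = "multidom_divergence_error")
})

test_that("virtual layer-by-layer construction dominates every layer", {
  g <- gen_k_regular(30, 2, 1)
  net_same <- multilayer(g, g)
  vd <- virtual_dsm(net_same)
  expect_equal(vd$size, ilp_mds(g)$size)   # second layer adds nothing

  for (s in 1:5) {
    net <- multilayer(gen_k_regular(30, 2, 10 + s), gen_k_regular(30, 2, 20 + s),
                      gen_k_regular(30, 2, 30 + s))
    vd <- virtual_dsm(net)
    expect_true(is_dominating_set(net, vd$members))
    expect_lte(fast_mdsm(net)$size, vd$size)   # it is a DSM, not necessarily minimum
  }
})

test_that("edge-endpoint and double-domination probabilities", {
  st <- star_graph("x", c("a", "b", "c"))
  expect_equal(estimate_p(st, "x"), 0.5)
  expect_equal(estimate_p(st, igraph::V(st)$name), 1.0)
  expect_equal(estimate_p(st, character(0)), 0.0)
  expect_error(estimate_p(ugraph(nodes = c("a", "b")), "a"),
               class = "multidom_undefined_error")

  expect_equal(estimate_q(st, "x"), 0)     # each leaf has exactly one set neighbour
  tri <- ugraph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(estimate_q(tri, c("a", "b")), 1)
  expect_equal(estimate_q(ugraph(nodes = c("a", "b", "c")), "a"), 0)
  expect_error(estimate_q(tri, c("a", "b", "c")), class = "multidom_undefined_error")
})

test_that("perturbation probability formulas are exact pure functions", {
  expect_equal(p_plus1_rewire(0.5, 0), 0.375)
  expect_equal(p_plus1_rewire(0, 0.3), 0)
  expect_equal(p_plus1_rewire(0.7, 1), 0)

  expect_equal(p_plus1_indel(0.5, 0, 1), 0.5)
  expect_equal(p_plus1_indel(0.5, 0.2, 0), 0)
  expect_equal(p_plus1_indel(1, 0, 0.7), 0)
  expect_error(p_plus1_rewire(1.2, 0), class = "multidom_parameter_error")
  expect_error(p_plus1_indel(0.5, 0, -0.1), class = "multidom_parameter_error")

  expect_equal(predicted_ratio(100, 0, 0.375), 1.0)
  expect_equal(predicted_ratio(100, 50, 0.375), 1.1875)
  k <- 0:20
  r <- predicted_ratio(50, k, 0.2)
  expect_equal(diff(r), rep(0.2 / 50, 20))   # affine in K
})

test_that("single-rewiring size jumps occur at the order predicted", {
  # over many single rewirings the frequency of one-node growth should be of
  # the same order as the per-step estimate (loose band: the estimate ignores
  # the degree-preservation constraint)
  g0 <- gen_powerlaw(150, 2.5, 31)
  base <- ilp_mds(g0)
  est <- perturbation_estimate(g0, base$members, "rewire")
  jumps <- vapply(1:40, function(s) {
    g1 <- rewire_degree_preserving(g0, 1, 5000 + s)$graph
    fast_mdsm(multilayer(g0, g1))$size - base$size
  }, numeric(1))
  expect_true(all(jumps >= 0))
  freq <- mean(jumps >= 1)
  expect_lt(abs(freq - est$p_plus1), 0.25)
})
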