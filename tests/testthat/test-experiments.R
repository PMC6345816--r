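test_that("rewiring experiment table has the required shape", {
  rt <- rewiring_experiment(2.5, n = 150, K_values = c(0, 10, 30), trials = 2, seed = 3)
  expect_s3_class(rt, "ratio_table")
  expect_equal(rt$observed_ratio[rt$K == 0], 1.0)
  expect_true(all(rt$observed_ratio >= 1))
  expect_gte(rt$observed_ratio[rt$K == 30], rt$observed_ratio[rt$K == 0])
  expect_equal(rt$trials, rep(2L, 3))
  detail <- attr(rt, "detail")
  expect_equal(nrow(detail), 6)
  expect_true(all(detail$observed_ratio >= 1))
  expect_length(attr(rt, "seeds"), 2 * (1 + 3))
  expect_error(rewiring_experiment(2.5, n = 100, K_values = c(10, 0), trials = 1, seed = 1),
               class = "multidom_parameter_error")
})

test_that("insertion/deletion experiment tracks its prediction more closely", {
  ind <- indel_experiment(2.5, n = 150, p_d = 0.5, step_values = c(0, 10, 30),
                          trials = 2, seed = 3)
  expect_equal(ind$observed_ratio[ind$K == 0], 1.0)
  expect_true(all(ind$observed_ratio >= 1))

  # pure insertions cannot push the pair below the base requirement
  ins <- indel_experiment(2.5, n = 120, p_d = 0, step_values = c(0, 15),
                          trials = 2, seed = 7)
  expect_true(all(ins$observed_ratio >= 1))
})

test_that("k-regular experiment agrees with the recursion at unit scale", {
  res <- multilayer_regular_experiment(2, 60, 2, trials = 5, seed = 9)
  expect_equal(nrow(res), 5)
  expect_true(all(res$mdsm_fraction <= res$virtual_fraction))
  rel_err <- abs(mean(res$virtual_fraction) - res$alpha_N[[1]]) / res$alpha_N[[1]]
  expect_lt(rel_err, 0.15)

  # single layer: the virtual construction is exactly one MDS
  r1 <- multilayer_regular_experiment(2, 30, 1, trials = 2, seed = 4)
  expect_equal(r1$virtual_size, r1$mdsm_size)
  expect_equal(r1$alpha_N, rep(1 / 3, 2))
})

test_that("pairwise workflow computes the full comparative report", {
  g <- gen_powerlaw(60, 2.5, 21)
  same <- pairwise_workflow(g, g)
  expect_equal(same$mds1_size, same$mds2_size)
  expect_equal(same$mds1_size, same$mdsm_size)
  expect_equal(same$mdsm_size, same$mdsi_size)

  for (s in 1:10) {
    g1 <- er_graph(10, 0.3, 8000 + s)
    g2 <- er_graph(10, 0.3, 8100 + s)
    rep <- pairwise_workflow(g1, g2)
    expect_lte(rep$mdsi_size, min(rep$mds1_size, rep$mds2_size))
    expect_gte(rep$mdsm_size, max(rep$mds1_size, rep$mds2_size))
    expect_lte(rep$mdsm_size, rep$mds1_size + rep$mds2_size)
    expect_lte(rep$union_mds_size, rep$mdsm_size)
    # the multilayer size is exact
    net <- multilayer(g1, g2)
    expect_equal(rep$mdsm_size, brute_force_mdsm(net)$size)
  }

  expect_error(pairwise_workflow(ugraph(nodes = "a"), ugraph(nodes = "b")),
               class = "multidom_workflow_error")
})

test_that("N-layer workflow equals the oracle and is monotone in layers", {
  layers <- lapply(1:6, function(s) er_graph(10, 0.3, 8200 + s))
  r6 <- nlayer_workflow(layers)
  expect_equal(r6$mdsm_size, brute_force_mdsm(multilayer(layers))$size)
  expect_lte(r6$intersection_size, min(unlist(r6$mds_sizes)))

  sizes <- vapply(2:6, function(k) nlayer_workflow(layers[1:k])$mdsm_size, numeric(1))
  expect_true(all(diff(sizes) >= 0))

  same <- nlayer_workflow(list(layers[[1]], layers[[1]], layers[[1]]))
  expect_equal(same$mdsm_size, ilp_mds(layers[[1]])$size)

  expect_error(nlayer_workflow(layers[1]), class = "multidom_workflow_error")
  expect_error(nlayer_workflow(c(layers, layers[1])), class = "multidom_workflow_error")
  expect_equal(nlayer_workflow(c(layers, layers[1]), max_layers = 7)$n_layers, 7)
})

test_that("experiment plots build without evaluation errors", {
  rt <- rewiring_experiment(2.5, n = 120, K_values = c(0, 10), trials = 1, seed = 2)
  p1 <- autoplot(rt)
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(alpha_series(4, 6))
  expect_s3_class(p2, "ggplot")
})
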