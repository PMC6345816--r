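test_that("brute-force oracle solves canonical small cases", {
  st <- star_graph("x", c("p", "q", "r", "s"))
  r <- brute_force_mds(st)
  expect_equal(r$size, 1)
  expect_identical(r$members, "x")

  expect_equal(brute_force_mds(path_graph(c("a", "b", "c", "d")))$size, 2)
  expect_equal(brute_force_mds(cycle_graph(letters[1:6]))$size, 2)
  expect_error(brute_force_mds(er_graph(26, 0.2, 1)), class = "multidom_size_error")
})

test_that("brute-force multilayer oracle matches its defining cases", {
  g <- er_graph(10, 0.3, 42)
  same <- brute_force_mdsm(multilayer(g, g))
  expect_equal(same$size, brute_force_mds(g)$size)

  disj <- multilayer(ugraph(rbind(c("a", "b"))), ugraph(rbind(c("c", "d"))))
  expect_equal(brute_force_mdsm(disj)$size, 2)

  over <- multilayer(ugraph(rbind(c("a", "b"))), ugraph(rbind(c("b", "c"))))
  r <- brute_force_mdsm(over)
  expect_equal(r$size, 1)
  expect_true(is_dominating_set(over, r$members))
})

test_that("single-layer ILP equals the exhaustive oracle on a random battery", {
  expect_equal(ilp_mds(star_graph("c", sprintf("l%d", 1:9)))$size, 1)
  for (s in 1:30) {
    g <- er_graph(10, 0.25, 500 + s)
    expect_equal(ilp_mds(g)$size, brute_force_mds(g)$size)
    expect_true(is_dominating_set(g, ilp_mds(g)$members))
  }
})

test_that("isolated nodes are forced in, or excluded, by the variant flag", {
  iso <- ugraph(nodes = c("a", "b", "c"))
  expect_equal(ilp_mds(iso, include_isolated = TRUE)$size, 3)
  expect_equal(ilp_mds(iso, include_isolated = FALSE)$size, 0)

  mixed <- ugraph(rbind(c("a", "b")), nodes = "z")
  expect_equal(ilp_mds(mixed, include_isolated = TRUE)$size, 2)
  expect_equal(ilp_mds(mixed, include_isolated = FALSE)$size, 1)
  expect_equal(brute_force_mds(mixed, include_isolated = FALSE)$size, 1)
})

test_that("multilayer ILP equals the oracle and respects forced nodes", {
  for (s in 1:30) {
    net <- multilayer(er_graph(8, 0.3, 600 + s), er_graph(8, 0.3, 700 + s))
    ri <- ilp_mdsm(net)
    rb <- brute_force_mdsm(net)
    expect_equal(ri$size, rb$size)
    expect_true(is_dominating_set(net, ri$members))
  }
  g <- er_graph(10, 0.3, 42)
  expect_equal(ilp_mdsm(multilayer(g))$size, ilp_mds(g)$size)
  expect_equal(ilp_mdsm(multilayer(g, g, g))$size, ilp_mds(g)$size)

  r <- ilp_mdsm(multilayer(g), forced = "v01")
  expect_true("v01" %in% r$members)
  expect_error(ilp_mdsm(multilayer(g), forced = "zzz"),
               class = "multidom_validation_error")
})

test_that("canonical solves are reproducible and size-preserving", {
  g <- cycle_graph(letters[1:6])   # many optimal 2-sets
  r1 <- ilp_mds(g, canonical = TRUE)
  r2 <- ilp_mds(g, canonical = TRUE)
  expect_identical(r1$members, r2$members)
  expect_equal(r1$size, brute_force_mds(g)$size)
  for (s in 1:5) {
    gg <- er_graph(12, 0.2, 800 + s)
    expect_equal(ilp_mds(gg, canonical = TRUE)$size, ilp_mds(gg)$size)
  }
})

test_that("size bounds hold and are tight in the degenerate families", {
  g <- er_graph(10, 0.3, 9)
  ident <- multilayer(g, g)
  b <- prop1_bounds(ident)
  expect_equal(b$upper, 2 * b$lower)
  expect_equal(ilp_mdsm(ident)$size, b$lower)

  disj <- multilayer(er_graph(8, 0.3, 1, prefix = "a"), er_graph(8, 0.3, 2, prefix = "b"))
  bd <- prop1_bounds(disj)
  expect_equal(ilp_mdsm(disj)$size, bd$upper)

  for (s in 1:10) {
    net <- multilayer(er_graph(9, 0.3, 900 + s), er_graph(9, 0.3, 950 + s))
    bb <- prop1_bounds(net)
    sz <- fast_mdsm(net)$size
    expect_gte(sz, bb$lower)
    expect_lte(sz, bb$upper)
  }
})

test_that("with enough distinct sparse layers the multilayer MDS approaches n - d_min", {
  # minimum degree 2 on 8 nodes: once many distinct 2-regular layers pile up,
  # no small set can dominate all of them simultaneously
  run <- function(N, reps, seed) {
    withr::with_seed(seed, {
      mean(vapply(seq_len(reps), function(r) {
        layers <- lapply(seq_len(N), function(i) gen_k_regular(8, 2, sample.int(1e6, 1)))
        brute_force_mdsm(multilayer(layers))$size >= 6
      }, logical(1)))
    })
  }
  p_few <- run(5, 4, 11)
  p_many <- run(1500, 4, 13)
  expect_gte(p_many, 0.75)
  expect_gt(p_many, p_few)
})

test_that("result accessors expose a tidy view", {
  g <- star_graph("x", c("p", "q"))
  r <- ilp_mds(g)
  td <- tidy(r)
  expect_identical(td$node, r$members)
  gl <- glance(r)
  expect_equal(gl$size, r$size)
  expect_identical(gl$solver_status, "optimal")
})
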