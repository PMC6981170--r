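test_that("action vanishes at rest and matches the single-segment closed form", {
  net <- pancreas_net()
  atlas <- pancreas_atlas_n4()
  p <- atlas$params
  s1 <- Filter(function(s) s$class == "stable", atlas$states)[[1]]
  const <- matrix(rep(unname(s1$x), each = 11), nrow = 11)
  expect_equal(path_action(const, net, p, dt = 0.1), 0)

  # 1-gene, 2-point path 0 -> 0.1 with dt = 1:
  # S = 1/4 * (0.1 - (f(0.1) + f(0))/2)^2, f(0.1) = 16e-4/1.0016 - 0.1
  toy <- toy_fixtures()$one_gene$network
  f01 <- 16 * 1e-4 / 1.0016 - 0.1
  expected <- 0.25 * (0.1 - f01 / 2)^2
  expect_equal(path_action(matrix(c(0, 0.1)), toy, hill_params(), dt = 1),
               expected, tolerance = 1e-12)
  expect_equal(expected, 0.005565, tolerance = 1e-4)
  expect_error(path_action(matrix(c(0, NA)), toy, hill_params(), dt = 1),
               "non-finite")
})

test_that("a flow-following path is nearly free and its reversal is not", {
  net <- pancreas_net()
  atlas <- pancreas_atlas_n4()
  cfg <- landscape_config()
  saddle <- Filter(function(s) s$class == "transition", atlas$states)[[1]]
  start <- unstable_perturbations(saddle, cfg)[1, ]
  tr <- integrate_trajectory(net, start, atlas$params, cfg)
  # re-discretize the trajectory on a uniform 101-point grid
  idx <- round(seq(1, nrow(tr$states), length.out = 101))
  pts <- tr$states[idx, ]
  dts <- diff(tr$times[idx])
  dt <- mean(dts)
  act <- path_action(pts, net, atlas$params, dt)
  expect_lt(act, 1e-3)
  expect_gt(path_action(pts[101:1, ], net, atlas$params, dt), 10 * act)
})

test_that("uphill toy action converges to the quadrature barrier", {
  toy <- toy_fixtures()$one_gene$network
  barrier <- toy_barrier(4, 0, 0.5)
  expect_equal(barrier, 0.0585, tolerance = 1e-3)
  sol <- minimize_action(toy, hill_params(), 0, 0.5, mpp_config(40, 400))
  expect_true(sol$converged)
  expect_equal(sol$action, barrier, tolerance = 5e-3)
  expect_lte(sol$action, sol$initial_action)
})

test_that("degenerate and near-equilibrium endpoint requests are flagged", {
  toy <- toy_fixtures()$one_gene$network
  expect_error(minimize_action(toy, hill_params(), 0.5, 0.5), "degenerate")
  expect_warning(minimize_action(toy, hill_params(), 0.2, 0.5,
                                 mpp_config(5, 20)),
                 "not an equilibrium")
})

test_that("endpoints are clamped exactly and actions converge with refinement", {
  toy <- toy_fixtures()$one_gene$network
  sols <- lapply(c(50, 100, 200), function(N)
    minimize_action(toy, hill_params(), 0, 0.5, mpp_config(10, N)))
  for (s in sols) {
    expect_identical(unname(s$points[1, 1]), 0)
    expect_identical(unname(s$points[nrow(s$points), 1]), 0.5)
  }
  # successive mesh refinements shrink toward a common limit
  acts <- vapply(sols, `[[`, 0, "action")
  gaps <- abs(diff(acts))
  expect_lt(gaps[2], gaps[1])
  expect_lt(gaps[1], 1e-3)
})

test_that("action is invariant under consistent gene permutation", {
  net <- pancreas_net()
  perm <- c(2, 4, 1, 6, 3, 8, 5, 7)
  pnet <- permute_network(net, perm)
  set.seed(3)
  pts <- matrix(runif(11 * 8), 11, 8)
  a1 <- path_action(pts, net, hill_params(), dt = 0.1)
  a2 <- path_action(pts[, match(pnet$genes, net$genes)], pnet,
                    hill_params(), dt = 0.1)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("refinement under identical configs reports zero deviation", {
  toy <- toy_fixtures()$one_gene$network
  rc <- refinement_check(toy, hill_params(), 0, 0.5,
                         mpp_config(10, 60), mpp_config(10, 60))
  expect_equal(rc$delta_action, 0)
  expect_equal(rc$max_path_deviation, 0)
  rc2 <- refinement_check(toy, hill_params(), 0, 0.5,
                          mpp_config(10, 100), mpp_config(10, 200))
  expect_lt(rc2$delta_action, 1e-4)
})

test_that("lineage suite runs all chains with exact endpoint patterns", {
  net <- pancreas_net()
  atlas <- pancreas_atlas_n4()
  map <- annotate_pancreas_atlas(atlas)
  suite <- cached("mpp_suite",
                  lineage_mpp_suite(net, atlas, map, mpp_config(10, 100)))
  labels <- vapply(atlas$states, `[[`, "", "label")
  for (cn in names(suite$chains)) {
    for (seg in names(suite$chains[[cn]])) {
      sol <- suite$chains[[cn]][[seg]]
      expect_true(sol$converged)
      ends <- strsplit(seg, "->", fixed = TRUE)[[1]]
      xs <- atlas$states[[match(map[[ends[1]]], labels)]]$x
      xe <- atlas$states[[match(map[[ends[2]]], labels)]]$x
      expect_equal(unname(sol$points[1, ]), unname(xs))
      expect_equal(unname(sol$points[nrow(sol$points), ]), unname(xe))
    }
  }
  # the two acinar routes take distinct interior paths
  p1 <- suite$chains$acinar_AciP$`TiP->AciP`$points
  p2 <- suite$chains$acinar_AciP2$`TiP->AciP2`$points
  expect_gt(max(abs(p1[2:100, ] - p2[2:100, ])), 1e-3)
  expect_error(
    lineage_mpp_suite(net, atlas, map[setdiff(names(map), "LEP")]),
    "LEP")
})
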