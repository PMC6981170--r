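test_that("eigenvalue classification follows the saddle taxonomy", {
  expect_identical(classify_equilibrium(c(-1, -2, -0.5)),
                   list(class = "stable", unstable_dim = 0L))
  expect_identical(classify_equilibrium(c(-1, 0.3, -2)),
                   list(class = "transition", unstable_dim = 1L))
  expect_identical(
    classify_equilibrium(c(-1, -1, 0.2, 0.3, -4)),
    list(class = "hyper_transition", unstable_dim = 2L))
  expect_identical(classify_equilibrium(c(-1, 1e-12))$class, "degenerate")
  expect_identical(classify_equilibrium(complex(real = c(-1, -1),
                                                imaginary = c(2, -2)))$class,
                   "stable")
  expect_error(classify_equilibrium(numeric(0)), "empty")
})

test_that("1-gene toy atlas equals the bisection oracle for n = 4..7", {
  toy <- toy_fixtures()$one_gene$network
  for (n in 4:7) {
    oracle <- toy_roots_bisect(n)
    atlas <- find_equilibria(toy, hill_params(n = n),
                             grid_points = c(0, 0.25, 0.5, 0.75, 1))
    found <- sort(vapply(atlas$states, function(s) unname(s$x), 0))
    expect_equal(found, oracle, tolerance = 1e-6)
  }
  # n = 4 classes: 0 and the high state stable, 0.5 a saddle
  a4 <- find_equilibria(toy, hill_params(n = 4))
  df <- as.data.frame(a4)
  expect_identical(df$class[order(df$A)],
                   c("stable", "transition", "stable"))
  expect_equal(sort(df$A), c(0, 0.5, 0.91964), tolerance = 1e-4)
})

test_that("the origin is always a stable equilibrium of the atlas", {
  for (fx in toy_fixtures()[c("one_gene", "toggle")]) {
    atlas <- find_equilibria(fx$network, hill_params(n = 4))
    i0 <- which(vapply(atlas$states, function(s) all(abs(s$x) < 1e-9), NA))
    expect_length(i0, 1)
    expect_identical(atlas$states[[i0]]$class, "stable")
  }
})

test_that("toggle switch has mirror-image attractors and a swap-symmetric saddle pair", {
  atlas <- find_equilibria(toy_fixtures()$toggle$network, hill_params(n = 4))
  df <- as.data.frame(atlas)
  stable <- df[df$class == "stable" & df$A + df$B > 0.1, ]
  expect_equal(nrow(stable), 2)
  # mirror symmetry of the two high states and of the saddle pair
  expect_equal(sort(stable$A), sort(stable$B), tolerance = 1e-8)
  saddles <- df[df$class == "transition", ]
  expect_equal(nrow(saddles), 2)
  expect_equal(sort(saddles$A), sort(saddles$B), tolerance = 1e-8)
  # the diagonal carries no interior equilibrium: the reduced 1-D flow
  # 16 a^4 / (1 + 16 a^4)^2 - a is strictly negative on (0, 1]
  a <- seq(1e-3, 1, by = 1e-3)
  expect_true(all(16 * a^4 / (1 + 16 * a^4)^2 - a < 0))
  expect_false(any(abs(saddles$A - saddles$B) < 1e-8))
})

test_that("atlas states re-verify as roots and are well separated", {
  atlas <- pancreas_atlas_n4()
  net <- pancreas_net()
  for (s in atlas$states) {
    expect_lt(max(abs(hill_rhs(net, s$x, atlas$params, permissive = TRUE))),
              1e-9)
    expect_lt(s$residual_norm, 1e-9)
  }
  xs <- do.call(rbind, lapply(atlas$states, function(s) unname(s$x)))
  d <- as.matrix(dist(xs))
  expect_gt(min(d[upper.tri(d)]), 1e-6)
  expect_true(all(xs > -0.05 & xs < 1.05))
  # no degenerate classifications at n = 4
  expect_equal(unname(atlas$meta$counts[["degenerate"]]), 0)
})

test_that("classification is invariant under gene reordering", {
  net <- pancreas_net()
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  pnet <- permute_network(net, perm)
  a <- pancreas_atlas_n4()
  b <- find_equilibria(pnet, hill_params(n = 4))
  counts_a <- table(vapply(a$states, `[[`, "", "class"))
  counts_b <- table(vapply(b$states, `[[`, "", "class"))
  expect_equal(counts_a, counts_b)
  # the state sets coincide up to coordinate permutation
  xa <- do.call(rbind, lapply(a$states, function(s) unname(s$x[pnet$genes])))
  xb <- do.call(rbind, lapply(b$states, function(s) unname(s$x)))
  for (i in seq_len(nrow(xa))) {
    expect_lt(min(sqrt(rowSums((xb - rep(xa[i, ], each = nrow(xb)))^2))),
              1e-6)
  }
})

test_that("robustness sweep on the toy tracks the bisection oracle per n", {
  toy <- toy_fixtures()$one_gene$network
  sweep <- robustness_sweep(toy, 4:7,
                            grid_points = c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(sweep$report$preserved))
  # the high state creeps toward 1 as the Hill function steepens
  hi <- vapply(4:7, function(n) max(toy_roots_bisect(n)), 0)
  expect_true(all(diff(hi) > 0))
  for (i in seq_along(4:7)) {
    found_hi <- max(as.data.frame(sweep$atlases[[i]])$A)
    expect_equal(found_hi, hi[i], tolerance = 1e-6)
  }
})

test_that("single-n sweep reports trivial preservation", {
  toy <- toy_fixtures()$one_gene$network
  sweep <- robustness_sweep(toy, 4)
  expect_true(all(sweep$report$preserved))
  expect_equal(nrow(sweep$report), 2)  # two stable states
})

test_that("atlas exports round-trip the key fields", {
  atlas <- pancreas_atlas_n4()
  csv <- tempfile(fileext = ".csv")
  write_atlas_csv(atlas, csv)
  df <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(df), 35)
  expect_equal(sum(df$class == "stable"), 11)
  js <- jsonlite::fromJSON(atlas_to_json(atlas))
  expect_equal(length(js$states$label), 35)
  expect_equal(js$params$n, 4)
})

test_that("trajectories from near a 1-D saddle settle into the flanking attractors", {
  toy <- toy_fixtures()$one_gene$network
  atlas <- find_equilibria(toy, hill_params(n = 4))
  cfg <- landscape_config()
  hi <- max(vapply(atlas$states, function(s) unname(s$x), 0))
  up <- integrate_trajectory(toy, 0.501, hill_params(), cfg)
  expect_true(up$converged)
  expect_equal(unname(up$states[nrow(up$states), 1]), hi, tolerance = 1e-6)
  dn <- integrate_trajectory(toy, 0.499, hill_params(), cfg)
  expect_equal(unname(dn$states[nrow(dn$states), 1]), 0, tolerance = 1e-6)
})
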