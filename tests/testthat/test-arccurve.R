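# Arc curve construction, null models, correction and fusion.

test_that("arc curve: worked examples and the brute-force crossing oracle", {
  # two mutual adjacent arcs (1<->2 in 1-based indexing)
  expect_identical(as.integer(compute_arc_curve(c(2L, 1L))), c(2L, 0L))
  # crossing pairs {1,3} and {2,4}, each twice
  expect_identical(as.integer(compute_arc_curve(c(3L, 4L, 1L, 2L))),
                   c(2L, 4L, 2L, 0L))
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:60, 1)
    idx <- sample(n)
    idx[idx == seq_len(n)] <- NA  # no self arcs
    ac <- compute_arc_curve(idx, n)
    expect_identical(as.integer(ac), brute_arc_curve(idx, n))
    # conservation: increments and decrements balance, sweep returns to 0
    expect_identical(sum(attr(ac, "nnmark")), 0L)
    expect_identical(ac[n], 0L)
  }
  expect_error(compute_arc_curve(c(2L, 5L), 2L), "out of range")
})

test_that("parabolic IAC: closed form, edges, beta(2,2) identity", {
  n <- 1000L
  iac <- idealized_arc_curve(n, "parabola")
  expect_equal(max(iac) / n, 0.5, tolerance = 2e-3)
  expect_identical(as.numeric(iac[1]), 0)
  expect_identical(as.numeric(iac[n]), 0)
  # normalized to unit area, the parabola IS the beta(2,2) density on [0, c]
  c0 <- n - 1
  i0 <- 0:c0
  dens <- as.numeric(iac) / (c0^2 / 3)
  expect_equal(dens, stats::dbeta(i0 / c0, 2, 2) / c0, tolerance = 1e-9)
})

test_that("Monte-Carlo null curves: bidirectional matches the parabola, left-only is lower and right-skewed", {
  n <- 1000L
  emp <- simulate_null_arc_curve(n, trials = 200, seed = 5, direction = "both")
  par <- as.numeric(idealized_arc_curve(n, "parabola"))
  expect_lt(max(abs(emp - par)) / max(par), 0.05)

  iac1d <- as.numeric(idealized_arc_curve(n, "one_directional",
                                          trials = 100, seed = 5))
  expect_lt(max(iac1d), max(par))           # shorter
  expect_lt(which.max(iac1d), n / 2)        # mode left of center = right-skewed
  # cached: identical object on repeat call
  again <- as.numeric(idealized_arc_curve(n, "one_directional",
                                          trials = 100, seed = 5))
  expect_identical(iac1d, again)
})

test_that("constrained null is flat in the interior with flagged edges", {
  iac <- idealized_arc_curve(600L, "constrained_uniform", trials = 50,
                             seed = 2, tc_samples = 100L)
  expect_identical(attr(iac, "edge_width"), 100L)
  expect_equal(length(unique(as.numeric(iac))), 1L)
  expect_error(idealized_arc_curve(600L, "constrained_uniform"), "tc_samples")
})

test_that("CAC correction: clamping, epsilon floor, edge hardcoding, bounds", {
  iac <- idealized_arc_curve(100L, "parabola")
  ac_same <- as.numeric(iac)
  expect_true(all(compute_cac(ac_same, iac) == 1))
  ac0 <- rep(0, 100)
  cac0 <- compute_cac(ac0, iac)
  expect_true(all(cac0[iac >= 1] == 0))    # informative positions -> 0
  expect_true(all(cac0[iac < 1] == 1))     # uninformative edges -> 1
  expect_true(all(compute_cac(2 * ac_same, iac) == 1))  # AC > IAC clamps to 1

  # constrained edges forced to 1 even where AC is 0
  iacc <- idealized_arc_curve(400L, "constrained_uniform", trials = 20,
                              seed = 3, tc_samples = 60L)
  cacc <- compute_cac(rep(0, 400), iacc)
  expect_true(all(cacc[c(1:60, 341:400)] == 1))
  expect_true(all(cacc[61:340] == 0))

  # bounds on randomized AC/IAC pairs
  for (seed in 1:25) {
    set.seed(seed)
    vals <- compute_cac(runif(50, 0, 30), runif(50, 0, 20))
    expect_true(all(vals >= 0 & vals <= 1))
  }
  expect_error(compute_cac(1:4, 1:5), "lengths differ")
})

test_that("fusion: identity, averaging, length contract", {
  a <- compute_cac(rep(5, 40), rep(10, 40))
  expect_equal(as.numeric(fuse_cacs(list(a))), as.numeric(a))
  z <- compute_cac(rep(0, 40), rep(10, 40))
  o <- compute_cac(rep(10, 40), rep(10, 40))
  expect_true(all(fuse_cacs(list(z, o)) == 0.5))
  expect_error(fuse_cacs(list(z, compute_cac(rep(1, 30), rep(2, 30)))),
               "mismatch")
})

test_that("on i.i.d. noise the CAC shows no consistent deep minimum", {
  frac_low <- argmins <- numeric(6)
  for (s in seq_along(argmins)) {
    set.seed(100 + s)
    cac <- fluss(rnorm(600), subseq_params(10))
    frac_low[s] <- mean(cac < 0.2)
    argmins[s] <- which.min(cac)
  }
  expect_lt(mean(frac_low), 0.1)          # few spuriously deep values
  expect_gt(stats::sd(argmins), 20)       # minimizer wanders across seeds
})
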