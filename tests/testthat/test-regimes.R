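# REA boundary extraction, threshold learning, snippet classification.

# a curve that is 1 everywhere except cosine valleys at given centers
valley_curve <- function(n, centers, depths, width = 15) {
  v <- rep(1, n)
  for (k in seq_along(centers)) {
    rng <- max(1, centers[k] - width):min(n, centers[k] + width)
    v[rng] <- pmin(v[rng], 1 - depths[k] *
                     (cos((rng - centers[k]) / width * pi / 2))^2)
  }
  v
}

test_that("REA picks the global minimum and honors the 5L exclusion zone", {
  n <- 600L; L <- 10L
  # deepest valley at 200; second-deepest only 2L away at 220 (inside the
  # exclusion zone); third at 400
  v <- valley_curve(n, c(200, 220, 400), c(0.9, 0.8, 0.5), width = 8)
  bd <- extract_regimes(v, 2, L = L)
  expect_identical(bd$positions, c(200L, 400L))
  # unimodal valley: argmin regardless of how many boundaries are asked later
  u <- valley_curve(n, 321, 0.7)
  expect_identical(extract_regimes(u, 1, L = L)$positions, 321L)
  # crafted two-valley curve -> exactly those indices
  w <- valley_curve(n, c(150, 450), c(0.6, 0.55))
  expect_identical(extract_regimes(w, 2, L = L)$positions, c(150L, 450L))
})

test_that("REA: pairwise spacing > 5L on randomized curves; deterministic; exhaustion warns", {
  L <- 8L
  for (seed in 1:20) {
    set.seed(seed)
    v <- runif(500)
    bd <- extract_regimes(v, 5, L = L)
    if (length(bd$positions) > 1)
      expect_true(all(diff(bd$positions) > 5L * L))
    expect_identical(bd$positions, extract_regimes(v, 5, L = L)$positions)
  }
  # a 5L zone each side blankets 81 positions: a 100-long curve is exhausted
  # after at most 2 picks when 8 are requested
  set.seed(1)
  v <- runif(100)
  expect_warning(bd <- extract_regimes(v, 8, L = 8L), "exhausted")
  expect_true(bd$exhausted)
  expect_lt(length(bd$positions), 8)
  expect_error(extract_regimes(runif(50), 1, L = 10L), "too short")
})

test_that("threshold learning: mean minus three population sds, clipped", {
  # the printed worked example: mean 0.671, sd 0.194 -> 0.089
  thr <- learn_threshold(0.671 + 0.194 * c(-1, 1))
  expect_equal(thr$train_mean, 0.671)
  expect_equal(thr$train_std, 0.194)
  expect_equal(thr$value, 0.089)
  # hand arithmetic with population sd
  thr2 <- learn_threshold(c(0.5, 0.7))
  expect_equal(thr2$train_std, 0.1)
  expect_equal(thr2$value, 0.3)
  # all-equal inputs: sd 0, threshold = mean
  expect_equal(learn_threshold(rep(0.42, 5))$value, 0.42)
  # clipping
  expect_equal(learn_threshold(c(0.05, 0.15))$value, 0)
  expect_error(learn_threshold(0.5), "at least 2")
})

test_that("classification separates positive and negative snippet suites", {
  expect_identical(classify_snippet(rep(1, 100), 0.5), "no_evidence")
  expect_identical(classify_snippet(c(rep(1, 99), 0), 1e-6), "regime_change")

  L <- 20L
  neg_min <- vapply(1:8, function(s) {
    # single behavior: two same-kind sine regimes = no change
    out <- make_regime_series(list(regime_spec("sine", L, 300),
                                   regime_spec("sine", L, 300)),
                              seed = s, check_adjacent = FALSE)
    min(fluss(out$series, subseq_params(L)))
  }, 1.0)
  pos_min <- vapply(1:8, function(s) {
    min(fluss(two_regime_series(seed = 100 + s)$series, subseq_params(L)))
  }, 1.0)
  expect_lt(stats::median(pos_min), stats::quantile(neg_min, 0.05))
  thr <- learn_threshold(neg_min)
  expect_gte(mean(vapply(pos_min, function(m) m < thr$value, TRUE)), 0.5)
})
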