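# Matrix Profile core: distance profiles and the batch profile.

test_that("distance profile: self-distance, affine invariance, flat handling", {
  set.seed(11)
  x <- cumsum(rnorm(64))
  L <- 8
  d <- dist_profile(x[5:(5 + L - 1)], x)
  expect_lt(d[5], 1e-6)
  # z-normalization kills positive affine transforms of the query
  d2 <- dist_profile(3.2 * x[5:(5 + L - 1)] - 7, x)
  expect_lt(d2[5], 1e-6)
  expect_equal(as.numeric(d), as.numeric(d2), tolerance = 1e-7)

  # flat query vs mixed windows: sqrt(L) against structure, 0 against flat,
  # never NaN, warns once
  y <- c(rep(1, 12), rnorm(12))
  expect_warning(df <- dist_profile(rep(5, 4), y), "flat")
  expect_true(all(is.finite(df)))
  expect_equal(df[1], 0)
  expect_equal(df[length(df)], 2, tolerance = 1e-12) # sqrt(L) = 2 for L = 4
})

test_that("distance profile matches the explicit z-normalization oracle on both code paths", {
  for (n in c(64L, 300L)) {   # 64 -> direct path, 300 -> FFT path
    set.seed(n)
    x <- cumsum(rnorm(n))
    L <- 8L
    q <- rnorm(L)
    expect_equal(as.numeric(dist_profile(q, x)), brute_dist_profile(q, x),
                 tolerance = 1e-8)
  }
})

test_that("batch profile equals the exhaustive all-pairs oracle (both directions)", {
  set.seed(42)
  x <- cumsum(rnorm(200))
  L <- 16L
  p <- subseq_params(L)
  mp <- compute_matrix_profile(x, p)
  br <- brute_matrix_profile(x, L)
  expect_identical(mp$mp_index, br$mp_index)
  expect_equal(mp$mp_values, br$mp_values, tolerance = 1e-8)

  mpl <- compute_matrix_profile(x, p, direction = "left")
  brl <- brute_matrix_profile(x, L, direction = "left")
  expect_profiles_equal(mpl$mp_index, mpl$mp_values, brl$mp_index, brl$mp_values)

  # temporal constraint path
  tc <- 40L
  mpc <- compute_matrix_profile(x, subseq_params(L, tc_samples = tc))
  brc <- brute_matrix_profile(x, L, tc = tc)
  expect_identical(mpc$mp_index, brc$mp_index)
  i <- seq_along(mpc$mp_index)
  expect_true(all(abs(mpc$mp_index - i) <= tc))
})

test_that("exclusion region, constraint bound and sentinels hold on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(150)
    L <- 10L
    mp <- compute_matrix_profile(x, subseq_params(L))
    i <- seq_along(mp$mp_index)
    expect_true(all(abs(mp$mp_index - i) > L %/% 2))
    mpl <- compute_matrix_profile(x, subseq_params(L), direction = "left")
    ok <- !is.na(mpl$mp_index)
    expect_true(all(mpl$mp_index[ok] < i[ok]))
    # early subsequences have no admissible left neighbor
    expect_true(all(is.na(mpl$mp_index[seq_len(L %/% 2 + 1L)])))
    expect_true(all(is.infinite(mpl$mp_values[seq_len(L %/% 2 + 1L)])))
  }
})

test_that("exact repeats give ~0 distances pointing at another repetition", {
  x <- rep(sin(2 * pi * (1:25) / 25), 8)
  mp <- compute_matrix_profile(x, subseq_params(25))
  expect_lt(max(mp$mp_values), 1e-6)
  expect_true(all(abs(mp$mp_index - seq_along(mp$mp_index)) %% 25 == 0))
})

test_that("profile index is invariant under positive affine transforms of the series", {
  out <- two_regime_series(seed = 3)
  x <- as.numeric(out$series)
  p <- subseq_params(20)
  mp1 <- compute_matrix_profile(x, p)
  mp2 <- compute_matrix_profile(5 * x + 100, p)
  expect_identical(mp1$mp_index, mp2$mp_index)
  expect_equal(mp1$mp_values, mp2$mp_values, tolerance = 1e-6)
})

test_that("contract violations error clearly", {
  expect_error(compute_matrix_profile(rnorm(30), subseq_params(16)),
               "too short")
  expect_error(subseq_params(2), ">= 3")
  expect_error(subseq_params(10, tc_samples = 10), "exceed")
  expect_error(ts_series(c(1, NA, 3)), "non-finite")
  expect_error(ts_series(c(1, 2, Inf)), "non-finite")
})
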