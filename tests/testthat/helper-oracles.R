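# Brute-force oracles, deliberately independent of the package's FFT/MASS
# code path: explicit z-normalization of every window and naive O(n^2 L)
# search. Used to freeze expected values for the fast implementations.

# explicit z-normalization; flat windows -> all zeros (package convention)
znorm <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s < 1e-8) return(rep(0, length(v))) else (v - mean(v)) / s
}

# naive distance profile: z-normalize query and every window, direct norm
brute_dist_profile <- function(query, x, L = length(query)) {
  m <- length(x) - L + 1
  q <- znorm(query)
  vapply(seq_len(m), function(j) {
    sqrt(sum((q - znorm(x[j:(j + L - 1)]))^2))
  }, 1.0)
}

# exhaustive all-pairs nearest-neighbor search with the same exclusion /
# temporal-constraint / direction rules; ties to the smallest index
brute_matrix_profile <- function(x, L, excl = L %/% 2, tc = NULL,
                                 direction = c("both", "left")) {
  direction <- match.arg(direction)
  m <- length(x) - L + 1
  Z <- t(vapply(seq_len(m), function(i) znorm(x[i:(i + L - 1)]),
                numeric(L)))
  D2 <- outer(rowSums(Z^2), rowSums(Z^2), `+`) - 2 * tcrossprod(Z)
  D <- sqrt(pmax(D2, 0))
  idx <- integer(m); val <- numeric(m)
  for (i in seq_len(m)) {
    d <- D[i, ]
    d[abs(seq_len(m) - i) <= excl] <- Inf
    if (!is.null(tc)) d[abs(seq_len(m) - i) > tc] <- Inf
    if (direction == "left") d[i:m] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) { idx[i] <- NA_integer_; val[i] <- Inf }
    else { idx[i] <- j; val[i] <- d[j] }
  }
  list(mp_index = idx, mp_values = val)
}

# literal crossing count: arc (i, j) covers min <= x < max
brute_arc_curve <- function(mp_index, n = length(mp_index)) {
  counts <- integer(n)
  for (i in seq_along(mp_index)) {
    j <- mp_index[i]
    if (is.na(j)) next
    a <- min(i, j); b <- max(i, j)
    for (x in seq_len(n)) if (a <= x && x < b) counts[x] <- counts[x] + 1L
  }
  counts
}

# compare two left-only profiles treating Inf == Inf as equal
expect_profiles_equal <- function(got_idx, got_val, want_idx, want_val,
                                  tol = 1e-8) {
  expect_identical(as.integer(got_idx), as.integer(want_idx))
  fin <- is.finite(want_val)
  expect_identical(is.finite(got_val), fin)
  if (any(fin)) expect_lt(max(abs(got_val[fin] - want_val[fin])), tol)
}

# quick 2-regime fixture used across files
two_regime_series <- function(seed = 1, period = 20, dur = 300, snr = 20) {
  make_regime_series(list(
    regime_spec("sine", period, dur, noise_db = snr),
    regime_spec("sawtooth", period, dur, noise_db = snr)), seed = seed)
}

# A - gap - B - gap - A fixture: both A blocks are the *same* noisy block, so
# every A subsequence has a zero-distance twin across the interior. Truth
# marks block edges; L = period = 25. A temporal constraint of 450 samples
# cuts the A-to-A twin arcs (offset 1500) while keeping every boundary
# outside the constrained null's hardcoded tc-wide edge regions.
repeated_regime_fixture <- function() {
  p <- 25L; dur <- 600L; gap <- 300L
  base <- make_regime_series(list(
    regime_spec("sine", p, dur, noise_db = 25),
    regime_spec("sawtooth", p, dur, noise_db = 25)), seed = 41)
  A <- as.numeric(base$series)[1:dur]
  B <- as.numeric(base$series)[(dur + 1):(2 * dur)]
  x <- c(A, B, A)
  x <- make_transition_gap(x, at = dur, gap_len = gap, seed = 5)
  x <- make_transition_gap(x, at = 2L * dur + gap, gap_len = gap, seed = 6)
  list(x = x, truth = c(dur, dur + gap, 2L * dur + gap, 2L * dur + 2L * gap),
       L = p)
}
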