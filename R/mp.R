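## Matrix Profile core: z-normalized distance profiles (MASS-style) and the
## batch all-pairs nearest-neighbor profile.
##
## Numerical conventions, fixed once for the whole package:
##  * rolling statistics use the population standard deviation;
##  * a window is "flat" (zero variance) when its variance falls below
##    FLAT_TOL relative to its squared mean scale; the z-normalized version of
##    a flat window is taken to be the all-zeros vector, so
##    d(flat, flat) = 0 and d(flat, non-flat) = sqrt(L) (a z-normalized
##    window has squared norm L);
##  * distances are clipped below at 0 before the square root.

FLAT_TOL <- 1e-12

## rolling mean / population sd of all length-L windows of x
rolling_stats <- function(x, L) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  css <- cumsum(c(0, x * x))
  idx <- seq_len(n - L + 1L)
  mu <- (cs[idx + L] - cs[idx]) / L
  va <- (css[idx + L] - css[idx]) / L - mu * mu
  scale2 <- pmax(mu * mu, 1)
  flat <- va < FLAT_TOL * scale2
  va[va < 0] <- 0
  list(mu = mu, sig = sqrt(va), flat = flat)
}

## sliding dot products of query (length L) against all windows of x,
## FFT cross-correlation when n >= fft_min, direct otherwise
sliding_dot <- function(query, x, fft_min = 256L, xfft = NULL, pad = NULL) {
  n <- length(x)
  L <- length(query)
  if (n < fft_min && is.null(xfft)) {
    m <- n - L + 1L
    qt <- numeric(m)
    for (j in seq_len(m)) qt[j] <- sum(query * x[j:(j + L - 1L)])
    return(qt)
  }
  if (is.null(pad)) pad <- 2^ceiling(log2(n + L))
  if (is.null(xfft)) xfft <- stats::fft(c(x, numeric(pad - n)))
  qr <- c(rev(query), numeric(pad - L))
  conv <- Re(stats::fft(xfft * stats::fft(qr), inverse = TRUE)) / pad
  conv[L:n]
}

## precompute per-series state reused across the m per-row profile calls
mass_precompute <- function(x, L, fft_min = 256L) {
  n <- length(x)
  st <- rolling_stats(x, L)
  use_fft <- n >= fft_min
  pad <- if (use_fft) 2^ceiling(log2(n + L)) else NULL
  xfft <- if (use_fft) stats::fft(c(x, numeric(pad - n))) else NULL
  list(x = x, n = n, L = L, m = n - L + 1L, mu = st$mu, sig = st$sig,
       flat = st$flat, use_fft = use_fft, pad = pad, xfft = xfft,
       fft_min = fft_min)
}

## distance profile given precomputed state; query need not come from x
dist_profile_pre <- function(pre, query, warn_flat = TRUE) {
  L <- pre$L
  mu_q <- mean(query)
  va_q <- mean(query * query) - mu_q * mu_q
  flat_q <- va_q < FLAT_TOL * max(mu_q * mu_q, 1)
  if ((flat_q || any(pre$flat)) && warn_flat)
    warning("zero-variance (flat) window encountered; treating its z-normalized form as all zeros",
            call. = FALSE)
  if (flat_q) {
    d <- rep(sqrt(L), pre$m)
    d[pre$flat] <- 0
    return(d)
  }
  qt <- sliding_dot(query, pre$x, fft_min = pre$fft_min,
                    xfft = pre$xfft, pad = pre$pad)
  sd_q <- sqrt(max(va_q, 0))
  dsq <- 2 * L * (1 - (qt - L * mu_q * pre$mu) / (L * sd_q * pre$sig))
  dsq[pre$flat] <- L                 # non-flat query vs flat window
  sqrt(pmax(dsq, 0))
}

#' z-normalized distance profile of a query against every subsequence
#'
#' Computes, for each start position `j`, the Euclidean distance between the
#' z-normalized query and the z-normalized window `series[j:(j+L-1)]`. Uses an
#' FFT cross-correlation plus rolling moments (the MASS recurrence) for series
#' of length >= 256 and a direct dot-product sweep below that, where FFT
#' round-off would dominate; both paths agree to ~1e-8.
#'
#' Flat (zero-variance) windows have no defined z-normalization; their
#' normalized form is taken as the all-zeros vector (distance 0 to another
#' flat window, `sqrt(L)` otherwise) and a warning is raised. Output is never
#' NaN.
#'
#' @param query numeric vector of length `L`.
#' @param series numeric vector or [ts_series()] of length `n >= L`.
#' @return numeric vector of length `n - L + 1`, all entries >= 0.
#' @export
#' @examples
#' x <- sin(seq(0, 10, length.out = 64))
#' d <- dist_profile(x[5:12], x)
#' d[5] # ~0: the query matches itself
dist_profile <- function(query, series) {
  x <- as_series_values(series)
  query <- as.numeric(query)
  if (any(!is.finite(query))) stop("query contains non-finite values")
  L <- length(query)
  if (L < 3L) stop("query length must be >= 3")
  if (L > length(x)) stop("query longer than series")
  pre <- mass_precompute(x, L)
  dist_profile_pre(pre, query)
}

#' Batch Matrix Profile
#'
#' For every subsequence of length `L`, finds its nearest neighbor under the
#' z-normalized Euclidean distance, excluding trivial matches (neighbors
#' starting within `exclusion_halfwidth` positions) and, when a temporal
#' constraint is set, neighbors farther than `tc_samples` away. With
#' `direction = "left"` the search is restricted to strictly earlier start
#' positions (the one-directional profile used by the streaming algorithm).
#'
#' Ties are broken toward the smallest admissible index so results are
#' platform-deterministic. A subsequence with no admissible neighbor (only
#' possible early in a left-only profile) gets the sentinel index
#' `NA_integer_` and distance `Inf`; sentinels are skipped when arcs are
#' counted downstream.
#'
#' @param series numeric vector or [ts_series()]; requires `n >= 2 * L`.
#' @param params a [subseq_params()] object (or a bare length `L`).
#' @param direction `"both"` (default) or `"left"`.
#' @return a `matrix_profile` list: `mp_values`, `mp_index` (1-based start
#'   positions), `direction`, `params`, `n`.
#' @export
#' @examples
#' x <- rep(sin(2 * pi * (1:25) / 25), 8)
#' mp <- compute_matrix_profile(x, subseq_params(25))
#' max(mp$mp_values) # ~0: every window repeats exactly
compute_matrix_profile <- function(series, params,
                                   direction = c("both", "left")) {
  direction <- match.arg(direction)
  x <- as_series_values(series)
  params <- as_subseq_params(params)
  n <- length(x)
  L <- params$L
  if (n < 2L * L) stop("series too short for L (need n >= 2L)")
  excl <- params$exclusion_halfwidth
  tc <- params$tc_samples
  pre <- mass_precompute(x, L)
  m <- pre$m
  mp_values <- numeric(m)
  mp_index <- integer(m)
  warned <- FALSE
  for (i in seq_len(m)) {
    d <- withCallingHandlers(
      dist_profile_pre(pre, x[i:(i + L - 1L)], warn_flat = !warned),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    lo <- max(1L, i - excl)
    hi <- min(m, i + excl)
    d[lo:hi] <- Inf
    if (!is.null(tc)) {
      if (i - tc > 1L) d[seq_len(i - tc - 1L)] <- Inf
      if (i + tc < m) d[(i + tc + 1L):m] <- Inf
    }
    if (direction == "left" && i < m) d[(i + 1L):m] <- Inf
    j <- which.min(d)           # ties -> smallest index
    if (!is.finite(d[j])) {
      mp_index[i] <- NA_integer_
      mp_values[i] <- Inf
    } else {
      mp_index[i] <- j
      mp_values[i] <- d[j]
    }
  }
  if (warned)
    warning("zero-variance (flat) window(s) encountered; z-normalized as all zeros",
            call. = FALSE)
  structure(list(mp_values = mp_values, mp_index = mp_index,
                 direction = direction, params = params, n = n),
            class = "matrix_profile")
}

#' @export
print.matrix_profile <- function(x, ...) {
  cat(sprintf("<matrix_profile> m = %d, L = %d, direction = %s%s\n",
              length(x$mp_values), x$params$L, x$direction,
              if (is.null(x$params$tc_samples)) ""
              else sprintf(", tc = %d", x$params$tc_samples)))
  invisible(x)
}
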