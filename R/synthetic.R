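## Seed-deterministic synthetic regime-change series, transition gaps, and a
## battery of realistic signal distortions. Every generator emits ground
## truth alongside the data so the rest of the package is testable offline.

REGIME_KINDS <- c("sine", "square-ish", "sawtooth", "pulse-train", "noise-walk")
DISTORTION_KINDS <- c("downsample_2x", "bitdepth_8", "linear_trend_10deg",
                      "white_noise_20db", "smooth", "delete3pct_interp")

#' Specify one regime of a synthetic series
#'
#' @param kind waveform family, one of `"sine"`, `"square-ish"` (smoothed
#'   square), `"sawtooth"`, `"pulse-train"` (one Gaussian bump per period),
#'   `"noise-walk"` (unstructured smoothed random walk).
#' @param period cycle length in samples.
#' @param duration regime length in samples; must be at least `4 * period` —
#'   the segmentation model assumes patterns repeat several times per regime
#'   and cannot place boundaries around single occurrences.
#' @param amplitude peak amplitude (arbitrary units).
#' @param noise_db additive white-noise level as an SNR in dB
#'   (signal power / noise power; 20 dB ~ amplitude ratio 10). `Inf` = clean.
#' @return a `regime_spec` list.
#' @export
regime_spec <- function(kind, period, duration, amplitude = 1,
                        noise_db = 20) {
  kind <- match.arg(kind, REGIME_KINDS)
  period <- as.integer(period)
  duration <- as.integer(duration)
  stopifnot(period >= 2L, amplitude > 0)
  if (duration < 4L * period)
    stop("regime duration must cover at least 4 periods (patterns must repeat)")
  structure(list(kind = kind, period = period, duration = duration,
                 amplitude = amplitude, noise_db = noise_db),
            class = "regime_spec")
}

## clean (noise-free) waveform for one regime
regime_waveform <- function(spec) {
  t <- seq_len(spec$duration)
  ph <- (t %% spec$period) / spec$period
  base <- switch(spec$kind,
    "sine" = sin(2 * pi * t / spec$period),
    "square-ish" = tanh(4 * sin(2 * pi * t / spec$period)),
    "sawtooth" = 2 * ph - 1,
    "pulse-train" = exp(-((ph - 0.5)^2) / (2 * 0.05^2)) - 0.25,
    "noise-walk" = {
      z <- cumsum(stats::rnorm(spec$duration))
      z <- z - mean(z)
      z / max(stats::sd(z), 1e-12)
    })
  spec$amplitude * base
}

add_snr_noise <- function(x, noise_db) {
  if (!is.finite(noise_db)) return(x)
  p_sig <- mean((x - mean(x))^2)
  sd_n <- sqrt(p_sig / 10^(noise_db / 10))
  x + stats::rnorm(length(x), 0, sd_n)
}

#' Generate a labeled regime-change series
#'
#' Concatenates the regimes described by `specs` (each a quasi-periodic
#' pattern at its stated SNR) and returns the series together with the true
#' boundary positions at the cumulative durations. Bit-identical per seed.
#'
#' @param specs list of >= 2 [regime_spec()] objects. Adjacent regimes must
#'   differ in waveform kind or period (set `check_adjacent = FALSE` for
#'   deliberately repeated regimes, e.g. when building per-channel fixtures
#'   whose boundaries are carried by another channel).
#' @param seed RNG seed.
#' @param sampling_rate_hz optional rate annotation for the output.
#' @param check_adjacent enforce the adjacent-distinctness invariant.
#' @return list with `series` (a [ts_series()]) and `truth` (integer
#'   boundary positions: the last sample index of each non-final regime).
#' @export
#' @examples
#' out <- make_regime_series(list(
#'   regime_spec("sine", 25, 300), regime_spec("sawtooth", 25, 300)), seed = 1)
#' out$truth # 300
make_regime_series <- function(specs, seed = 1L, sampling_rate_hz = NULL,
                               check_adjacent = TRUE) {
  if (!is.list(specs) || length(specs) < 2L)
    stop("need at least 2 regime specs")
  stopifnot(all(vapply(specs, inherits, TRUE, "regime_spec")))
  if (check_adjacent) {
    for (k in seq_len(length(specs) - 1L)) {
      a <- specs[[k]]; b <- specs[[k + 1L]]
      if (a$kind == b$kind && a$period == b$period)
        stop(sprintf("adjacent regimes %d and %d are indistinguishable (same kind and period)",
                     k, k + 1L))
    }
  }
  with_seed(seed, {
    chunks <- lapply(specs, function(s) add_snr_noise(regime_waveform(s),
                                                      s$noise_db))
    durs <- vapply(specs, `[[`, 1L, "duration")
    series <- ts_series(unlist(chunks), sampling_rate_hz = sampling_rate_hz)
    truth <- cumsum(durs)[-length(durs)]
    list(series = series, truth = as.integer(truth))
  })
}

#' Insert an unstructured transition gap into a series
#'
#' Splices `gap_len` samples of low-amplitude smoothed noise (5% of the
#' series' sd) after position `at`, emulating the loosely structured
#' "transient" periods between activities in wearable recordings.
#'
#' @param series numeric vector or [ts_series()].
#' @param at 1-based position after which the gap is inserted (0 prepends).
#' @param gap_len gap length in samples (0 = identity).
#' @param seed RNG seed.
#' @return numeric vector of length `length(series) + gap_len`.
#' @export
make_transition_gap <- function(series, at, gap_len, seed = 1L) {
  x <- as_series_values(series)
  at <- as.integer(at)
  gap_len <- as.integer(gap_len)
  stopifnot(at >= 0L, at <= length(x), gap_len >= 0L)
  if (gap_len == 0L) return(x)
  gap <- with_seed(seed, {
    z <- stats::rnorm(gap_len + 4L)
    z <- stats::filter(z, rep(1 / 5, 5), sides = 2)
    z <- as.numeric(z[!is.na(z)])[seq_len(gap_len)]
    z / max(stats::sd(z), 1e-12)
  })
  lvl <- mean(x)
  c(x[seq_len(at)], lvl + 0.05 * stats::sd(x) * gap,
    if (at < length(x)) x[(at + 1L):length(x)])
}

#' Apply one named distortion to a series
#'
#' The battery of realistic corruptions used to probe robustness of the
#' corrected arc curve:
#' \describe{
#'   \item{downsample_2x}{keep every second sample (250 Hz -> 125 Hz analogue);
#'     output has half the length.}
#'   \item{bitdepth_8}{re-quantize to 256 uniform levels across the range.}
#'   \item{linear_trend_10deg}{add a ramp whose slope spans ten visual degrees
#'     on a unit-aspect plot: `tan(10°) * range(x) / n` per sample.}
#'   \item{white_noise_20db}{additive Gaussian noise at 20 dB SNR.}
#'   \item{smooth}{centered moving average, window 5 (shrinking at edges).}
#'   \item{delete3pct_interp}{delete a random 3% of samples, then linearly
#'     interpolate back onto the original grid — length preserved exactly.}
#' }
#'
#' @param series numeric vector or [ts_series()].
#' @param kind one of the names above.
#' @param seed RNG seed (used by the stochastic kinds).
#' @return distorted numeric vector.
#' @export
distort <- function(series, kind, seed = 1L) {
  x <- as_series_values(series)
  kind <- match.arg(kind, DISTORTION_KINDS)
  n <- length(x)
  switch(kind,
    "downsample_2x" = x[seq(1L, n, by = 2L)],
    "bitdepth_8" = {
      r <- range(x)
      if (r[2] == r[1]) return(x)
      q <- round((x - r[1]) / (r[2] - r[1]) * 255)
      r[1] + q * (r[2] - r[1]) / 255
    },
    "linear_trend_10deg" = {
      slope <- tan(10 * pi / 180) * diff(range(x)) / n
      x + slope * (seq_len(n) - 1L)
    },
    "white_noise_20db" = with_seed(seed, add_snr_noise(x, 20)),
    "smooth" = {
      pad <- c(rep(x[1], 2), x, rep(x[n], 2))
      sm <- stats::filter(pad, rep(1 / 5, 5), sides = 2)
      as.numeric(sm[3:(n + 2L)])
    },
    "delete3pct_interp" = with_seed(seed, {
      drop <- sample(n, size = max(1L, round(0.03 * n)))
      keep <- setdiff(seq_len(n), drop)
      stats::approx(x = keep, y = x[keep], xout = seq_len(n), rule = 2)$y
    }))
}
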