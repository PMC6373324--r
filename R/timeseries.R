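#' Construct a single-channel time series
#'
#' A uniformly sampled sequence of finite real values, optionally annotated
#' with a sampling rate. Multi-channel data is represented as a plain list of
#' equal-length `floss_ts` objects (one per channel/dimension).
#'
#' Non-finite values (NA/NaN/Inf) are rejected at ingest: downstream
#' z-normalized distance computations cannot produce meaningful output for
#' them, and silent imputation would corrupt boundary positions.
#'
#' @param values numeric vector, length >= 1, all finite.
#' @param sampling_rate_hz optional positive sampling rate in Hz.
#' @return a `floss_ts` object (numeric vector with attributes).
#' @export
#' @examples
#' x <- ts_series(sin(seq(0, 20, by = 0.1)), sampling_rate_hz = 10)
#' length(x)
ts_series <- function(values, sampling_rate_hz = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time series must contain at least one sample")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop(sprintf("non-finite values at position(s) %s (first shown); NaN/Inf rejected at ingest",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (!is.null(sampling_rate_hz)) {
    stopifnot(is.numeric(sampling_rate_hz), length(sampling_rate_hz) == 1L,
              is.finite(sampling_rate_hz), sampling_rate_hz > 0)
    attr(values, "sampling_rate_hz") <- as.numeric(sampling_rate_hz)
  }
  class(values) <- c("floss_ts", "numeric")
  values
}

#' @export
print.floss_ts <- function(x, ...) {
  rate <- attr(x, "sampling_rate_hz")
  cat(sprintf("<floss_ts> n = %d%s\n", length(x),
              if (is.null(rate)) "" else sprintf(", %g Hz", rate)))
  utils::str(as.numeric(unclass(x)))
  invisible(x)
}

## coerce numeric vector / floss_ts to bare numeric, validating finiteness
as_series_values <- function(x) {
  if (inherits(x, "floss_ts")) return(as.numeric(unclass(x)))
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("series contains non-finite values")
  x
}

#' Subsequence-search parameters
#'
#' Bundles the subsequence length `L`, the trivial-match exclusion half-width
#' (neighbors within `exclusion_halfwidth` positions of a subsequence's own
#' start are never candidates, so a window cannot match an overlapping copy of
#' itself), and an optional temporal constraint capping arc length in samples.
#'
#' @param L integer subsequence length in samples, >= 3.
#' @param exclusion_halfwidth integer >= 1; default `floor(L / 2)`.
#' @param tc_samples optional integer > L: maximum allowed |i - j| between a
#'   subsequence and its nearest neighbor. Use [sec_to_samples()] to convert a
#'   wall-clock constraint.
#' @return a `subseq_params` list.
#' @export
subseq_params <- function(L, exclusion_halfwidth = NULL, tc_samples = NULL) {
  L <- as.integer(L)
  stopifnot(length(L) == 1L, !is.na(L), L >= 3L)
  if (is.null(exclusion_halfwidth)) exclusion_halfwidth <- L %/% 2L
  exclusion_halfwidth <- as.integer(exclusion_halfwidth)
  stopifnot(exclusion_halfwidth >= 1L)
  if (!is.null(tc_samples)) {
    tc_samples <- as.integer(tc_samples)
    if (is.na(tc_samples) || tc_samples <= L)
      stop("tc_samples must exceed the subsequence length L")
  }
  structure(list(L = L, exclusion_halfwidth = exclusion_halfwidth,
                 tc_samples = tc_samples),
            class = "subseq_params")
}

as_subseq_params <- function(params) {
  if (inherits(params, "subseq_params")) return(params)
  if (is.numeric(params) && length(params) == 1L) return(subseq_params(params))
  stop("params must be a subseq_params object or a single subsequence length")
}
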