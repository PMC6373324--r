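## Arc curves and their null models.
##
## An arc is a pair (i, j = mp_index[i]). Under the half-open crossing
## convention an arc covers positions min(i,j) <= x < max(i,j): the sweep
## increments at min, decrements at max, and the cumulative sum *is* the
## crossing count. This makes the fast algorithm provably identical to the
## brute-force count.

#' Arc Curve: per-position arc-crossing counts
#'
#' @param mp_index integer vector of nearest-neighbor start positions
#'   (1-based); `NA` entries (left-only sentinels) are skipped.
#' @param n curve length; defaults to `length(mp_index)`.
#' @return an `arc_curve`: integer vector of crossing counts, with the raw
#'   increment/decrement sweep in attribute `nnmark`.
#' @export
#' @examples
#' compute_arc_curve(c(2L, 1L)) # two mutual adjacent arcs: 2, 0
compute_arc_curve <- function(mp_index, n = length(mp_index)) {
  mp_index <- as.integer(mp_index)
  n <- as.integer(n)
  valid <- which(!is.na(mp_index))
  j <- mp_index[valid]
  bad <- valid[j < 1L | j > n]
  if (length(bad))
    stop(sprintf("mp_index out of range [1, %d] at position(s) %s",
                 n, paste(utils::head(bad, 5L), collapse = ", ")))
  if (any(valid > n)) stop("mp_index longer than requested curve length")
  nnmark <- numeric(n)
  a <- pmin(valid, j)
  b <- pmax(valid, j)
  inc <- tabulate(a, nbins = n)
  dec <- tabulate(b, nbins = n)
  nnmark <- inc - dec
  counts <- cumsum(nnmark)
  structure(as.integer(counts), nnmark = as.integer(nnmark),
            class = c("arc_curve", "integer"))
}

#' Empirical mean arc curve under a structureless null
#'
#' Simulates `trials` random nearest-neighbor index vectors — each
#' subsequence's arc points to an effectively random admissible location —
#' and averages their arc curves. `direction = "both"` draws the neighbor
#' uniformly over all other positions (optionally within `tc_samples`);
#' `direction = "left"` draws uniformly over strictly earlier positions
#' (position 1 is a sentinel), which produces the shorter, right-skewed curve
#' characteristic of one-directional arcs.
#'
#' @param n curve length.
#' @param trials number of Monte-Carlo replicates.
#' @param seed RNG seed (evaluated via an isolated RNG stream).
#' @param direction `"both"` or `"left"`.
#' @param tc_samples optional arc-length cap.
#' @return numeric vector of length `n`: the mean crossing count.
#' @export
simulate_null_arc_curve <- function(n, trials = 200L, seed = 1L,
                                    direction = c("both", "left"),
                                    tc_samples = NULL) {
  direction <- match.arg(direction)
  n <- as.integer(n)
  stopifnot(n >= 4L, trials >= 1L)
  with_seed(seed, {
    acc <- numeric(n)
    for (t in seq_len(trials)) {
      if (direction == "left") {
        ## j ~ Uniform{1..i-1}; first position has no left neighbor
        j <- c(NA_integer_,
               1L + as.integer(floor(stats::runif(n - 1L) * seq_len(n - 1L))))
      } else if (is.null(tc_samples)) {
        ## j ~ Uniform over {1..n} \ {i}
        i <- seq_len(n)
        j <- 1L + as.integer(floor(stats::runif(n) * (n - 1L)))
        j <- ifelse(j >= i, j + 1L, j)
      } else {
        i <- seq_len(n)
        lo <- pmax(1L, i - as.integer(tc_samples))
        hi <- pmin(n, i + as.integer(tc_samples))
        j <- lo + as.integer(floor(stats::runif(n) * (hi - lo)))
        j <- ifelse(j >= i, j + 1L, j)   # skip self, stay within [lo, hi]
      }
      acc <- acc + compute_arc_curve(j, n)
    }
    acc / trials
  })
}

#' Idealized Arc Curve (IAC): expected crossings under no structure
#'
#' The null-model expectation used to normalize an observed arc curve:
#' \describe{
#'   \item{parabola}{closed form `2 i (n-1-i) / (n-1)` (0-based `i`): an
#'     inverted parabola, zero at both edges, peaking at ~`n/2` in the
#'     center. Proportional to the beta(2,2) density.}
#'   \item{one_directional}{seeded Monte-Carlo mean of left-only random arcs
#'     (no closed form is committed to; the empirical curve is cached per
#'     `(n, trials, seed)`), right-skewed with a lower peak.}
#'   \item{constrained_uniform}{under a temporal constraint the expectation is
#'     flat away from the edges; the constant interior level is estimated
#'     empirically and the first and last `tc_samples` positions are flagged
#'     as edge regions (forced to 1 in the corrected curve).}
#' }
#'
#' @param n curve length (>= 4).
#' @param model one of `"parabola"`, `"one_directional"`,
#'   `"constrained_uniform"`.
#' @param trials Monte-Carlo replicates for the empirical models.
#' @param seed RNG seed for the empirical models.
#' @param tc_samples required for `"constrained_uniform"`.
#' @return an `iac` object: numeric `expected` values of length `n` plus
#'   `model`, `trials`, `seed` and `edge_width` attributes.
#' @export
#' @examples
#' iac <- idealized_arc_curve(1000, "parabola")
#' max(iac) / 1000 # ~ 0.5
idealized_arc_curve <- function(n, model = c("parabola", "one_directional",
                                             "constrained_uniform"),
                                trials = 200L, seed = 1L, tc_samples = NULL) {
  model <- match.arg(model)
  n <- as.integer(n)
  stopifnot(n >= 4L)
  edge_width <- 0L
  if (model == "parabola") {
    i0 <- 0:(n - 1L)
    expected <- 2 * i0 * (n - 1 - i0) / (n - 1)
  } else if (model == "one_directional") {
    key <- sprintf("iac1d_%d_%d_%d", n, trials, seed)
    if (is.null(.flossr_cache[[key]]))
      .flossr_cache[[key]] <- simulate_null_arc_curve(n, trials, seed, "left")
    expected <- .flossr_cache[[key]]
  } else {
    if (is.null(tc_samples)) stop("constrained_uniform requires tc_samples")
    tc_samples <- as.integer(tc_samples)
    key <- sprintf("iacc_%d_%d_%d_%d", n, trials, seed, tc_samples)
    if (is.null(.flossr_cache[[key]])) {
      emp <- simulate_null_arc_curve(n, trials, seed, "both",
                                     tc_samples = tc_samples)
      interior <- if (n > 2L * tc_samples)
        (tc_samples + 1L):(n - tc_samples) else seq_len(n)
      .flossr_cache[[key]] <- rep(mean(emp[interior]), n)
    }
    expected <- .flossr_cache[[key]]
    edge_width <- min(tc_samples, n)
  }
  structure(expected, model = model, trials = trials, seed = seed,
            edge_width = edge_width, class = c("iac", "numeric"))
}

#' Corrected Arc Curve (CAC)
#'
#' Pointwise `min(AC / IAC, 1)`, the observed crossings relative to the null
#' expectation, bounded to `[0, 1]`. Positions where the null expects fewer
#' than `eps` crossings are uninformative edges and are set to 1, as are the
#' hardcoded edge regions of a temporally constrained null. Deep minima of
#' the CAC are candidate regime boundaries; a high minimum is absence of
#' evidence for a change, not evidence of absence.
#'
#' @param ac an [compute_arc_curve()] result (or numeric vector).
#' @param iac an [idealized_arc_curve()] result (or numeric vector).
#' @param eps expected-crossing floor below which a position is uninformative.
#' @return a `floss_cac`: numeric vector in `[0, 1]`.
#' @export
compute_cac <- function(ac, iac, eps = 1.0) {
  ac <- as.numeric(ac)
  iac_v <- as.numeric(iac)
  if (length(ac) != length(iac_v)) stop("AC and IAC lengths differ")
  vals <- ifelse(iac_v < eps, 1, pmin(ac / pmax(iac_v, eps), 1))
  ew <- attr(iac, "edge_width")
  if (!is.null(ew) && ew > 0L) {
    n <- length(vals)
    vals[seq_len(min(ew, n))] <- 1
    vals[max(1L, n - ew + 1L):n] <- 1
  }
  structure(vals, model = attr(iac, "model"), class = c("floss_cac", "numeric"))
}

#' Fuse corrected arc curves from multiple channels
#'
#' Pointwise arithmetic mean. Because every CAC is already normalized to
#' `[0, 1]`, curves from sensors with different units or precisions are
#' commensurate; curves must nevertheless be index-aligned (equal length) —
#' resample channels to a common rate first if needed.
#'
#' @param cacs a list of equal-length [compute_cac()] curves.
#' @return a single `floss_cac`.
#' @export
fuse_cacs <- function(cacs) {
  if (!is.list(cacs) || length(cacs) < 1L) stop("need a non-empty list of CACs")
  lens <- vapply(cacs, length, 1L)
  if (length(unique(lens)) != 1L)
    stop(sprintf("CAC length mismatch: %s; curves must be index-aligned",
                 paste(lens, collapse = ", ")))
  vals <- Reduce(`+`, lapply(cacs, as.numeric)) / length(cacs)
  structure(vals, class = c("floss_cac", "numeric"))
}

#' FLUSS: batch corrected arc curve for one or several channels
#'
#' The full batch pipeline: Matrix Profile (bidirectional, with the optional
#' temporal constraint) -> arc curve -> normalization by the matching null
#' (parabolic, or constrained-uniform when `tc_samples` is set) per channel,
#' then fusion across channels by the mean. Deterministic given input and
#' parameters.
#'
#' @param series a numeric vector / [ts_series()], or a list of equal-length
#'   channels.
#' @param params a [subseq_params()] (or bare `L`).
#' @param trials,seed Monte-Carlo settings for the constrained-uniform null
#'   (unused by the parabolic null).
#' @return a `floss_cac` of length `n - L + 1`, with attributes `L` and `n`.
#' @export
#' @examples
#' x <- c(sin(2 * pi * (1:300) / 20), sign(sin(2 * pi * (1:300) / 20)) * 0.8)
#' cac <- fluss(x, subseq_params(20))
#' which.min(cac) # near the junction at 300
fluss <- function(series, params, trials = 200L, seed = 1L) {
  params <- as_subseq_params(params)
  channels <- if (is.list(series) && !inherits(series, "floss_ts"))
    series else list(series)
  xs <- lapply(channels, as_series_values)
  ns <- vapply(xs, length, 1L)
  if (length(unique(ns)) != 1L) stop("all channels must have equal length")
  cacs <- lapply(xs, function(x) {
    mp <- compute_matrix_profile(x, params, direction = "both")
    ac <- compute_arc_curve(mp$mp_index)
    m <- length(ac)
    iac <- if (is.null(params$tc_samples))
      idealized_arc_curve(m, "parabola")
    else
      idealized_arc_curve(m, "constrained_uniform", trials = trials,
                          seed = seed, tc_samples = params$tc_samples)
    compute_cac(ac, iac)
  })
  out <- fuse_cacs(cacs)
  attr(out, "L") <- params$L
  attr(out, "n") <- ns[1]
  attr(out, "params") <- params
  out
}

#' Overlay plot of a series and its corrected arc curve
#'
#' The standard two-panel diagnostic: the raw series on top, the CAC below,
#' with extracted boundaries (if supplied) marked on both.
#'
#' @param x a `floss_cac` curve.
#' @param series optional numeric vector / [ts_series()] the curve came from.
#' @param boundaries optional [extract_regimes()] result to mark.
#' @param ... passed to the CAC panel's `plot()`.
#' @return `x`, invisibly.
#' @export
plot.floss_cac <- function(x, series = NULL, boundaries = NULL, ...) {
  op <- graphics::par(mfrow = if (is.null(series)) c(1, 1) else c(2, 1),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  pos <- if (is.null(boundaries)) NULL else boundaries$positions
  if (!is.null(series)) {
    graphics::plot(as_series_values(series), type = "l", ylab = "series",
                   xlab = "")
    if (!is.null(pos)) graphics::abline(v = pos, col = 2, lty = 2)
  }
  graphics::plot(as.numeric(x), type = "l", ylim = c(0, 1), ylab = "CAC",
                 xlab = "position", ...)
  if (!is.null(pos)) graphics::abline(v = pos, col = 2, lty = 2)
  invisible(x)
}

#' @export
print.floss_cac <- function(x, ...) {
  cat(sprintf("<floss_cac> length %d, min %.4f at %d\n",
              length(x), min(x), which.min(x)))
  invisible(x)
}
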