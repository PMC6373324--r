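## Regime extraction (REA) and alert-threshold learning.

#' Extract regime boundaries from a corrected arc curve (REA)
#'
#' Repeatedly takes the global minimum of the working curve, records it, and
#' masks an exclusion zone of `5 * L` positions on each side (clipped at the
#' array bounds) before the next pick. The wide zone reflects the method's
#' repetition assumption: patterns must repeat several times within a regime,
#' so two genuine boundaries cannot sit closer than a few subsequence lengths
#' — without the zone, the second pick would almost surely be the immediate
#' neighbor of the first.
#'
#' Ties on equal minima break toward the lowest index; the algorithm is fully
#' deterministic. If the curve is exhausted (everything masked) before
#' `num_boundaries` picks, the boundaries found so far are returned with
#' `exhausted = TRUE` and a warning.
#'
#' @param cac a [compute_cac()]/[fluss()] curve; length must exceed `10 * L`.
#' @param num_boundaries number of boundary positions to extract (>= 1).
#' @param L subsequence length in samples (taken from the curve's attribute
#'   when present).
#' @return a `regime_boundaries` list: sorted `positions`, matching
#'   `cac_values`, `num_requested`, `exhausted`.
#' @export
extract_regimes <- function(cac, num_boundaries, L = attr(cac, "L")) {
  if (is.null(L)) stop("L not supplied and not carried by the curve")
  L <- as.integer(L)
  vals <- as.numeric(cac)
  n <- length(vals)
  if (n <= 10L * L) stop("CAC too short for REA (need length > 10 * L)")
  num_boundaries <- as.integer(num_boundaries)
  stopifnot(num_boundaries >= 1L)
  work <- vals
  pos <- integer(0)
  exhausted <- FALSE
  for (k in seq_len(num_boundaries)) {
    if (all(!is.finite(work))) {
      exhausted <- TRUE
      warning(sprintf("CAC exhausted after %d of %d boundaries", k - 1L,
                      num_boundaries), call. = FALSE)
      break
    }
    x <- which.min(work)               # ties -> lowest index
    pos <- c(pos, x)
    work[max(1L, x - 5L * L):min(n, x + 5L * L)] <- Inf
  }
  ord <- order(pos)
  structure(list(positions = pos[ord], cac_values = vals[pos[ord]],
                 num_requested = num_boundaries, exhausted = exhausted,
                 L = L),
            class = "regime_boundaries")
}

#' REA convenience wrapper taking a regime count
#'
#' `k` regimes are separated by `k - 1` boundaries; this wrapper does that
#' arithmetic so callers thinking in regimes cannot be off by one.
#'
#' @inheritParams extract_regimes
#' @param num_regimes number of regimes (>= 2).
#' @return see [extract_regimes()].
#' @export
extract_regimes_k <- function(cac, num_regimes, L = attr(cac, "L")) {
  num_regimes <- as.integer(num_regimes)
  stopifnot(num_regimes >= 2L)
  extract_regimes(cac, num_regimes - 1L, L)
}

#' @export
print.regime_boundaries <- function(x, ...) {
  cat(sprintf("<regime_boundaries> %d of %d requested%s\n", length(x$positions),
              x$num_requested, if (x$exhausted) " (exhausted)" else ""))
  if (length(x$positions))
    print(data.frame(position = x$positions, cac = round(x$cac_values, 4)))
  invisible(x)
}

#' Learn an alert threshold from negative-only training snippets
#'
#' Statistical-process-control heuristic: given the minimum CAC value of each
#' *negative* (no regime change) training snippet, the alert threshold is the
#' mean minus three standard deviations (population sd, divide-by-n), clipped
#' to `[0, 1]`. A test snippet whose CAC dips below this value is flagged.
#'
#' @param min_cac_per_snippet numeric vector (length >= 2) of per-snippet
#'   minimum CAC values.
#' @return an `alert_threshold` list: `value`, `train_mean`, `train_std`,
#'   `n_snippets`.
#' @export
#' @examples
#' # mean 0.671, sd 0.194 -> threshold 0.089
#' learn_threshold(0.671 + 0.194 * c(-1, 1))$value
learn_threshold <- function(min_cac_per_snippet) {
  x <- as.numeric(min_cac_per_snippet)
  if (length(x) < 2L) stop("need at least 2 training snippets")
  if (any(!is.finite(x))) stop("non-finite training values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))           # population sd, fixed for reproducibility
  structure(list(value = min(max(m - 3 * s, 0), 1),
                 train_mean = m, train_std = s, n_snippets = length(x)),
            class = "alert_threshold")
}

#' Classify a snippet's CAC against a learned threshold
#'
#' Returns `"regime_change"` when the minimum of the curve falls below the
#' threshold, else `"no_evidence"`. The label is deliberately asymmetric: a
#' high minimum is *absence of evidence* for a change, not evidence that no
#' change occurred.
#'
#' @param cac a corrected arc curve.
#' @param threshold an [learn_threshold()] result (or a bare number).
#' @return `"regime_change"` or `"no_evidence"`.
#' @export
classify_snippet <- function(cac, threshold) {
  thr <- if (inherits(threshold, "alert_threshold")) threshold$value
         else as.numeric(threshold)
  if (min(as.numeric(cac)) < thr) "regime_change" else "no_evidence"
}
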