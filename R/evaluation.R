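## Segmentation scoring and the rescaled-snippet heuristic for learning the
## subsequence length L.

#' Score a proposed segmentation against ground truth
#'
#' Every predicted boundary is mapped to its *nearest* ground-truth boundary
#' (many-to-one mappings allowed, so one missed boundary does not wreck an
#' otherwise good solution), the absolute position errors are summed, and the
#' sum is divided by `length(predicted) * n`. 0 is a perfect segmentation, 1
#' the worst possible. Because mapping runs predictions -> truth, unmatched
#' ground-truth points are not directly penalized — a deliberate, documented
#' asymmetry of the metric.
#'
#' @param predicted integer positions (1-based, in `[1, n]`), non-empty.
#' @param truth integer ground-truth positions, non-empty.
#' @param n length of the underlying time series.
#' @return a `seg_score` list: `value` in `[0, 1]`, `per_boundary_distance`.
#' @export
#' @examples
#' score_segmentation(c(100, 205), c(100, 200), n = 1000)$value # 5/2000
score_segmentation <- function(predicted, truth, n) {
  predicted <- as.numeric(predicted)
  truth <- as.numeric(truth)
  n <- as.numeric(n)
  if (!length(predicted)) stop("empty prediction; caller decides the policy")
  if (!length(truth)) stop("empty ground truth")
  if (any(predicted < 1 | predicted > n) || any(truth < 1 | truth > n))
    stop(sprintf("positions must lie in [1, %d]", as.integer(n)))
  d <- vapply(predicted, function(p) min(abs(p - truth)), 1.0)
  structure(list(value = sum(d) / (length(predicted) * n),
                 per_boundary_distance = as.integer(round(d))),
            class = "seg_score")
}

#' Win / lose / draw comparison of two scores
#'
#' A method *wins* when its score is less than half its rival's; otherwise the
#' comparison is a draw. Useful for benchmark tables where the metric is too
#' fine-grained for raw ordering to be meaningful.
#'
#' @param score_a,score_b numeric scores (or `seg_score` objects).
#' @return `"win"`, `"lose"` or `"draw"` from the perspective of `score_a`.
#' @export
compare_scores <- function(score_a, score_b) {
  a <- if (inherits(score_a, "seg_score")) score_a$value else as.numeric(score_a)
  b <- if (inherits(score_b, "seg_score")) score_b$value else as.numeric(score_b)
  if (a < b / 2) "win" else if (b < a / 2) "lose" else "draw"
}

#' Build a labeled training pair by appending a rescaled copy of a snippet
#'
#' With only unlabeled snippets of a single behavior available, labeled
#' regime-change data can be manufactured: concatenate the snippet with a
#' copy of itself linearly resampled to `shrink` (default 95%) of its length.
#' The rate change is barely perceptible to the eye, yet constitutes a true
#' regime change at exactly `length(snippet)` — which is what the label
#' says.
#'
#' @param snippet numeric vector or [ts_series()]; ideally >= 10 periods of
#'   its dominant cycle.
#' @param shrink rescaling factor in (0, 1).
#' @return list with `series` (length `n + round(shrink * n)`) and
#'   `boundary` (= `length(snippet)`).
#' @export
make_length_training_pair <- function(snippet, shrink = 0.95) {
  x <- as_series_values(snippet)
  if (!is.numeric(shrink) || length(shrink) != 1L || shrink <= 0 || shrink >= 1)
    stop("shrink must lie strictly inside (0, 1)")
  n <- length(x)
  n2 <- max(2L, as.integer(round(shrink * n)))
  rescaled <- stats::approx(x = seq_len(n), y = x,
                            xout = seq(1, n, length.out = n2))$y
  list(series = c(x, rescaled), boundary = n)
}

#' Learn the subsequence length L from a single-behavior snippet
#'
#' For each candidate `L`, runs the batch pipeline ([fluss()] +
#' [extract_regimes()] asking for one boundary) on the synthetic rescaled
#' pair from [make_length_training_pair()] and scores the detected boundary
#' against the known junction; returns the grid minimizer. The score-vs-L
#' curve is typically flat near its minimum, so the exact grid spacing is not
#' critical.
#'
#' @param snippet numeric vector or [ts_series()].
#' @param grid integer vector of candidate subsequence lengths; every entry
#'   must satisfy the REA length precondition for the pair
#'   (`10 * L < length of the pair`).
#' @param shrink passed to [make_length_training_pair()].
#' @return a `length_search` list: `best_L`, `grid`, `scores`.
#' @export
learn_subsequence_length <- function(snippet, grid, shrink = 0.95) {
  grid <- as.integer(grid)
  stopifnot(length(grid) >= 1L)
  pair <- make_length_training_pair(snippet, shrink)
  npair <- length(pair$series)
  bad <- grid[10L * grid >= npair]
  if (length(bad))
    stop(sprintf("grid value(s) %s too large for the %d-sample synthetic pair (need 10*L < n)",
                 paste(bad, collapse = ", "), npair))
  scores <- vapply(grid, function(L) {
    cac <- fluss(pair$series, subseq_params(L))
    bd <- extract_regimes(cac, num_boundaries = 1L, L = L)
    score_segmentation(bd$positions, pair$boundary, npair)$value
  }, 1.0)
  best <- which.min(scores)
  structure(list(best_L = grid[best], grid = grid, scores = scores),
            class = "length_search")
}

#' @export
print.length_search <- function(x, ...) {
  cat(sprintf("<length_search> best_L = %d (score %.4g)\n",
              x$best_L, min(x$scores)))
  print(data.frame(L = x$grid, score = signif(x$scores, 4)))
  invisible(x)
}
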