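## FLOSS driver: maintain the one-directional CAC over a sliding window and
## emit boundary events / alerts as the stream advances.

#' Configuration for a streaming FLOSS run
#'
#' @param window_w sliding-window capacity in samples; must be >= `4 * L` so
#'   several pattern repetitions fit in view.
#' @param params a [subseq_params()] (or bare `L`); its `tc_samples`, if set,
#'   constrains the left-neighbor search.
#' @param report_every emit an event every this many ingested samples once
#'   the window is full (default 1: per-point maintenance; raise it to thin
#'   output — the per-point cumulative-sum recompute is cheap either way).
#' @param threshold optional [learn_threshold()] result or bare number in
#'   `[0, 1]`; when set, events dipping below it are flagged as alerts, with
#'   successive alerts within `5 * L` samples merged into one (the streaming
#'   analogue of the REA exclusion zone).
#' @param iac_trials,iac_seed Monte-Carlo settings for the one-directional
#'   null curve, computed once per run for the full-window length and cached.
#' @return a `floss_config` list.
#' @export
floss_config <- function(window_w, params, report_every = 1L,
                         threshold = NULL, iac_trials = 200L, iac_seed = 7L) {
  params <- as_subseq_params(params)
  window_w <- as.integer(window_w)
  if (window_w < 4L * params$L) stop("window_w must be at least 4 * L")
  report_every <- as.integer(report_every)
  stopifnot(report_every >= 1L)
  thr <- if (is.null(threshold)) NULL
         else if (inherits(threshold, "alert_threshold")) threshold$value
         else as.numeric(threshold)
  structure(list(window_w = window_w, params = params,
                 report_every = report_every, threshold = thr,
                 iac_trials = as.integer(iac_trials),
                 iac_seed = as.integer(iac_seed)),
            class = "floss_config")
}

## CAC of the current (full) window from the streaming left-only index
stream_window_cac <- function(state, iac1d) {
  prof <- stream_left_profile(state)
  idx <- prof$mp_index
  idx[!is.finite(prof$mp_values)] <- NA_integer_   # sentinels carry no arc
  ac <- compute_arc_curve(idx)
  compute_cac(ac, iac1d)
}

#' Run FLOSS over a stream of samples
#'
#' Ingests the source sample by sample ([stream_ingress()] /
#' [stream_egress()]); once the window is full, every `report_every` steps the
#' left-only arc curve is normalized by the one-directional null and an event
#' is emitted carrying the minimizing position translated into global stream
#' coordinates. Streams shorter than the window produce zero events and a
#' warning.
#'
#' @param source numeric vector of finite samples (the stream).
#' @param config a [floss_config()].
#' @param keep_window_cac keep each event's full window CAC for audit
#'   (memory-hungry; default FALSE).
#' @return a `floss_events` data.frame with columns `step` (samples ingested),
#'   `global_position` (1-based position of the window CAC minimum in the
#'   full stream), `cac_min`, `alert`; the final state and config are
#'   attached as attributes.
#' @export
run_floss <- function(source, config, keep_window_cac = FALSE) {
  stopifnot(inherits(config, "floss_config"))
  x <- as_series_values(source)
  w <- config$window_w
  L <- config$params$L
  m_full <- w - L + 1L
  iac1d <- idealized_arc_curve(m_full, "one_directional",
                               trials = config$iac_trials,
                               seed = config$iac_seed)
  state <- floss_state(w, config$params)
  events <- list()
  cacs <- list()
  last_alert_pos <- -Inf
  for (t in seq_along(x)) {
    state <- stream_ingress(state, x[t])
    if (length(state$values) == w && t %% config$report_every == 0L) {
      cac <- stream_window_cac(state, iac1d)
      k <- which.min(cac)
      gpos <- state$start_global + k - 1L
      cmin <- as.numeric(cac[k])
      alert <- FALSE
      if (!is.null(config$threshold) && cmin < config$threshold &&
          gpos - last_alert_pos > 5L * L) {
        alert <- TRUE
        last_alert_pos <- gpos
      }
      events[[length(events) + 1L]] <-
        data.frame(step = t, global_position = gpos, cac_min = cmin,
                   alert = alert)
      if (keep_window_cac) cacs[[length(events)]] <- cac
    }
  }
  if (!length(events)) {
    warning("stream shorter than the window: no events emitted", call. = FALSE)
    out <- data.frame(step = integer(0), global_position = integer(0),
                      cac_min = numeric(0), alert = logical(0))
  } else {
    out <- do.call(rbind, events)
  }
  attr(out, "state") <- state
  attr(out, "config") <- config
  if (keep_window_cac) attr(out, "window_cacs") <- cacs
  class(out) <- c("floss_events", "data.frame")
  out
}
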