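## Streaming one-directional nearest-neighbor state.
##
## The state keeps the last (up to) w samples plus, for every complete
## subsequence in the window, its *left* nearest neighbor (an arc pointing
## strictly backward in time). Positions are stored as global stream indices,
## so egress never rewrites the surviving entries: the window origin simply
## advances. Window-relative views are derived on demand.

#' Create an empty streaming window state
#'
#' @param w window capacity in samples; must satisfy `w >= 2 * L`.
#' @param params a [subseq_params()] object (or bare `L`).
#' @return a `floss_state` list. Feed it samples with [stream_ingress()].
#' @export
floss_state <- function(w, params) {
  params <- as_subseq_params(params)
  w <- as.integer(w)
  if (w < 2L * params$L) stop("window capacity w must be at least 2 * L")
  structure(list(values = numeric(0), start_global = 1L, w = w,
                 params = params, count_ingested = 0L,
                 left_index = integer(0),   # global subsequence starts, NA = sentinel
                 left_values = numeric(0),
                 n_dp_calls = 0L),          # instrumentation: distance-profile calls
            class = "floss_state")
}

## admissible left-neighbor window-local range for local subsequence i_loc
left_admissible <- function(i_loc, params) {
  lo <- 1L
  if (!is.null(params$tc_samples)) lo <- max(lo, i_loc - params$tc_samples)
  hi <- i_loc - params$exclusion_halfwidth - 1L
  if (hi < lo) return(NULL)
  c(lo, hi)
}

## left nearest neighbor of the window-local subsequence i_loc, searched over
## the current window contents; returns list(j_loc, d) or NULL
left_nn <- function(state, i_loc) {
  rng <- left_admissible(i_loc, state$params)
  if (is.null(rng)) return(NULL)
  L <- state$params$L
  query <- state$values[i_loc:(i_loc + L - 1L)]
  ## distances only over the admissible prefix of windows
  seg <- state$values[rng[1]:(rng[2] + L - 1L)]
  d <- suppressWarnings(dist_profile(query, seg))
  j <- which.min(d)
  list(j_loc = rng[1] + j - 1L, d = d[j])
}

#' Ingest one sample into the streaming state
#'
#' Appends the sample (evicting the oldest first if the window is full), and
#' when a new complete subsequence is formed, finds its left nearest neighbor
#' by a single distance-profile call over the current window — one FFT-sized
#' unit of work per arriving point. Existing entries are never touched: arcs
#' only point backward, so earlier subsequences cannot prefer the newcomer.
#'
#' @param state a [floss_state()].
#' @param value a finite numeric sample.
#' @return the updated state.
#' @export
stream_ingress <- function(state, value) {
  stopifnot(inherits(state, "floss_state"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("ingested value must be a single finite number")
  if (length(state$values) == state$w) state <- stream_egress(state)
  state$values <- c(state$values, value)
  state$count_ingested <- state$count_ingested + 1L
  len <- length(state$values)
  L <- state$params$L
  if (len >= L) {
    i_loc <- len - L + 1L
    nn <- left_nn(state, i_loc)
    state$n_dp_calls <- state$n_dp_calls + !is.null(nn)
    if (is.null(nn)) {
      state$left_index <- c(state$left_index, NA_integer_)
      state$left_values <- c(state$left_values, Inf)
    } else {
      state$left_index <- c(state$left_index,
                            state$start_global + nn$j_loc - 1L)
      state$left_values <- c(state$left_values, nn$d)
    }
  }
  state
}

#' Evict the oldest sample from a full streaming window
#'
#' Drops the oldest sample and the oldest profile entry in one step, then
#' repairs the (typically zero or few) surviving entries whose recorded
#' neighbor was the evicted subsequence, so that no dangling reference
#' remains and the state stays exactly equal to a batch left-only profile of
#' the current window. No routine rescan of the whole index happens: repair
#' work is triggered only by actual danglers (see `n_dp_calls`).
#'
#' @param state a full [floss_state()].
#' @return the updated state.
#' @export
stream_egress <- function(state) {
  stopifnot(inherits(state, "floss_state"))
  if (length(state$values) < state$w)
    stop("egress on non-full window")
  evicted <- state$start_global        # global start of the departing subsequence
  state$values <- state$values[-1L]
  state$start_global <- state$start_global + 1L
  if (length(state$left_index)) {
    state$left_index <- state$left_index[-1L]
    state$left_values <- state$left_values[-1L]
  }
  dangling <- which(!is.na(state$left_index) & state$left_index == evicted)
  for (k in dangling) {
    i_loc <- k                          # entry k is the subsequence at local start k
    nn <- left_nn(state, i_loc)
    state$n_dp_calls <- state$n_dp_calls + !is.null(nn)
    if (is.null(nn)) {
      state$left_index[k] <- NA_integer_
      state$left_values[k] <- Inf
    } else {
      state$left_index[k] <- state$start_global + nn$j_loc - 1L
      state$left_values[k] <- nn$d
    }
  }
  state
}

#' Window-relative left profile of a streaming state
#'
#' @param state a [floss_state()].
#' @return list with `mp_index` (window-local 1-based starts, NA sentinel) and
#'   `mp_values`; comparable entry-for-entry with
#'   `compute_matrix_profile(window, params, direction = "left")`.
#' @export
stream_left_profile <- function(state) {
  stopifnot(inherits(state, "floss_state"))
  list(mp_index = as.integer(state$left_index - state$start_global + 1L),
       mp_values = state$left_values)
}

#' @export
print.floss_state <- function(x, ...) {
  cat(sprintf("<floss_state> %d/%d samples, %d ingested, %d subsequences\n",
              length(x$values), x$w, x$count_ingested, length(x$left_index)))
  invisible(x)
}
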