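## File I/O. The R API is 1-based; every file written or read here uses
## 0-based sample indices, stated in each file's header where the format
## allows one.

## delimiter sniffing: comma, tab, else whitespace
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) return(",")
  if (grepl("\t", first, fixed = TRUE)) return("\t")
  ""
}

#' Read one or more time-series channels from a delimited text file
#'
#' Accepts a single-column file (one sample per line) or a multi-column
#' CSV/TSV, with or without a header row (auto-detected: a first row that
#' does not parse as numbers is treated as a header). Non-numeric cells and
#' NaN rows are rejected with their line numbers.
#'
#' @param path file path.
#' @param columns column names or indices to keep (default: all).
#' @param sampling_rate_hz optional rate annotation applied to each channel.
#' @return a list of equal-length [ts_series()] channels, named after the
#'   file's columns when a header is present.
#' @export
read_series <- function(path, columns = NULL, sampling_rate_hz = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  sep <- sniff_sep(path)
  first <- scan(path, what = character(), nlines = 1L, sep = if (sep == "") "" else sep,
                quiet = TRUE, comment.char = "#")
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(path, header = header, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    missing_cols <- if (is.character(columns)) setdiff(columns, names(df))
                    else columns[columns > ncol(df)]
    if (length(missing_cols))
      stop(sprintf("column(s) not present: %s",
                   paste(missing_cols, collapse = ", ")))
    df <- df[, columns, drop = FALSE]
  }
  header_off <- as.integer(header)
  lapply(stats::setNames(seq_along(df), names(df)), function(k) {
    v <- df[[k]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric cell in column %s at line %d",
                   names(df)[k], bad + header_off))
    }
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-finite value(s) in column %s at line(s) %s",
                   names(df)[k],
                   paste(utils::head(bad + header_off, 5L), collapse = ", ")))
    ts_series(v, sampling_rate_hz = sampling_rate_hz)
  })
}

#' Write one or more channels to a delimited text file
#'
#' @param series a [ts_series()] or list of equal-length channels.
#' @param path output path; `.csv` extension writes comma-separated,
#'   anything else tab-separated.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  channels <- if (is.list(series) && !inherits(series, "floss_ts"))
    series else list(series)
  xs <- lapply(channels, as_series_values)
  if (length(unique(vapply(xs, length, 1L))) != 1L)
    stop("channels must have equal length")
  df <- as.data.frame(xs, col.names = paste0("ch", seq_along(xs)))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' Write a corrected arc curve as two-column TSV
#'
#' Columns: 0-based position, CAC value.
#'
#' @param cac a [compute_cac()]/[fluss()] curve.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cac <- function(cac, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# position(0-based)\tcac", con)
  utils::write.table(data.frame(pos = seq_along(cac) - 1L,
                                cac = as.numeric(cac)),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write regime boundaries as JSON
#'
#' Positions are converted to 0-based sample indices in the file.
#'
#' @param boundaries an [extract_regimes()] result.
#' @param path output path.
#' @param params optional [subseq_params()] echoed into the file.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path, params = NULL) {
  stopifnot(inherits(boundaries, "regime_boundaries"))
  obj <- list(positions = boundaries$positions - 1L,
              cac_values = boundaries$cac_values,
              num_requested = boundaries$num_requested,
              exhausted = boundaries$exhausted,
              index_base = 0L)
  if (!is.null(params))
    obj$params <- list(L = params$L,
                       exclusion_halfwidth = params$exclusion_halfwidth,
                       tc_samples = params$tc_samples)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read ground-truth boundary positions
#'
#' One integer per line, 0-based in the file; returned 1-based.
#'
#' @param path file path.
#' @return integer vector of 1-based positions.
#' @export
read_boundaries <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (any(v != floor(v))) stop("boundary file must contain integers")
  as.integer(v) + 1L
}

#' Write ground-truth boundary positions (one integer per line, 0-based)
#'
#' @param positions 1-based integer positions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(positions, path) {
  writeLines(as.character(as.integer(positions) - 1L), path)
  invisible(path)
}

#' Write streaming events as JSON-lines
#'
#' One JSON object per event; `global_position` is 0-based in the file.
#'
#' @param events a [run_floss()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(list(step = events$step[i],
                                     global_position = events$global_position[i] - 1L,
                                     cac_min = events$cac_min[i],
                                     alert = events$alert[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
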