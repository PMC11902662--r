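#' Construct a multichannel insole recording
#'
#' A `recording` is a fixed-rate multichannel time series from one run of
#' one participant: plantar pressure in kg/cm^2, acceleration in g, angular
#' velocity in dps and magnetic field in gauss. Channel names come from the
#' canonical 26-name set (see [ski_channels()]).
#'
#' @param samples numeric matrix, rows = time ticks, columns = channels.
#'   `NA` entries are explicit missing markers for the cleaning stage.
#' @param channels character vector of canonical channel names, one per
#'   column of `samples`.
#' @param participant_id,run_id identifying strings.
#' @param rate_hz sampling rate in Hz (positive; 100 for the datalogger).
#' @param start_ms time of the first row, in ms from the run origin. Kept so
#'   that segments produced by [clean_recording()] stay aligned with label
#'   intervals.
#' @return an object of class `recording`.
#' @export
#' @examples
#' rec <- recording(matrix(0, 10, 2), c("R_H", "L_H"), "A", "run1")
#' n_samples(rec)
recording <- function(samples, channels, participant_id = "A",
                      run_id = "run1", rate_hz = 100, start_ms = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  rec <- structure(
    list(participant_id = as.character(participant_id),
         run_id = as.character(run_id),
         rate_hz = as.numeric(rate_hz),
         start_ms = as.numeric(start_ms),
         channels = as.character(channels),
         samples = samples),
    class = "recording")
  validate_recording(rec)
}

#' @rdname recording
#' @param rec a `recording`.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(rec$rate_hz) || length(rec$rate_hz) != 1 || rec$rate_hz <= 0) {
    stop("rate_hz must be a single positive number", call. = FALSE)
  }
  bad <- setdiff(rec$channels, ski_channels())
  if (length(bad) > 0) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rec$channels)) {
    stop("duplicate channel names", call. = FALSE)
  }
  if (ncol(rec$samples) != length(rec$channels)) {
    stop("samples must have one column per channel", call. = FALSE)
  }
  colnames(rec$samples) <- rec$channels
  rec
}

#' @rdname recording
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' @rdname recording
#' @export
duration_ms <- function(rec) n_samples(rec) * 1000 / rec$rate_hz

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> participant %s, run %s: %d samples x %d channels @ %g Hz (%.1f s, start %g ms)\n",
    x$participant_id, x$run_id, n_samples(x), length(x$channels),
    x$rate_hz, duration_ms(x) / 1000, x$start_ms))
  invisible(x)
}

# fixed significant-digit formatting so writes are byte-deterministic and
# round-trip to >= 6 significant digits; NA -> empty cell
format_cells <- function(m, digits = 7) {
  out <- sprintf(paste0("%.", digits, "g"), m)
  out[is.na(m)] <- ""
  dim(out) <- dim(m)
  out
}

#' Write a recording to a datalogger-style text file
#'
#' The dialect is a plain CSV: `#`-prefixed metadata lines
#' (participant_id, run_id, rate_hz, start_ms), then a header row naming a
#' leading `time_ms` column followed by the channels, then one row per tick.
#' Missing values are written as empty cells. Values are written with 7
#' significant digits so a write/read round trip is the identity to well
#' below 1e-6 relative tolerance.
#'
#' @param rec a valid `recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  rec <- validate_recording(rec)
  n <- n_samples(rec)
  time_ms <- rec$start_ms + (seq_len(n) - 1) * 1000 / rec$rate_hz
  meta <- c(sprintf("# participant_id: %s", rec$participant_id),
            sprintf("# run_id: %s", rec$run_id),
            sprintf("# rate_hz: %.10g", rec$rate_hz),
            sprintf("# start_ms: %.10g", rec$start_ms))
  header <- paste(c("time_ms", rec$channels), collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, header), con)
  if (n > 0) {
    cells <- cbind(sprintf("%.10g", time_ms), format_cells(rec$samples))
    writeLines(apply(cells, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a datalogger-style recording file
#'
#' Inverse of [write_recording()]. The reader validates rather than repairs:
#' unknown channel names, a missing or non-monotone time column, or
#' non-uniform sampling raise a format error. Blank cells become `NA`
#' missing markers for the cleaning stage.
#'
#' @param path file written by [write_recording()] (or any text file in the
#'   same dialect).
#' @return a `recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(participant_id = "A", run_id = "run1",
               rate_hz = NA_real_, start_ms = 0)
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop("format error: no header row in ", path, call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 1 || header[1] != "time_ms") {
    stop("format error: first column must be time_ms", call. = FALSE)
  }
  channels <- header[-1]
  bad <- setdiff(channels, ski_channels())
  if (length(bad) > 0) {
    stop("format error: unknown channel name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0) {
    samples <- matrix(numeric(0), 0, length(channels))
    time_ms <- numeric(0)
  } else {
    parts <- strsplit(rows, ",", fixed = TRUE)
    ncell <- length(header)
    flat <- vapply(parts, function(p) {
      length(p) <- ncell          # trailing empty cells
      p
    }, character(ncell))
    flat[is.na(flat) | flat == ""] <- NA_character_
    vals <- suppressWarnings(as.numeric(flat))
    m <- matrix(vals, nrow = length(rows), ncol = ncell, byrow = TRUE)
    time_ms <- m[, 1]
    samples <- m[, -1, drop = FALSE]
    if (anyNA(time_ms) || (length(time_ms) > 1 && any(diff(time_ms) <= 0))) {
      stop("format error: time_ms column must be present and strictly increasing",
           call. = FALSE)
    }
  }
  rate_hz <- suppressWarnings(as.numeric(meta$rate_hz))
  if (is.na(rate_hz)) {
    if (length(time_ms) > 1) {
      rate_hz <- 1000 / stats::median(diff(time_ms))
    } else {
      rate_hz <- 100
    }
  }
  if (length(time_ms) > 1) {
    step <- diff(time_ms)
    if (max(abs(step - 1000 / rate_hz)) > 1e-6 * (1000 / rate_hz) + 1e-9) {
      stop("format error: non-uniform sampling interval", call. = FALSE)
    }
  }
  start_ms <- if (length(time_ms) > 0) time_ms[1] else
    suppressWarnings(as.numeric(meta$start_ms))
  if (is.na(start_ms)) start_ms <- 0
  recording(samples, channels,
            participant_id = meta$participant_id, run_id = meta$run_id,
            rate_hz = rate_hz, start_ms = start_ms)
}

#' Gear label intervals for one run
#'
#' A `label_track` marks the expert-annotated gear periods (the ascents):
#' non-overlapping `[start_ms, end_ms)` intervals, each carrying one gear in
#' `r paste(gear_levels(), collapse = ", ")`. Time between intervals
#' (preparation, turning around) is unlabeled and later excluded from
#' segmentation.
#'
#' @param intervals data frame (or coercible) with columns `start_ms`,
#'   `end_ms`, `gear`.
#' @return a `label_track`: a validated, start-sorted data frame.
#' @export
#' @examples
#' label_track(data.frame(start_ms = 0, end_ms = 10000, gear = "G3"))
label_track <- function(intervals) {
  df <- as.data.frame(intervals)
  stopifnot(all(c("start_ms", "end_ms", "gear") %in% names(df)))
  df <- df[, c("start_ms", "end_ms", "gear")]
  df$start_ms <- as.numeric(df$start_ms)
  df$end_ms <- as.numeric(df$end_ms)
  df$gear <- as_gear(df$gear)
  if (any(!is.finite(df$start_ms)) || any(!is.finite(df$end_ms))) {
    stop("label intervals must have finite start_ms/end_ms", call. = FALSE)
  }
  if (any(df$start_ms >= df$end_ms)) {
    stop("label intervals must satisfy start_ms < end_ms", call. = FALSE)
  }
  df <- df[order(df$start_ms), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1 && any(df$start_ms[-1] < df$end_ms[-nrow(df)])) {
    stop("label intervals overlap", call. = FALSE)
  }
  structure(df, class = c("label_track", "data.frame"))
}

#' @rdname label_track
#' @param track a `label_track`.
#' @param path CSV path with columns `start_ms,end_ms,gear`.
#' @export
write_labels <- function(track, path) {
  track <- label_track(track)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("start_ms,end_ms,gear", con)
  if (nrow(track) > 0) {
    writeLines(sprintf("%.10g,%.10g,%s", track$start_ms, track$end_ms,
                       as.character(track$gear)), con)
  }
  invisible(path)
}

#' @rdname label_track
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_track(df)
}
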