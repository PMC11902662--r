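# Preprocessing chain: pressure offset removal, force-to-pressure
# conversion, gap cleaning, EMA smoothing, sliding-window segmentation with
# per-subframe median features, and train-statistics normalization.

#' Pressure sensor geometry
#'
#' The piezoresistive sensors are 9.53 mm diameter discs; force readings in
#' kg are converted to pressure by dividing by the sensing area,
#' `pi * (d/2)^2` = 0.7133057 cm^2.
#'
#' @param diameter_mm sensor diameter in mm.
#' @return list with `diameter_mm` and derived `area_cm2`.
#' @export
sensor_geometry <- function(diameter_mm = 9.53) {
  stopifnot(diameter_mm > 0)
  structure(list(diameter_mm = diameter_mm,
                 area_cm2 = pi * (diameter_mm / 20)^2),
            class = "sensor_geometry")
}

#' Convert a force reading to pressure
#'
#' @param force_kg non-negative force in kg.
#' @param geom a [sensor_geometry()].
#' @return pressure in kg/cm^2 (`force_kg / area_cm2`).
#' @export
#' @examples
#' force_to_pressure(1)  # ~1.402 kg/cm^2
force_to_pressure <- function(force_kg, geom = sensor_geometry()) {
  stopifnot(inherits(geom, "sensor_geometry"))
  if (any(force_kg < 0)) stop("force must be >= 0", call. = FALSE)
  force_kg / geom$area_cm2
}

#' Remove the piezoresistive baseline from pressure channels
#'
#' Each pressure channel carries a sensor-specific baseline offset even
#' when the ski is off the snow. The default estimator takes the 5th
#' percentile of the channel over the run (a non-contact-phase proxy),
#' subtracts it and clips at zero. Inertial channels are untouched.
#'
#' @param rec a `recording` containing at least one pressure channel.
#' @param baseline either a probability in (0,1) for a per-channel quantile
#'   estimator (default 0.05), or a function `f(x) -> scalar` applied to
#'   each pressure channel (missing values removed first).
#' @return the recording with zero-baseline pressure channels; the
#'   estimated baselines are attached as attribute `"baseline"`.
#' @export
remove_offset <- function(rec, baseline = 0.05) {
  rec <- validate_recording(rec)
  pch <- pressure_channels(rec$channels)
  if (length(pch) == 0) stop("no pressure channels present", call. = FALSE)
  est <- if (is.function(baseline)) baseline else
    function(x) unname(stats::quantile(x, probs = baseline, names = FALSE))
  base <- vapply(pch, function(ch) {
    x <- rec$samples[, ch]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("channel ", ch, " is entirely missing", call. = FALSE)
    est(x)
  }, numeric(1))
  for (ch in pch) {
    rec$samples[, ch] <- pmax(rec$samples[, ch] - base[[ch]], 0)
  }
  attr(rec, "baseline") <- base
  rec
}

#' Exponential moving average
#'
#' The first-order recursive smoother `y[1] = x[1]`,
#' `y[t] = alpha * x[t] + (1 - alpha) * y[t-1]`.
#'
#' @param x non-empty numeric vector (no missing values).
#' @param alpha smoothing factor in (0, 1]; `alpha = 1` is the identity.
#' @return smoothed numeric vector, same length as `x`.
#' @export
#' @examples
#' ema_smooth(c(0, 1, 1), 0.5)  # 0, 0.5, 0.75
ema_smooth <- function(x, alpha) {
  if (length(x) == 0) stop("series must be non-empty", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (anyNA(x)) stop("series contains missing values; clean first", call. = FALSE)
  if (alpha == 1) return(as.numeric(x))
  # y_t = (1-a) y_{t-1} + a x_t with y_0 chosen so that y_1 = x_1
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

#' @rdname ema_smooth
#' @param rec a `recording` without missing values.
#' @export
ema_recording <- function(rec, alpha = 0.3) {
  rec <- validate_recording(rec)
  for (j in seq_along(rec$channels)) {
    rec$samples[, j] <- ema_smooth(rec$samples[, j], alpha)
  }
  rec
}

#' Clean missing samples from a recording
#'
#' Interior missing runs of at most `max_gap_ms` per channel are linearly
#' interpolated. A longer missing run (in any channel) splits the recording
#' at that point into separate segments whose `start_ms` stays aligned with
#' the original time axis, so label intervals remain valid. Leading and
#' trailing missing samples are trimmed. A channel that is more than 50%
#' missing rejects the run.
#'
#' @param rec a `recording`.
#' @param max_gap_ms longest interpolatable gap (default 200 ms).
#' @return list of gap-free `recording` segments (length 1 when no long
#'   gap was found).
#' @export
clean_recording <- function(rec, max_gap_ms = 200) {
  rec <- validate_recording(rec)
  n <- n_samples(rec)
  if (n == 0) return(list(rec))
  frac_missing <- colMeans(is.na(rec$samples))
  if (any(frac_missing > 0.5)) {
    stop("channel(s) more than 50% missing: ",
         paste(rec$channels[frac_missing > 0.5], collapse = ", "),
         call. = FALSE)
  }
  max_gap <- floor(max_gap_ms * rec$rate_hz / 1000)
  # rows covered by a too-long missing run in any channel
  long_bad <- rep(FALSE, n)
  for (j in seq_len(ncol(rec$samples))) {
    r <- rle(is.na(rec$samples[, j]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths > max_gap)) {
      long_bad[starts[k]:ends[k]] <- TRUE
    }
  }
  any_na_row <- rowSums(is.na(rec$samples)) > 0
  # trim leading/trailing missing rows of the whole run
  good_rows <- which(!any_na_row)
  if (length(good_rows) == 0) stop("recording entirely missing", call. = FALSE)
  keep <- seq(min(good_rows), max(good_rows))
  segments <- list()
  r <- rle(long_bad[keep])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(!r$values)) {
    idx <- keep[starts[k]:ends[k]]
    m <- rec$samples[idx, , drop = FALSE]
    # interpolate remaining (short) interior gaps per channel
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) {
        ok <- which(!na)
        m[na, j] <- stats::approx(ok, m[ok, j], xout = which(na), rule = 2)$y
      }
    }
    seg <- recording(m, rec$channels, participant_id = rec$participant_id,
                     run_id = rec$run_id, rate_hz = rec$rate_hz,
                     start_ms = rec$start_ms + (idx[1] - 1) * 1000 / rec$rate_hz)
    segments[[length(segments) + 1L]] <- seg
  }
  segments
}

#' Segmented, labeled window tensor
#'
#' The model input container: an `n x steps x channels` array of
#' per-subframe medians, one gear label and one participant id per window.
#'
#' @param tensor numeric array `windows x steps x channels`.
#' @param labels gear label per window.
#' @param groups participant id per window.
#' @param window_ms,stride_ms,subframe_ms segmentation parameters.
#' @param channel_names channel name per tensor slice.
#' @return a `window_set`.
#' @export
window_set <- function(tensor, labels, groups, window_ms, stride_ms,
                       subframe_ms, channel_names) {
  stopifnot(length(dim(tensor)) == 3)
  steps <- window_ms / subframe_ms
  if (steps != round(steps)) {
    stop("window_ms must be divisible by subframe_ms", call. = FALSE)
  }
  if (dim(tensor)[1] > 0 && dim(tensor)[2] != steps) {
    stop("tensor step axis disagrees with window_ms / subframe_ms", call. = FALSE)
  }
  stopifnot(dim(tensor)[3] == length(channel_names),
            dim(tensor)[1] == length(labels),
            length(labels) == length(groups))
  structure(list(tensor = tensor, labels = as_gear(labels),
                 groups = as.character(groups),
                 window_ms = window_ms, stride_ms = stride_ms,
                 subframe_ms = subframe_ms,
                 channel_names = as.character(channel_names)),
            class = "window_set")
}

#' @rdname window_set
#' @param ws a `window_set`.
#' @export
n_windows <- function(ws) dim(ws$tensor)[1]

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d steps x %d channels (%g/%g/%g ms window/stride/subframe)\n",
              n_windows(x), dim(x$tensor)[2], dim(x$tensor)[3],
              x$window_ms, x$stride_ms, x$subframe_ms))
  if (n_windows(x) > 0) print(table(gear = x$labels, participant = x$groups))
  invisible(x)
}

# column medians of each consecutive block of `spf` rows of matrix m
# (vectorized two-key ordering; handles even and odd block sizes)
.block_medians <- function(m, spf) {
  n_sub <- nrow(m) %/% spf
  m <- m[seq_len(n_sub * spf), , drop = FALSE]
  out <- matrix(0, n_sub, ncol(m))
  block <- rep(seq_len(n_sub), each = spf)
  lo <- (spf + 1) %/% 2
  hi <- spf %/% 2 + 1
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    sorted <- matrix(x[order(block, x)], nrow = spf)
    out[, j] <- (sorted[lo, ] + sorted[hi, ]) / 2
  }
  out
}

#' Segment a recording into labeled median-feature windows
#'
#' Windows of `window_ms` start every `stride_ms` from the recording start.
#' A window is kept only when it lies entirely inside one label interval;
#' windows straddling a gear boundary or overlapping unlabeled time are
#' dropped (transition periods are excluded from analysis). Each kept
#' window is reduced to `window_ms / subframe_ms` per-subframe medians per
#' channel, giving the classifier a genuine temporal axis while denoising
#' within subframes.
#'
#' @param rec a cleaned (gap-free) `recording`.
#' @param track a `label_track` on the same time axis.
#' @param window_ms window length (default 5000 ms).
#' @param stride_ms step between window starts (default 50 ms).
#' @param subframe_ms median-feature granularity (default 50 ms).
#' @return a `window_set` (possibly with zero windows).
#' @export
segment_windows <- function(rec, track, window_ms = 5000, stride_ms = 50,
                            subframe_ms = 50) {
  rec <- validate_recording(rec)
  track <- label_track(track)
  if (anyNA(rec$samples)) stop("recording has missing values; clean first", call. = FALSE)
  steps <- window_ms / subframe_ms
  if (steps != round(steps)) {
    stop("window_ms must be divisible by subframe_ms", call. = FALSE)
  }
  spf <- subframe_ms * rec$rate_hz / 1000        # samples per subframe
  spw <- window_ms * rec$rate_hz / 1000          # samples per window
  sps <- stride_ms * rec$rate_hz / 1000          # samples per stride
  if (spf != round(spf) || spw != round(spw) || sps != round(sps)) {
    stop("window/stride/subframe must be whole numbers of samples", call. = FALSE)
  }
  spf <- as.integer(spf); spw <- as.integer(spw); sps <- as.integer(sps)
  n <- n_samples(rec)
  nwin <- if (n < spw) 0L else (n - spw) %/% sps + 1L
  empty <- function() window_set(
    array(0, c(0, steps, length(rec$channels))), character(0), character(0),
    window_ms, stride_ms, subframe_ms, rec$channels)
  if (nwin == 0L) return(empty())
  win_start_row <- (seq_len(nwin) - 1L) * sps + 1L
  win_start_ms <- rec$start_ms + (win_start_row - 1) * 1000 / rec$rate_hz
  win_end_ms <- win_start_ms + window_ms
  # label: the interval (if any) fully containing the window
  lab <- rep(NA_character_, nwin)
  for (i in seq_len(nrow(track))) {
    inside <- win_start_ms >= track$start_ms[i] & win_end_ms <= track$end_ms[i]
    lab[inside] <- as.character(track$gear[i])
  }
  keep <- which(!is.na(lab))
  if (length(keep) == 0) return(empty())
  aligned <- sps %% spf == 0
  pre <- if (aligned) .block_medians(rec$samples, spf) else NULL
  tensor <- array(0, c(length(keep), steps, length(rec$channels)))
  for (w in seq_along(keep)) {
    r0 <- win_start_row[keep[w]]
    if (aligned) {
      s0 <- (r0 - 1L) %/% spf + 1L
      tensor[w, , ] <- pre[s0:(s0 + steps - 1L), ]
    } else {
      tensor[w, , ] <- .block_medians(
        rec$samples[r0:(r0 + spw - 1L), , drop = FALSE], spf)
    }
  }
  window_set(tensor, lab[keep], rep(rec$participant_id, length(keep)),
             window_ms, stride_ms, subframe_ms, rec$channels)
}

#' Combine window sets
#'
#' @param ws_list list of `window_set`s with identical window parameters
#'   and channel names.
#' @return the row-concatenated `window_set`.
#' @export
combine_windows <- function(ws_list) {
  ws_list <- Filter(function(w) n_windows(w) > 0, ws_list)
  if (length(ws_list) == 0) stop("no windows to combine", call. = FALSE)
  ref <- ws_list[[1]]
  for (w in ws_list[-1]) {
    stopifnot(identical(w$channel_names, ref$channel_names),
              identical(c(w$window_ms, w$stride_ms, w$subframe_ms),
                        c(ref$window_ms, ref$stride_ms, ref$subframe_ms)))
  }
  ntot <- sum(vapply(ws_list, n_windows, integer(1)))
  steps <- dim(ref$tensor)[2]
  tensor <- array(0, c(ntot, steps, dim(ref$tensor)[3]))
  labels <- character(ntot); groups <- character(ntot)
  at <- 0L
  for (w in ws_list) {
    idx <- at + seq_len(n_windows(w))
    tensor[idx, , ] <- w$tensor
    labels[idx] <- as.character(w$labels)
    groups[idx] <- w$groups
    at <- at + n_windows(w)
  }
  window_set(tensor, labels, groups, ref$window_ms, ref$stride_ms,
             ref$subframe_ms, ref$channel_names)
}

#' Restrict a window set to a channel subset
#'
#' @param ws a `window_set`.
#' @param channels channel names to keep (e.g. from [channels_for()]).
#' @return the reduced `window_set`, slices in the requested order.
#' @export
select_channels <- function(ws, channels) {
  idx <- match(channels, ws$channel_names)
  if (anyNA(idx)) {
    stop("channel(s) not in window set: ",
         paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  window_set(ws$tensor[, , idx, drop = FALSE], ws$labels, ws$groups,
             ws$window_ms, ws$stride_ms, ws$subframe_ms, channels)
}

#' Subset windows by index or participant
#'
#' @param ws a `window_set`.
#' @param idx integer or logical index over windows.
#' @return the subset `window_set`.
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$tensor[idx, , , drop = FALSE], ws$labels[idx], ws$groups[idx],
             ws$window_ms, ws$stride_ms, ws$subframe_ms, ws$channel_names)
}

#' Per-channel normalization statistics from training windows
#'
#' Mean and standard deviation per channel over all training windows and
#' steps. Validation data must be transformed with the training statistics
#' only (no leakage). A zero-variance channel gets sd 1 with a warning.
#'
#' @param train a non-empty training `window_set`.
#' @return a `norm_stats` list with `mean` and `sd` per channel.
#' @export
fit_norm <- function(train) {
  stopifnot(inherits(train, "window_set"))
  if (n_windows(train) == 0) stop("training window set is empty", call. = FALSE)
  nch <- dim(train$tensor)[3]
  mu <- numeric(nch); sdv <- numeric(nch)
  for (j in seq_len(nch)) {
    x <- train$tensor[, , j]
    mu[j] <- mean(x)
    sdv[j] <- stats::sd(as.vector(x))
  }
  zero <- !is.finite(sdv) | sdv == 0
  if (any(zero)) {
    warning("zero-variance channel(s): ",
            paste(train$channel_names[zero], collapse = ", "),
            "; sd set to 1")
    sdv[zero] <- 1
  }
  structure(list(mean = stats::setNames(mu, train$channel_names),
                 sd = stats::setNames(sdv, train$channel_names)),
            class = "norm_stats")
}

#' @rdname fit_norm
#' @param ws a `window_set` with the same channels as the training set.
#' @param stats a `norm_stats` from [fit_norm()].
#' @export
apply_norm <- function(ws, stats) {
  stopifnot(inherits(ws, "window_set"), inherits(stats, "norm_stats"))
  if (!identical(ws$channel_names, names(stats$mean))) {
    stop("channel mismatch between window set and normalization stats",
         call. = FALSE)
  }
  for (j in seq_along(ws$channel_names)) {
    ws$tensor[, , j] <- (ws$tensor[, , j] - stats$mean[j]) / stats$sd[j]
  }
  ws
}

#' Full preprocessing of one labeled run
#'
#' Offset removal, gap cleaning, EMA smoothing and segmentation, in that
#' order (normalization is fold-dependent and applied later via
#' [fit_norm()]/[apply_norm()]).
#'
#' @param rec raw `recording`.
#' @param track its `label_track`.
#' @param alpha EMA smoothing factor.
#' @param baseline offset estimator, see [remove_offset()].
#' @param max_gap_ms see [clean_recording()].
#' @inheritParams segment_windows
#' @return a `window_set` for the run (zero windows possible).
#' @export
preprocess_run <- function(rec, track, window_ms = 5000, stride_ms = 50,
                           subframe_ms = 50, alpha = 0.3, baseline = 0.05,
                           max_gap_ms = 200) {
  rec <- remove_offset(rec, baseline)
  segs <- clean_recording(rec, max_gap_ms)
  ws <- lapply(segs, function(s) {
    segment_windows(ema_recording(s, alpha), track, window_ms, stride_ms,
                    subframe_ms)
  })
  ws <- Filter(function(w) n_windows(w) > 0, ws)
  if (length(ws) == 0) {
    steps <- window_ms / subframe_ms
    return(window_set(array(0, c(0, steps, length(rec$channels))),
                      character(0), character(0), window_ms, stride_ms,
                      subframe_ms, rec$channels))
  }
  combine_windows(ws)
}

#' Preprocess a whole dataset into one window set
#'
#' @param dataset result of [load_dataset()] (or a directory path).
#' @param ... passed to [preprocess_run()].
#' @return combined `window_set` with participant groups.
#' @export
preprocess_dataset <- function(dataset, ...) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  ws <- lapply(dataset$runs, function(r) {
    preprocess_run(r$recording, r$labels, ...)
  })
  combine_windows(ws)
}
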