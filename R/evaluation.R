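# Metrics, participant-grouped cross-validation and the sensor-ablation
# harness. Weighted average accuracy (WAA) is support-weighted recall,
# which equals overall accuracy (trace/total of the confusion matrix).

#' Confusion matrix over the gear classes
#'
#' @param y_true,y_pred equal-length gear label vectors (values among
#'   [gear_levels()]; unknown labels are an error).
#' @return 3x3 integer matrix, rows = true, cols = predicted, class order
#'   G2R, G3, G2L.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  y_true <- as_gear(y_true); y_pred <- as_gear(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  unclass(table(true = y_true, predicted = y_pred))
}

#' Per-class precision, recall, F1 and support
#'
#' `precision_c` = diagonal / column sum, `recall_c` = diagonal / row sum,
#' F1 their harmonic mean; a zero denominator yields 0 with a warning.
#' Works on any square count matrix with class dimnames.
#'
#' @param conf square confusion matrix (rows true, cols predicted).
#' @return data frame with columns `class`, `precision`, `recall`, `f1`,
#'   `support`.
#' @export
class_report <- function(conf) {
  conf <- as.matrix(conf)
  stopifnot(nrow(conf) == ncol(conf), all(conf >= 0))
  classes <- rownames(conf)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(conf)))
  d <- diag(conf)
  cs <- colSums(conf); rs <- rowSums(conf)
  zdiv <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning("zero denominator in ", what, " for class(es) ",
              paste(classes[den == 0], collapse = ", "), "; reported as 0",
              call. = FALSE)
    }
    out
  }
  precision <- zdiv(d, cs, "precision")
  recall <- zdiv(d, rs, "recall")
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  data.frame(class = classes, precision = unname(precision),
             recall = unname(recall), f1 = unname(f1),
             support = unname(rs))
}

#' Support-weighted average of a per-class metric
#'
#' `sum(values * supports) / sum(supports)`. Applied to per-class recalls
#' this is the weighted average accuracy (WAA), identical to overall
#' accuracy.
#'
#' @param values per-class metric values.
#' @param supports per-class window counts (total must be positive).
#' @return the weighted average.
#' @export
#' @examples
#' weighted_average(c(0.98, 0.99, 0.99), c(2933, 2106, 2799))  # ~0.9863
weighted_average <- function(values, supports) {
  stopifnot(length(values) == length(supports), all(supports >= 0))
  if (sum(supports) <= 0) stop("total support must be positive", call. = FALSE)
  sum(values * supports) / sum(supports)
}

#' Evaluation report for one prediction set
#'
#' Bundles the confusion matrix, the per-class report, support-weighted
#' precision/recall/F1 (the recall one being the WAA) and, when available,
#' the training history.
#'
#' @param conf confusion matrix from [confusion_matrix()].
#' @param history optional training history data frame.
#' @return an `eval_report`.
#' @export
eval_report <- function(conf, history = NULL) {
  per_class <- class_report(conf)
  w <- function(v) weighted_average(v, per_class$support)
  structure(list(confusion = conf, per_class = per_class,
                 waa = w(per_class$recall),
                 weighted_precision = w(per_class$precision),
                 weighted_f1 = w(per_class$f1),
                 history = history),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$confusion)
  df <- x$per_class
  df[, 2:4] <- round(df[, 2:4], 2)
  print(df, row.names = FALSE)
  cat(sprintf("WAA %.2f  weighted precision %.2f  weighted F1 %.2f\n",
              x$waa, x$weighted_precision, x$weighted_f1))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report an `eval_report`.
#' @param dir output directory; writes `report.json` (metrics + history)
#'   and `confusion.csv`.
#' @return the directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(per_class = report$per_class, waa = report$waa,
                  weighted_precision = report$weighted_precision,
                  weighted_f1 = report$weighted_f1,
                  history = report$history)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(dir, "confusion.csv"))
  invisible(dir)
}

#' Participant-exclusive fold assignment
#'
#' Shuffles the unique participant ids under the seed and deals them
#' round-robin into `k` near-balanced folds, so every participant's data
#' lies entirely on one side of each train/test split.
#'
#' @param participants participant id vector (duplicates allowed).
#' @param k number of folds (default 2).
#' @param seed RNG seed; identical seeds give identical assignments.
#' @return list of `k` disjoint character vectors of participant ids.
#' @export
participant_folds <- function(participants, k = 2, seed = 1L) {
  ids <- unique(as.character(participants))
  if (length(ids) < k) {
    stop("need at least ", k, " participants for ", k, "-fold grouping",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample(ids))
  split(perm, rep_len(seq_len(k), length(perm)))
}

#' Participant-grouped cross-validation of one sensor configuration
#'
#' Restricts the window set to the configuration's channels, assigns
#' participants to `k` folds, and for each fold trains on the remaining
#' participants and evaluates on the held-out ones. Normalization
#' statistics are fit on each training fold only and applied to both sides
#' (no leakage); each fold gets its own derived model/training seed.
#' Per-class metrics and the WAA are averaged across folds; the pooled
#' confusion matrix is also kept.
#'
#' @param ws preprocessed, *unnormalized* `window_set` with participant
#'   groups.
#' @param config a `sensor_config` (or its name).
#' @param tspec a [train_spec()].
#' @param mspec a [model_spec()].
#' @param k number of folds.
#' @param seed fold-assignment seed; fold f trains with seed
#'   `tspec$seed + f`.
#' @return a `cv_result`: `mean_report`, `fold_reports`, `folds`,
#'   `fold_stats` (per-fold normalization stats), `config`.
#' @export
cross_validate <- function(ws, config, tspec = train_spec(),
                           mspec = model_spec(), k = 2, seed = 1L) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(ws, "window_set"), inherits(config, "sensor_config"))
  wsub <- select_channels(ws, channels_for(config))
  folds <- participant_folds(wsub$groups, k = k, seed = seed)
  steps <- dim(wsub$tensor)[2]
  fold_reports <- list(); fold_stats <- list()
  for (f in seq_along(folds)) {
    is_val <- wsub$groups %in% folds[[f]]
    train_ws <- subset_windows(wsub, !is_val)
    val_ws <- subset_windows(wsub, is_val)
    stats <- fit_norm(train_ws)
    fold_stats[[f]] <- stats
    train_n <- apply_norm(train_ws, stats)
    val_n <- apply_norm(val_ws, stats)
    tsp <- tspec; tsp$seed <- tspec$seed + f
    model <- build_model(steps, length(wsub$channel_names), mspec,
                         seed = seed + f,
                         channel_names = wsub$channel_names)
    model <- train_model(model, train_n, val_n, tsp)
    pred <- predict(model, val_n)
    conf <- confusion_matrix(val_n$labels, pred$gear)
    fold_reports[[f]] <- eval_report(conf, history = model$history)
  }
  per_class <- fold_reports[[1]]$per_class
  for (col in c("precision", "recall", "f1", "support")) {
    per_class[[col]] <- rowMeans(vapply(fold_reports,
                                        function(r) r$per_class[[col]],
                                        numeric(nrow(per_class))))
  }
  pooled <- Reduce(`+`, lapply(fold_reports, `[[`, "confusion"))
  mean_report <- list(
    per_class = per_class,
    waa = mean(vapply(fold_reports, `[[`, numeric(1), "waa")),
    weighted_precision = mean(vapply(fold_reports, `[[`, numeric(1),
                                     "weighted_precision")),
    weighted_f1 = mean(vapply(fold_reports, `[[`, numeric(1), "weighted_f1")),
    pooled_confusion = pooled)
  structure(list(config = config, folds = folds,
                 fold_reports = fold_reports, fold_stats = fold_stats,
                 mean_report = mean_report),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean WAA %.4f over %d participant-grouped folds\n",
              x$config$name, x$mean_report$waa, length(x$folds)))
  invisible(x)
}

#' First epoch exceeding a WAA threshold
#'
#' Scans a training history for the first epoch whose validation WAA is
#' strictly above `threshold` and reports that epoch with its cumulative
#' elapsed seconds; `reached = FALSE` when the threshold is never exceeded.
#'
#' @param history data frame with columns `epoch`, `waa` and optionally
#'   `elapsed_s`.
#' @param threshold WAA threshold (default 0.90).
#' @return list `(reached, epoch, elapsed_s)`.
#' @export
#' @examples
#' h <- data.frame(epoch = c(1, 10, 13), waa = c(0.48, 0.72, 0.92))
#' time_to_threshold(h)$epoch  # 13
time_to_threshold <- function(history, threshold = 0.90) {
  stopifnot(is.data.frame(history), nrow(history) >= 1,
            all(c("epoch", "waa") %in% names(history)))
  hit <- which(history$waa > threshold)
  if (length(hit) == 0) {
    return(list(reached = FALSE, epoch = NA_integer_, elapsed_s = NA_real_))
  }
  i <- hit[1]
  list(reached = TRUE, epoch = history$epoch[i],
       elapsed_s = if ("elapsed_s" %in% names(history))
         history$elapsed_s[i] else NA_real_)
}

#' Run the sensor-subset ablation
#'
#' One [cross_validate()] per configuration, collected into the ablation
#' grid: rows = pressure subsets (0P, 2P.1m5m, 2P.1mH, 2P.5mH, 3P.1m5mH,
#' 4P), columns = inertial subsets (None, A, AG, AGM), cells = mean WAA
#' across folds (the forbidden 0P/None cell stays empty). Mean seconds per
#' training epoch are recorded as diagnostics. A failing configuration
#' aborts with an error carrying the partial grid (`partial_grid`
#' condition field).
#'
#' @param ws preprocessed, unnormalized `window_set` (>= 2 participants).
#' @param configs list of `sensor_config`s (default all 23).
#' @param tspec,mspec,k,seed passed to [cross_validate()].
#' @return an `ablation_grid`: `waa` and `sec_per_epoch` matrices plus the
#'   per-config `cv_result`s.
#' @export
run_ablation <- function(ws, configs = enumerate_configs(),
                         tspec = train_spec(), mspec = model_spec(),
                         k = 2, seed = 1L) {
  rows <- names(.pressure_subsets())
  cols <- c("None", "A", "AG", "AGM")
  waa <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  spe <- waa
  results <- list()
  for (cfg in configs) {
    res <- tryCatch(
      cross_validate(ws, cfg, tspec = tspec, mspec = mspec, k = k,
                     seed = seed),
      error = function(e) e)
    r <- .pressure_label(cfg$pressure)
    cl <- if (length(cfg$inertial) == 0) "None" else
      paste(cfg$inertial, collapse = "")
    if (inherits(res, "error")) {
      grid <- structure(list(waa = waa, sec_per_epoch = spe,
                             results = results),
                        class = "ablation_grid")
      stop(errorCondition(
        paste0("configuration ", cfg$name, " failed: ",
               conditionMessage(res), " (partial grid attached)"),
        partial_grid = grid, class = "skigears_ablation_error"))
    }
    waa[r, cl] <- res$mean_report$waa
    epochs <- lapply(res$fold_reports, function(fr) fr$history)
    spe[r, cl] <- mean(vapply(epochs, function(h) {
      if (is.null(h) || nrow(h) == 0) NA_real_ else
        h$elapsed_s[nrow(h)] / nrow(h)
    }, numeric(1)), na.rm = TRUE)
    results[[cfg$name]] <- res
  }
  structure(list(waa = waa, sec_per_epoch = spe, results = results),
            class = "ablation_grid")
}

#' @export
print.ablation_grid <- function(x, ...) {
  cat("<ablation_grid> mean WAA across folds\n")
  print(round(x$waa, 2))
  invisible(x)
}

#' Write an ablation grid as CSV
#'
#' Layout mirrors the summary table of the study: one row per pressure
#' subset, columns None/A/AG/AGM, WAA cells (two extra columns blocks for
#' seconds per epoch).
#'
#' @param grid an `ablation_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ablation_csv <- function(grid, path) {
  stopifnot(inherits(grid, "ablation_grid"))
  df <- data.frame(pressure = rownames(grid$waa),
                   round(grid$waa, 4),
                   stats::setNames(round(grid$sec_per_epoch, 2),
                                   paste0("t_epoch_", colnames(grid$waa))),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
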