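test_that("confusion matrix counts agree with a brute-force oracle", {
  y <- c("G2R", "G3", "G3", "G2L")
  p <- c("G2R", "G2L", "G3", "G2L")
  cm <- confusion_matrix(y, p)
  expect_equal(dim(cm), c(3, 3))
  expect_equal(sum(cm), 4)
  expect_equal(cm["G3", "G2L"], 1)
  expect_equal(cm["G2R", "G2R"], 1)
  # perfect prediction -> diagonal of class supports
  yy <- rep(gear_levels(), times = c(5, 2, 7))
  cmp <- confusion_matrix(yy, yy)
  expect_equal(diag(cmp), c(G2R = 5, G3 = 2, G2L = 7))
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
  # random labelings: every cell equals the direct pair count
  set.seed(41)
  for (i in 1:10) {
    yt <- sample(gear_levels(), 200, replace = TRUE)
    yp <- sample(gear_levels(), 200, replace = TRUE)
    cm <- confusion_matrix(yt, yp)
    for (a in gear_levels()) for (b in gear_levels()) {
      expect_equal(cm[a, b], sum(yt == a & yp == b))
    }
  }
  expect_error(confusion_matrix(c("G2R", "XX"), c("G2R", "G3")),
               "unknown gear")
  expect_error(confusion_matrix("G3", c("G3", "G3")), "equal length")
})

test_that("class_report matches hand-derived values and handles zeros", {
  # diagonal matrix: all metrics 1
  cm <- diag(c(4, 5, 6)); dimnames(cm) <- list(gear_levels(), gear_levels())
  rep1 <- class_report(cm)
  expect_true(all(rep1$precision == 1 & rep1$recall == 1 & rep1$f1 == 1))
  expect_equal(rep1$support, c(4, 5, 6))
  # 2-class toy [[1,1],[0,0]]: precision_1 = 1, recall_1 = 0.5
  toy <- matrix(c(1, 0, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  rep2 <- suppressWarnings(class_report(toy))
  expect_equal(rep2$precision[1], 1.0)
  expect_equal(rep2$recall[1], 0.5)
  # class never predicted and never correct -> F1 = 0 with warning
  expect_warning(r <- class_report(toy), "zero denominator")
  expect_equal(r$f1[2], 0)
})

test_that("class_report agrees with a brute-force counting oracle", {
  set.seed(77)
  for (i in 1:40) {
    yt <- sample(gear_levels(), 120, replace = TRUE)
    yp <- sample(gear_levels(), 120, replace = TRUE)
    rep <- suppressWarnings(class_report(confusion_matrix(yt, yp)))
    for (ci in seq_along(gear_levels())) {
      g <- gear_levels()[ci]
      tp <- sum(yt == g & yp == g)
      prec <- if (sum(yp == g) > 0) tp / sum(yp == g) else 0
      rec <- if (sum(yt == g) > 0) tp / sum(yt == g) else 0
      expect_equal(rep$precision[ci], prec)
      expect_equal(rep$recall[ci], rec)
      expect_equal(rep$support[ci], sum(yt == g))
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      expect_equal(rep$f1[ci], f1)
    }
  }
})

test_that("weighted average reproduces the published table arithmetic", {
  supports <- c(2933, 2106, 2799)
  waa <- weighted_average(c(0.98, 0.99, 0.99), supports)
  expect_equal(round(waa, 2), 0.99)
  wprec <- weighted_average(c(0.96, 0.99, 0.97), supports)
  expect_equal(round(wprec, 2), 0.97)
  # equal values are invariant to supports
  expect_equal(weighted_average(c(0.8, 0.8, 0.8), c(1, 10, 100)), 0.8)
  expect_error(weighted_average(c(1, 1), c(0, 0)), "positive")
  expect_error(weighted_average(c(1, 1), c(1, 2, 3)), "length")
})

test_that("WAA equals trace/total on random confusion matrices", {
  set.seed(13)
  for (i in 1:50) {
    cm <- matrix(rpois(9, 20), 3, 3,
                 dimnames = list(gear_levels(), gear_levels()))
    rep <- suppressWarnings(class_report(cm))
    waa <- weighted_average(rep$recall, rep$support)
    expect_equal(waa, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("participant folds are deterministic, disjoint and balanced", {
  ids <- rep(c("A", "B", "C", "D"), each = 10)
  f1 <- participant_folds(ids, k = 2, seed = 3)
  f2 <- participant_folds(ids, k = 2, seed = 3)
  expect_identical(f1, f2)
  expect_length(f1, 2)
  expect_length(f1[[1]], 2); expect_length(f1[[2]], 2)
  expect_length(intersect(f1[[1]], f1[[2]]), 0)
  expect_setequal(unlist(f1), c("A", "B", "C", "D"))
  expect_error(participant_folds("A", k = 2), "at least 2")
  # 5 participants -> 3 + 2 split
  f3 <- participant_folds(LETTERS[1:5], k = 2, seed = 1)
  expect_equal(sort(unname(lengths(f3))), c(2, 3))
})

test_that("time_to_threshold extracts the first crossing", {
  h <- data.frame(epoch = c(1, 10, 13), elapsed_s = c(2, 20, 26),
                  waa = c(0.48, 0.72, 0.92))
  hit <- time_to_threshold(h, 0.90)
  expect_true(hit$reached)
  expect_equal(hit$epoch, 13)
  expect_equal(hit$elapsed_s, 26)
  expect_equal(time_to_threshold(h, 0)$epoch, 1)
  miss <- time_to_threshold(h, 0.95)
  expect_false(miss$reached)
  expect_true(is.na(miss$epoch))
  # strictly greater than the threshold
  expect_equal(time_to_threshold(h, 0.92)$epoch, NA_integer_)
})

test_that("eval_report averaging of identical folds is the identity", {
  cm <- matrix(c(50, 2, 1, 3, 40, 2, 1, 1, 45), 3, 3, byrow = TRUE,
               dimnames = list(gear_levels(), gear_levels()))
  r <- eval_report(cm)
  # support equals confusion row sums (type invariant)
  expect_equal(r$per_class$support, unname(rowSums(cm)))
  expect_true(r$waa >= 0 && r$waa <= 1)
  # averaging two identical per-fold reports returns the same metrics
  mean_waa <- mean(c(r$waa, r$waa))
  expect_equal(mean_waa, r$waa)
  dir <- withr::local_tempdir()
  write_eval_report(r, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$waa, r$waa, tolerance = 1e-12)
  conf_csv <- utils::read.csv(file.path(dir, "confusion.csv"), row.names = 1)
  expect_equal(unname(as.matrix(conf_csv)), unname(cm))
})

test_that("a small ablation subset populates exactly its cells", {
  ws <- toy_window_set(run_ms = 12000, stride_ms = 1000,
                       participants = c("A", "B"))
  configs <- lapply(c("2P.1m5m", "0P + A"), parse_config)
  tsp <- train_spec(epochs = 2, batch_size = 16, seed = 1)
  grid <- suppressWarnings(   # toy models may miss a class entirely
    run_ablation(ws, configs, tspec = tsp, mspec = toy_model_spec(),
                 k = 2, seed = 4))
  expect_equal(sum(!is.na(grid$waa)), 2)
  expect_false(is.na(grid$waa["2P.1m5m", "None"]))
  expect_false(is.na(grid$waa["0P", "A"]))
  expect_true(is.na(grid$waa["0P", "None"]))     # forbidden cell stays empty
  expect_true(all(grid$waa[!is.na(grid$waa)] >= 0 &
                  grid$waa[!is.na(grid$waa)] <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ablation_csv(grid, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_equal(df$pressure, rownames(grid$waa))
  expect_equal(sum(!is.na(df$A)), 1)
})

test_that("cross_validate keeps folds participant-exclusive", {
  ws <- toy_window_set(run_ms = 12000, stride_ms = 1000,
                       participants = c("A", "B"))
  cv <- suppressWarnings(     # 2-epoch toy fit: degenerate predictions ok
    cross_validate(ws, "2P.1m5m + A",
                   tspec = train_spec(epochs = 2, batch_size = 16, seed = 2),
                   mspec = toy_model_spec(), k = 2, seed = 9))
  expect_length(intersect(cv$folds[[1]], cv$folds[[2]]), 0)
  expect_setequal(unlist(cv$folds), c("A", "B"))
  # per-fold normalization stats derive from the training side only
  for (f in 1:2) {
    train_side <- subset_windows(
      select_channels(ws, channels_for(cv$config)),
      !(ws$groups %in% cv$folds[[f]]))
    expect_equal(cv$fold_stats[[f]], fit_norm(train_side))
  }
  # mean report averages fold WAAs
  expect_equal(cv$mean_report$waa,
               mean(vapply(cv$fold_reports, `[[`, numeric(1), "waa")))
})

test_that("adding sensors does not lose more than 2 points of mean WAA", {
  # echoes the published ablation ordering: the full array is at least as
  # informative as the two-metatarsal subset (within a 0.02 margin)
  full <- acceptance_cv("4P + AGM")$mean_report$waa
  # the weaker 2-sensor model may leave a class unpredicted in a fold;
  # the resulting zero-denominator precision warning is expected
  twop <- suppressWarnings(acceptance_cv("2P.1m5m"))$mean_report$waa
  expect_gte(full, twop - 0.02)
})
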