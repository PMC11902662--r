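test_that("sensor geometry and force-to-pressure conversion", {
  geom <- sensor_geometry()
  # pi * (0.953 cm / 2)^2, derived by hand
  expect_equal(geom$area_cm2, 0.7133057, tolerance = 1e-6)
  expect_equal(force_to_pressure(0), 0)
  expect_equal(force_to_pressure(1), 1.4019235, tolerance = 1e-6)
  expect_equal(round(force_to_pressure(1), 4), 1.4019)
  expect_error(force_to_pressure(-0.1), ">= 0")
  # linearity in force
  expect_equal(force_to_pressure(3.5), 3.5 * force_to_pressure(1))
})

test_that("offset removal zeroes a constant channel and keeps IMU intact", {
  n <- 200
  m <- cbind(rep(0.7, n), rnorm(n))
  rec <- recording(m, c("R_H", "R_Ax"))
  out <- remove_offset(rec)
  expect_true(all(out$samples[, "R_H"] == 0))
  expect_identical(out$samples[, "R_Ax"], rec$samples[, "R_Ax"])
  # already-zero-baseline channel unchanged (quantile of half-cosine bump
  # signal that rests at 0 most of the time)
  x <- pmax(sin(seq(0, 20 * pi, length.out = n)), 0)
  rec2 <- recording(cbind(x), "L_1m")
  out2 <- remove_offset(rec2)
  expect_equal(out2$samples[, 1], x, tolerance = 1e-12)
  expect_error(remove_offset(recording(cbind(rnorm(5)), "R_Ax")),
               "no pressure channels")
  expect_error(remove_offset(recording(cbind(rep(NA_real_, 5)), "R_H")),
               "entirely missing")
})

test_that("offset estimator recovers the simulator baseline", {
  p <- sim_params("G2R", offset = c(BT = 0.2, `1m` = 0.2, `5m` = 0.2, H = 0.2),
                  seed = 6)
  rec <- simulate_recording(p, 30000)$recording
  out <- remove_offset(rec)
  base <- attr(out, "baseline")
  for (ch in pressure_channels()) {
    expect_lt(abs(base[[ch]] - 0.2), 2 * p$noise_sd[["pressure"]], label = ch)
  }
})

test_that("EMA matches the hand recurrence", {
  expect_equal(ema_smooth(c(0, 1, 1), 0.5), c(0, 0.5, 0.75))
  x <- rnorm(40)
  expect_identical(ema_smooth(x, 1), x)                  # alpha = 1 identity
  expect_equal(ema_smooth(rep(2.5, 10), 0.3), rep(2.5, 10))  # constant fixed
  # brute-force recurrence oracle on random inputs and alphas
  brute <- function(x, a) {
    y <- numeric(length(x)); y[1] <- x[1]
    for (t in seq_along(x)[-1]) y[t] <- a * x[t] + (1 - a) * y[t - 1]
    y
  }
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(2:80, 1))
    a <- runif(1, 0.01, 1)
    expect_equal(ema_smooth(x, a), brute(x, a), tolerance = 1e-12)
  }
  expect_error(ema_smooth(1:5, 0), "alpha")
  expect_error(ema_smooth(1:5, 1.2), "alpha")
  expect_error(ema_smooth(numeric(0), 0.5), "non-empty")
})

test_that("cleaning interpolates short gaps and splits on long ones", {
  n <- 1000
  m <- matrix(seq_len(n) / 100, n, 2)
  rec <- recording(m, c("R_H", "L_H"))
  # identity on complete data
  segs <- clean_recording(rec)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$samples, rec$samples, ignore_attr = TRUE)
  # single interior missing sample -> linear midpoint
  rec$samples[500, 1] <- NA
  segs <- clean_recording(rec)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$samples[500, 1],
               (rec$samples[499, 1] + rec$samples[501, 1]) / 2)
  # 300 ms gap (30 samples) with max_gap 200 ms -> split into 2 segments
  rec2 <- recording(m, c("R_H", "L_H"))
  rec2$samples[401:430, 2] <- NA
  segs2 <- clean_recording(rec2, max_gap_ms = 200)
  expect_length(segs2, 2)
  expect_equal(n_samples(segs2[[1]]), 400)
  expect_equal(n_samples(segs2[[2]]), n - 430)
  # split keeps the absolute time axis
  expect_equal(segs2[[2]]$start_ms, 430 * 10)
  expect_false(anyNA(segs2[[1]]$samples) || anyNA(segs2[[2]]$samples))
  # leading/trailing missing trimmed
  rec3 <- recording(m, c("R_H", "L_H"))
  rec3$samples[1:5, 1] <- NA
  rec3$samples[(n - 3):n, 2] <- NA
  segs3 <- clean_recording(rec3)
  expect_length(segs3, 1)
  expect_equal(n_samples(segs3[[1]]), n - 9)
  expect_equal(segs3[[1]]$start_ms, 50)
  # > 50% missing in a channel rejects the run
  rec4 <- recording(m, c("R_H", "L_H"))
  rec4$samples[1:601, 1] <- NA
  expect_error(clean_recording(rec4), "50%")
})

test_that("window counts follow the closed form before label filtering", {
  # brute-force enumeration oracle over random (T, W, S) in samples
  set.seed(52)
  for (i in 1:25) {
    spw <- sample(4:40, 1) * 5          # window samples (mult of subframe 5)
    sps <- sample(1:30, 1) * 5          # stride samples
    n <- sample(spw:(spw + 500), 1)
    n <- (n %/% 5) * 5
    brute <- length(seq(1, n - spw + 1, by = sps))
    rec <- recording(matrix(rnorm(n * 2), n), c("R_H", "L_Az"))
    track <- label_track(data.frame(start_ms = 0, end_ms = n * 10 + 1e6,
                                    gear = "G3"))
    ws <- segment_windows(rec, track, window_ms = spw * 10,
                          stride_ms = sps * 10, subframe_ms = 50)
    expect_equal(n_windows(ws), brute,
                 label = sprintf("n=%d W=%d S=%d", n, spw, sps))
  }
})

test_that("segmentation keeps only windows inside one label interval", {
  n <- 1500   # 15 s @ 100 Hz
  rec <- recording(matrix(rnorm(n * 2), n), c("R_H", "L_Az"))
  # G3 on [0, 7000), G2R on [8000, 15000): 1 s unlabeled gap between
  track <- label_track(data.frame(start_ms = c(0, 8000),
                                  end_ms = c(7000, 15000),
                                  gear = c("G3", "G2R")))
  ws <- segment_windows(rec, track, window_ms = 5000, stride_ms = 500)
  starts <- seq(0, 10000, by = 500)
  keep_g3 <- sum(starts + 5000 <= 7000)
  keep_g2r <- sum(starts >= 8000 & starts + 5000 <= 15000)
  expect_equal(n_windows(ws), keep_g3 + keep_g2r)
  expect_equal(sum(ws$labels == "G3"), keep_g3)
  expect_equal(sum(ws$labels == "G2R"), keep_g2r)
  # single fully-labeled 5000 ms recording -> exactly 1 window
  rec1 <- recording(matrix(rnorm(500 * 2), 500), c("R_H", "L_Az"))
  tr1 <- label_track(data.frame(start_ms = 0, end_ms = 5000, gear = "G2L"))
  expect_equal(n_windows(segment_windows(rec1, tr1)), 1)
  # 6000 ms fully labeled, stride 50 -> floor((6000-5000)/50)+1 = 21
  rec2 <- recording(matrix(rnorm(600 * 2), 600), c("R_H", "L_Az"))
  tr2 <- label_track(data.frame(start_ms = 0, end_ms = 6000, gear = "G3"))
  expect_equal(n_windows(segment_windows(rec2, tr2)), 21)
  # window longer than recording -> empty set, not an error
  expect_equal(n_windows(segment_windows(rec1, tr1, window_ms = 10000)), 0)
})

test_that("per-subframe medians are permutation invariant within subframes", {
  n <- 500
  m <- matrix(rnorm(n * 2), n, 2)
  rec <- recording(m, c("R_H", "L_Az"))
  tr <- label_track(data.frame(start_ms = 0, end_ms = 5000, gear = "G3"))
  ws1 <- segment_windows(rec, tr)
  set.seed(99)
  perm <- m
  for (b in seq_len(n / 5)) {
    idx <- ((b - 1) * 5 + 1):(b * 5)
    perm[idx, ] <- m[sample(idx), ]
  }
  ws2 <- segment_windows(recording(perm, c("R_H", "L_Az")), tr)
  expect_equal(ws1$tensor, ws2$tensor)
  # medians agree with stats::median per subframe / channel
  expect_equal(ws1$tensor[1, 7, 2], median(m[31:35, 2]))
  expect_equal(ws1$tensor[1, 100, 1], median(m[496:500, 1]))
})

test_that("window labels never disagree with their covering interval", {
  sim <- simulate_recording(sim_params("G2R", seed = 31), 20000)
  track <- label_track(data.frame(start_ms = c(0, 11000),
                                  end_ms = c(10000, 20000),
                                  gear = c("G2R", "G3")))
  ws <- segment_windows(sim$recording, track, stride_ms = 250)
  starts <- (which(!is.na(match(seq_len(n_windows(ws)), seq_len(n_windows(ws))))) - 1)
  # reconstruct start times from stride and check containment
  all_starts <- seq(0, 20000 - 5000, by = 250)
  kept <- all_starts[all_starts + 5000 <= 10000 |
                     (all_starts >= 11000 & all_starts + 5000 <= 20000)]
  expect_equal(n_windows(ws), length(kept))
  expected <- ifelse(kept + 5000 <= 10000, "G2R", "G3")
  expect_equal(as.character(ws$labels), expected)
})

test_that("normalization stats come from training data only", {
  ws <- toy_window_set()
  stats <- fit_norm(ws)
  normed <- apply_norm(ws, stats)
  for (j in seq_along(ws$channel_names)) {
    expect_lt(abs(mean(normed$tensor[, , j])), 1e-6)
    expect_lt(abs(sd(as.vector(normed$tensor[, , j])) - 1), 1e-6)
  }
  # validation transformed with training stats keeps its shift
  val <- ws
  val$tensor <- val$tensor + 1
  vn <- apply_norm(val, stats)
  expect_gt(abs(mean(vn$tensor[, , 1])), 0.5)
  # stats computed on different participants differ
  sA <- fit_norm(subset_windows(ws, ws$groups == "A"))
  sB <- fit_norm(subset_windows(ws, ws$groups == "B"))
  expect_false(isTRUE(all.equal(sA$mean, sB$mean)))
})

test_that("zero-variance channels normalize to zero with a warning", {
  tensor <- array(rnorm(8 * 10 * 2), c(8, 10, 2))
  tensor[, , 2] <- 3.3
  ws <- window_set(tensor, rep("G3", 8), rep("A", 8), 500, 50, 50,
                   c("R_H", "L_H"))
  expect_warning(stats <- fit_norm(ws), "zero-variance")
  expect_equal(stats$sd[["L_H"]], 1)
  out <- suppressWarnings(apply_norm(ws, stats))
  expect_true(all(out$tensor[, , 2] == 0))
})

test_that("the preprocessing pipeline is deterministic", {
  sim <- simulate_recording(sim_params("G3", seed = 17, missing_rate = 0.001),
                            15000)
  a <- preprocess_run(sim$recording, sim$labels, stride_ms = 500)
  b <- preprocess_run(sim$recording, sim$labels, stride_ms = 500)
  expect_identical(a$tensor, b$tensor)
  expect_identical(a$labels, b$labels)
})
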