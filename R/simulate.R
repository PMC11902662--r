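# Synthetic insole-signal generator.
#
# The waveform family is deliberately simple but reproduces the qualitative
# per-gear morphology used for classification: per-foot gait cycles with a
# contact and a non-contact phase, within-contact pressure order
# heel -> first metatarsal / big toe -> fifth metatarsal (raised-cosine
# bumps with per-sensor onset lags), a dominant-side pressure surplus for
# the asymmetric G2 gears, phase-locked IMU sinusoids with a gyroscope
# burst during propulsion, a slowly varying magnetometer, additive Gaussian
# noise per modality and a per-sensor pressure baseline (offset).

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation parameters for one synthetic run
#'
#' Defaults describe a plausible uphill skating effort on a 10% slope:
#' a 1400 ms gait cycle, 55% of the cycle in ski-snow contact per foot,
#' 2 kg/cm^2 peak plantar pressure, a 1.3x total-pressure surplus on the
#' dominant side for the asymmetric gears, within-contact onset lags
#' ordered heel < first metatarsal (with the big toe alongside) < fifth
#' metatarsal, modest per-modality sensor noise and a 0.2 kg/cm^2
#' piezoresistive baseline offset.
#'
#' @param gear one of `"G2R"`, `"G2L"`, `"G3"`.
#' @param cycle_ms gait-cycle length in ms (default 1400).
#' @param duty fraction of the cycle each foot is in contact (0 < duty < 1).
#' @param peak_pressure_kg_cm2 peak bump pressure, kg/cm^2.
#' @param asymmetry >= 1; multiplier on the dominant-side total pressure for
#'   G2-type gears (left for G2R, right for G2L); ignored for G3.
#' @param onset_lags_ms named numeric lag (ms) of each pressure sensor's
#'   activation within the contact phase; must satisfy `H <= 1m <= 5m` and
#'   every lag < `duty * cycle_ms`.
#' @param noise_sd named additive Gaussian sd per modality
#'   (`pressure` kg/cm^2, `acc` g, `gyro` dps, `mag` gauss); all >= 0.
#' @param offset named per-pressure-sensor baseline (kg/cm^2, >= 0).
#' @param missing_rate fraction of sample cells dropped to `NA`.
#' @param seed integer RNG seed; identical params + seed give identical
#'   sample matrices.
#' @return a `sim_params` list.
#' @export
sim_params <- function(gear = "G2R",
                       cycle_ms = 1400,
                       duty = 0.55,
                       peak_pressure_kg_cm2 = 2.0,
                       asymmetry = 1.3,
                       onset_lags_ms = c(H = 0, `1m` = 120, BT = 140, `5m` = 280),
                       noise_sd = c(pressure = 0.05, acc = 0.05, gyro = 5, mag = 0.01),
                       offset = c(BT = 0.2, `1m` = 0.2, `5m` = 0.2, H = 0.2),
                       missing_rate = 0,
                       seed = 1L) {
  gear <- match.arg(gear, gear_levels())
  stopifnot(cycle_ms > 0, duty > 0, duty < 1, peak_pressure_kg_cm2 > 0)
  if (asymmetry < 1) stop("asymmetry must be >= 1", call. = FALSE)
  if (length(offset) == 1) offset <- stats::setNames(rep(offset, 4), pressure_sites())
  stopifnot(all(pressure_sites() %in% names(onset_lags_ms)),
            all(pressure_sites() %in% names(offset)),
            all(c("pressure", "acc", "gyro", "mag") %in% names(noise_sd)))
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(offset < 0)) stop("offset must be >= 0", call. = FALSE)
  l <- onset_lags_ms
  if (!(l["H"] <= l["1m"] && l["1m"] <= l["5m"])) {
    stop("onset lags must satisfy H <= 1m <= 5m", call. = FALSE)
  }
  if (any(l >= duty * cycle_ms)) {
    stop("onset lags must be shorter than the contact phase", call. = FALSE)
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(list(gear = gear, cycle_ms = cycle_ms, duty = duty,
                 peak_pressure_kg_cm2 = peak_pressure_kg_cm2,
                 asymmetry = asymmetry, onset_lags_ms = l,
                 noise_sd = noise_sd, offset = offset,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_params")
}

# relative bump amplitude per pressure site (heel and first metatarsal
# carry most load; big toe least)
.site_weights <- c(BT = 0.7, `1m` = 1.0, `5m` = 0.8, H = 1.0)

# channels whose sign flips under a left/right mirror (lateral axes:
# lateral acceleration, roll and yaw rate, lateral magnetic component)
.lateral_suffixes <- c("Ay", "Gx", "Gz", "My")

# raised-cosine pressure bump for one sensor over the cycle phase
# u_ms: time within cycle; active on [lag, contact_ms)
.bump <- function(u_ms, lag, contact_ms) {
  act <- u_ms >= lag & u_ms < contact_ms
  out <- numeric(length(u_ms))
  out[act] <- 0.5 * (1 - cos(2 * pi * (u_ms[act] - lag) / (contact_ms - lag)))
  out
}

#' Simulate one labeled insole recording
#'
#' Generates all 26 canonical channels for `duration_ms` at 100 Hz plus a
#' label track covering the whole run with the single gear. The two feet
#' run in counter-phase (half a cycle apart). G2L is generated exactly as
#' the left/right mirror of the G2R generator at the same seed
#' (`simulate_recording(G2L, seed) == mirror_recording(simulate_recording(G2R, seed))`).
#'
#' @param params a [sim_params()] object.
#' @param duration_ms run length in ms; must be at least one cycle.
#' @param participant_id,run_id metadata for the emitted [recording()].
#' @param amp_mult,cycle_mult per-participant multiplicative perturbations
#'   of signal amplitude and cycle length (used by [make_dataset()]).
#' @param rate_hz sampling rate (default 100).
#' @return `list(recording =, labels =)`.
#' @export
#' @examples
#' sim <- simulate_recording(sim_params("G3", seed = 7), 3000)
#' sim$recording
simulate_recording <- function(params, duration_ms, participant_id = "A",
                               run_id = "run1", amp_mult = 1, cycle_mult = 1,
                               rate_hz = 100) {
  stopifnot(inherits(params, "sim_params"))
  cycle <- params$cycle_ms * cycle_mult
  if (duration_ms < cycle) {
    stop("duration_ms must cover at least one gait cycle", call. = FALSE)
  }
  if (params$gear == "G2L") {
    p <- params
    p$gear <- "G2R"
    sim <- simulate_recording(p, duration_ms, participant_id, run_id,
                              amp_mult, cycle_mult, rate_hz)
    rec <- mirror_recording(sim$recording)
    labs <- sim$labels
    labs$gear <- factor("G2L", levels = gear_levels())
    return(list(recording = rec, labels = label_track(labs)))
  }

  n <- floor(duration_ms * rate_hz / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / rate_hz
  contact_ms <- params$duty * cycle
  sd <- params$noise_sd
  # dominant-side multiplier: for G2R the left ski bears more load
  side_mult <- switch(params$gear,
                      G2R = c(R = 1, L = params$asymmetry),
                      G3  = c(R = 1, L = 1))
  mag_phase <- switch(params$gear, G2R = 0, G3 = pi / 2)

  samples <- matrix(NA_real_, n, 26, dimnames = list(NULL, ski_channels()))
  with_seed(params$seed, {
    for (foot in c("R", "L")) {
      # feet alternate: left starts its cycle at t = 0, right half a cycle in
      shift <- if (foot == "L") 0 else cycle / 2
      u <- (t_ms + shift) %% cycle
      ph <- u / cycle
      fsign <- if (foot == "L") 1 else -1
      amp <- params$peak_pressure_kg_cm2 * side_mult[[foot]] * amp_mult
      for (site in pressure_sites()) {
        x <- amp * .site_weights[[site]] *
          .bump(u, params$onset_lags_ms[[site]], contact_ms)
        x <- x + params$offset[[site]] + stats::rnorm(n, 0, sd[["pressure"]])
        samples[, paste0(foot, "_", site)] <- pmax(x, 0)
      }
      a <- sqrt(side_mult[[foot]]) * amp_mult
      imu <- list(
        Ax = a * 0.5 * sin(2 * pi * ph + 0.5),
        Ay = fsign * a * 0.3 * sin(2 * pi * ph + 1.0),
        Az = 1 + a * 0.4 * sin(2 * pi * ph),
        Gx = fsign * a * 40 * sin(2 * pi * ph + 0.3),
        Gy = a * 60 * sin(2 * pi * ph + 0.8),
        # external-rotation burst during the propulsion (late-contact) phase
        Gz = fsign * a * 120 *
          .bump(u, 0.7 * contact_ms, contact_ms),
        Mx = 0.30 + 0.05 * sin(2 * pi * t_ms / (6 * cycle) + mag_phase),
        My = fsign * (0.10 + 0.05 * cos(2 * pi * t_ms / (6 * cycle) + mag_phase)),
        Mz = -0.20 + 0.05 * sin(2 * pi * t_ms / (6 * cycle) + mag_phase + 1))
      mod_sd <- c(A = sd[["acc"]], G = sd[["gyro"]], M = sd[["mag"]])
      for (ch in names(imu)) {
        samples[, paste0(foot, "_", ch)] <-
          imu[[ch]] + stats::rnorm(n, 0, mod_sd[[substr(ch, 1, 1)]])
      }
    }
    if (params$missing_rate > 0) {
      drop <- which(stats::runif(length(samples)) < params$missing_rate)
      samples[drop] <- NA_real_
    }
  })

  rec <- recording(samples, ski_channels(), participant_id = participant_id,
                   run_id = run_id, rate_hz = rate_hz)
  labs <- label_track(data.frame(start_ms = 0, end_ms = duration_ms,
                                 gear = params$gear))
  list(recording = rec, labels = labs)
}

#' Mirror a recording left/right
#'
#' Swaps each `R_`/`L_` channel pair and flips the sign of the lateral-axis
#' channels (`Ay`, `Gx`, `Gz`, `My`), the simulator's laterality
#' convention. An involution: `mirror_recording(mirror_recording(rec))`
#' equals `rec`.
#'
#' @param rec a `recording` (any subset of canonical channels).
#' @return the mirrored `recording`.
#' @export
mirror_recording <- function(rec) {
  rec <- validate_recording(rec)
  swapped <- ifelse(grepl("^R_", rec$channels),
                    sub("^R_", "L_", rec$channels),
                    sub("^L_", "R_", rec$channels))
  m <- rec$samples
  colnames(m) <- swapped
  flip <- sub("^[RL]_", "", swapped) %in% .lateral_suffixes
  m[, flip] <- -m[, flip]
  # normalize to canonical subset order
  ord <- ski_channels()[ski_channels() %in% swapped]
  m <- m[, ord, drop = FALSE]
  recording(m, colnames(m), participant_id = rec$participant_id,
            run_id = rec$run_id, rate_hz = rec$rate_hz,
            start_ms = rec$start_ms)
}

#' Write a multi-participant synthetic dataset to disk
#'
#' Generates `n_participants x length(gears) x runs_per_gear` recording +
#' label file pairs plus a JSON manifest. Distinct participants get
#' perturbed parameter draws (signal amplitude +/-15%, cycle length
#' +/-10%) from the master seed, so participant-grouped folds are
#' non-trivial. Identical seeds give byte-identical output files.
#'
#' @param out_dir output directory (created if needed). An existing
#'   non-empty directory is refused unless `overwrite = TRUE`.
#' @param n_participants number of synthetic skiers (>= 1).
#' @param gears gear labels to simulate.
#' @param runs_per_gear ascents per participant and gear.
#' @param run_ms run length in ms.
#' @param seed master seed; all per-run seeds derive from it.
#' @param base_params a [sim_params()] giving the shared morphology
#'   (its `gear` and `seed` fields are overridden per run).
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest, invisibly; also written as `manifest.json`.
#' @export
make_dataset <- function(out_dir, n_participants = 4,
                         gears = gear_levels(), runs_per_gear = 3,
                         run_ms = 60000, seed = 1L,
                         base_params = sim_params(), overwrite = FALSE) {
  stopifnot(n_participants >= 1, runs_per_gear >= 1, length(gears) >= 1)
  gears <- vapply(gears, function(g) match.arg(g, gear_levels()), character(1))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("out_dir exists and is not empty; pass overwrite = TRUE", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  participants <- make.unique(rep(LETTERS, length.out = n_participants), sep = "")
  n_runs <- n_participants * length(gears) * runs_per_gear
  draws <- with_seed(seed, list(
    amp = stats::runif(n_participants, 0.85, 1.15),
    cyc = stats::runif(n_participants, 0.90, 1.10),
    run_seeds = sample.int(.Machine$integer.max - 1L, n_runs)))
  entries <- list()
  k <- 0L
  for (pi in seq_len(n_participants)) {
    for (g in gears) {
      for (r in seq_len(runs_per_gear)) {
        k <- k + 1L
        p <- base_params
        p$gear <- g
        p$seed <- draws$run_seeds[k]
        run_id <- sprintf("%s_run%d", g, r)
        sim <- simulate_recording(p, run_ms,
                                  participant_id = participants[pi],
                                  run_id = run_id,
                                  amp_mult = draws$amp[pi],
                                  cycle_mult = draws$cyc[pi])
        rec_file <- sprintf("%s_%s_run%d.csv", participants[pi], g, r)
        lab_file <- sprintf("%s_%s_run%d_labels.csv", participants[pi], g, r)
        write_recording(sim$recording, file.path(out_dir, rec_file))
        write_labels(sim$labels, file.path(out_dir, lab_file))
        entries[[k]] <- list(participant = participants[pi], gear = g,
                             run = r, recording = rec_file, labels = lab_file,
                             seed = draws$run_seeds[k])
      }
    }
  }
  manifest <- list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    gears = gears, runs_per_gear = as.integer(runs_per_gear),
    run_ms = run_ms,
    participants = data.frame(participant = participants,
                              amp_mult = draws$amp, cycle_mult = draws$cyc),
    files = do.call(rbind, lapply(entries, as.data.frame)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset written by [make_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list with `manifest` and `runs`, the latter a list of
#'   `list(recording =, labels =, participant =)` per file pair.
#' @export
load_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  runs <- lapply(seq_len(nrow(manifest$files)), function(i) {
    f <- manifest$files[i, ]
    list(recording = read_recording(file.path(dir, f$recording)),
         labels = read_labels(file.path(dir, f$labels)),
         participant = f$participant)
  })
  list(manifest = manifest, runs = runs)
}
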