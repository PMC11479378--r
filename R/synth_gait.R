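# Synthetic multichannel inertial gait generator with controllable
# stance-time symmetry (STSR = right stance time / left stance time).
#
# Signal model: per channel, a sum of 4 harmonics of the stride frequency
# with fixed location/side/channel-specific amplitudes, evaluated on a
# piecewise-linear warped gait phase so the stance/swing split realizes the
# scheduled STSR exactly. Waveform shape is additionally coupled to STSR by
# scaling side-specific harmonics in proportion to asymmetry_gain * (STSR-1),
# with opposite signs on the two sides; pelvis channels mix both sides.

GAIT_LOCATIONS <- c("pelvis", "UL", "UR", "LL", "LR")
CHANNEL_NAMES <- c("gyro_x", "gyro_y", "gyro_z", "accel_x", "accel_y", "accel_z")
N_HARMONICS <- 4L
STANCE_FRACTION <- 0.6  # mean stance fraction of the stride, able-bodied gait

#' Gait profile for the synthetic generator
#'
#' Describes one synthetic participant: cadence, number of gait cycles, a
#' per-cycle schedule of target stance-time symmetry ratios, waveform noise,
#' the STSR-to-shape coupling gain, and optional turn-cycle insertion.
#'
#' @param cadence_mean Mean cadence in steps/min (> 0). Two steps = one
#'   stride, so the mean stride duration is `120 / cadence_mean` seconds.
#' @param cadence_sd Stride-to-stride cadence standard deviation (steps/min);
#'   realized stride durations are jittered accordingly.
#' @param stsr_schedule Either a single target STSR applied to every cycle, or
#'   a data frame with columns `cycle` and `stsr` giving anchor points that
#'   are linearly interpolated over cycle index. All targets must lie in
#'   (0.5, 2).
#' @param n_cycles Number of steady-state gait cycles (>= 1), excluding any
#'   inserted turn cycles.
#' @param noise_sd Additive Gaussian noise, as a fraction of each channel's
#'   template amplitude (>= 0).
#' @param asymmetry_gain Dimensionless coupling of the STSR deviation from 1
#'   to waveform shape change; 0 restricts the STSR effect to timing alone.
#' @param turn_every Insert one flagged turn cycle after every `turn_every`
#'   steady cycles (0 = no turns).
#' @param seed Integer RNG seed; the profile is fully deterministic given it.
#' @param id Participant identifier.
#' @return Object of class `gait_profile`.
#' @export
gait_profile <- function(cadence_mean = 105, cadence_sd = 2.8,
                         stsr_schedule = 1.0, n_cycles = 100,
                         noise_sd = 0.05, asymmetry_gain = 1.0,
                         turn_every = 0L, seed = 1L, id = "P1") {
  stopifnot(is_scalar_num(cadence_mean), cadence_mean > 0,
            is_scalar_num(cadence_sd), cadence_sd >= 0,
            is_scalar_num(n_cycles), n_cycles >= 1,
            is_scalar_num(noise_sd), noise_sd >= 0,
            is_scalar_num(asymmetry_gain),
            is_scalar_num(turn_every), turn_every >= 0)
  if (is.numeric(stsr_schedule) && is.null(dim(stsr_schedule))) {
    stsr_schedule <- data.frame(cycle = seq_along(stsr_schedule) *
                                  (n_cycles / max(1, length(stsr_schedule))),
                                stsr = as.numeric(stsr_schedule))
    if (nrow(stsr_schedule) == 1L) stsr_schedule$cycle <- 1
  }
  if (!is.data.frame(stsr_schedule) ||
      !all(c("cycle", "stsr") %in% names(stsr_schedule))) {
    stopf("stsr_schedule must be a number, numeric vector, or data frame with columns cycle, stsr")
  }
  if (any(!is.finite(stsr_schedule$stsr))) stopf("non-finite STSR targets in schedule")
  if (any(stsr_schedule$stsr <= 0.5 | stsr_schedule$stsr >= 2.0)) {
    stopf("all target STSR values must lie in (0.5, 2.0)")
  }
  structure(list(cadence_mean = cadence_mean, cadence_sd = cadence_sd,
                 stsr_schedule = stsr_schedule,
                 n_cycles = as.integer(n_cycles), noise_sd = noise_sd,
                 asymmetry_gain = asymmetry_gain,
                 turn_every = as.integer(turn_every),
                 seed = as.integer(seed), id = as.character(id)),
            class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf("gait_profile '%s': %d cycles, cadence %.1f +/- %.1f steps/min, STSR %.3f..%.3f, noise %.3f, gain %.2f\n",
              x$id, x$n_cycles, x$cadence_mean, x$cadence_sd,
              min(x$stsr_schedule$stsr), max(x$stsr_schedule$stsr),
              x$noise_sd, x$asymmetry_gain))
  invisible(x)
}

# Fixed harmonic amplitude/phase tables per location. Units: gyro deg/s,
# accel g; magnitudes typical of lower-body IMUs at comfortable walking
# speed and far below the +/-2000 deg/s and +/-16 g sensor ranges. The
# `coupling` table directs how asymmetry reshapes each harmonic.
location_template <- function(location) {
  base <- switch(location,
    pelvis = list(scale_gyro = 40, scale_acc = 0.25),
    UL = list(scale_gyro = 180, scale_acc = 0.45),
    UR = list(scale_gyro = 180, scale_acc = 0.45),
    LL = list(scale_gyro = 320, scale_acc = 0.8),
    LR = list(scale_gyro = 320, scale_acc = 0.8),
    stopf("unknown sensor location '%s' (expected one of %s)", location,
          paste(GAIT_LOCATIONS, collapse = ", ")))
  # Harmonic falloff ~1/h with channel-specific weighting; deterministic
  # pseudo-random phases fixed per channel/harmonic so templates are stable.
  h <- seq_len(N_HARMONICS)
  amp <- matrix(0, 6, N_HARMONICS, dimnames = list(CHANNEL_NAMES, NULL))
  weights <- rbind(
    c(0.45, 0.25, 0.12, 0.06),   # gyro_x (frontal)
    c(1.00, 0.40, 0.20, 0.10),   # gyro_y (sagittal, dominant)
    c(0.30, 0.18, 0.10, 0.05),   # gyro_z (transverse)
    c(0.50, 0.35, 0.18, 0.08),   # accel_x (AP)
    c(0.30, 0.22, 0.10, 0.05),   # accel_y (ML)
    c(0.80, 0.45, 0.22, 0.10))   # accel_z (vertical)
  amp[1:3, ] <- base$scale_gyro * weights[1:3, ]
  amp[4:6, ] <- base$scale_acc * weights[4:6, ]
  loc_idx <- match(location, GAIT_LOCATIONS)
  phase <- outer(seq_len(6), h, function(c, k) {
    2 * pi * (((c * 7 + k * 13 + loc_idx * 3) %% 17) / 17)
  })
  # Asymmetry reshapes mostly the first two harmonics; alternating signs
  # across channels/harmonics change shape, not just overall scale. The
  # magnitudes are calibrated so a 0.1 STSR deviation (a clearly visible
  # limp) changes dominant-harmonic amplitudes by ~15% and shifts harmonic
  # timing by ~0.1 rad, comparable to published between-level similarity
  # responses.
  coupling <- outer(seq_len(6), h, function(c, k) {
    ((-1)^(c + k)) * c(1.5, 1.0, 0.5, 0.25)[k]
  })
  phase_coupling <- outer(seq_len(6), h, function(c, k) {
    ((-1)^c) * c(1.2, 0.8, 0.5, 0.3)[k]
  })
  dc <- c(0, 0, 0, 0.05, 0.02, 1.0)  # gravity on accel_z
  side <- switch(location, pelvis = "both", UL = , LL = "left",
                 UR = , LR = "right")
  list(amp = amp, phase = phase, coupling = coupling,
       phase_coupling = phase_coupling, dc = dc, side = side)
}

# Piecewise-linear warped gait phase for one side: stance maps to
# [0, STANCE_FRACTION), swing to [STANCE_FRACTION, 1). `hs` are heel-strike
# times (length n+1, last = end boundary), `stance` per-cycle stance
# durations (length n). Samples outside [hs[1], hs[n+1]) are clamped.
warp_phase <- function(t, hs, stance) {
  n <- length(stance)
  idx <- findInterval(t, hs)
  idx <- pmin(pmax(idx, 1L), n)
  stride <- diff(hs)
  x <- t - hs[idx]
  x <- pmin(pmax(x, 0), stride[idx] - 1e-12)
  st <- stance[idx]
  in_stance <- x < st
  u <- numeric(length(t))
  u[in_stance] <- STANCE_FRACTION * x[in_stance] / st[in_stance]
  u[!in_stance] <- STANCE_FRACTION +
    (1 - STANCE_FRACTION) * (x[!in_stance] - st[!in_stance]) /
    (stride[idx][!in_stance] - st[!in_stance])
  list(u = u, cycle = idx)
}

# Harmonic template evaluated at warped phase u for one side.
# `shape_mult` is a 6 x n_harmonics multiplier matrix per cycle-wise STSR;
# here applied per sample via the cycle index.
side_signal <- function(u, cycle, tpl, stsr_by_cycle, asymmetry_gain,
                        side_sign, turn_by_cycle) {
  out <- matrix(0, 6, length(u))
  dev <- (stsr_by_cycle[cycle] - 1) * asymmetry_gain * side_sign
  turn_damp <- ifelse(turn_by_cycle[cycle], 0.3, 1)
  for (c in seq_len(6)) {
    acc <- numeric(length(u))
    for (h in seq_len(N_HARMONICS)) {
      mult <- 1 + dev * tpl$coupling[c, h]
      acc <- acc + tpl$amp[c, h] * mult *
        sin(2 * pi * h * u + tpl$phase[c, h] +
              dev * tpl$phase_coupling[c, h])
    }
    out[c, ] <- acc * turn_damp
  }
  out
}

#' Generate a synthetic multichannel inertial gait recording
#'
#' Produces 60 Hz tri-axial gyroscope + accelerometer signals for the
#' requested lower-body sensor locations, together with heel-strike/toe-off
#' event annotations per foot and turn flags per cycle. Right and left stance
#' durations of every cycle realize the scheduled STSR exactly (before
#' noise); waveform shape changes bilaterally and monotonically with the STSR
#' deviation from 1.
#'
#' @param profile A [gait_profile].
#' @param locations Character subset of `c("pelvis", "UL", "UR", "LL", "LR")`
#'   (upper/lower leg, left/right).
#' @param fs Sampling rate in Hz (default 60).
#' @return Object of class `synthetic_recording`: named list of 6 x T channel
#'   matrices in `$signals`, sampling rate `$fs`, event table `$events`
#'   (foot, event_type, time_s, is_turn), and per-cycle table `$cycles`
#'   (t_start, stride_s, stance_right_s, stance_left_s, stsr_target,
#'   is_turn).
#' @export
generate_recording <- function(profile, locations = GAIT_LOCATIONS, fs = 60) {
  stopifnot(inherits(profile, "gait_profile"), is_scalar_num(fs), fs > 0)
  locations <- unique(as.character(locations))
  if (length(locations) == 0L) stopf("at least one sensor location required")
  bad <- setdiff(locations, GAIT_LOCATIONS)
  if (length(bad)) stopf("unknown sensor location '%s'", bad[[1L]])
  with_seed(profile$seed, {
    n_steady <- profile$n_cycles
    sched <- profile$stsr_schedule
    target <- if (nrow(sched) == 1L) rep(sched$stsr, n_steady) else
      stats::approx(x = sched$cycle, y = sched$stsr,
                    xout = seq_len(n_steady), rule = 2)$y
    # interleave turn cycles
    is_turn <- logical(0); stsr <- numeric(0)
    k <- 0L
    for (i in seq_len(n_steady)) {
      is_turn <- c(is_turn, FALSE); stsr <- c(stsr, target[i]); k <- k + 1L
      if (profile$turn_every > 0L && k %% profile$turn_every == 0L &&
          i < n_steady) {
        is_turn <- c(is_turn, TRUE); stsr <- c(stsr, 1.0)
      }
    }
    n <- length(stsr)
    stride_mean <- 120 / profile$cadence_mean  # s per stride (2 steps)
    cad <- profile$cadence_mean + rnorm(n, 0, profile$cadence_sd)
    cad <- pmax(cad, 0.5 * profile$cadence_mean)
    stride <- 120 / cad
    stride[is_turn] <- stride[is_turn] * 1.4  # slower through turns

    hs_r <- c(0, cumsum(stride))              # right heel strikes + end
    stance_l <- 2 * STANCE_FRACTION * stride / (1 + stsr)
    stance_r <- stsr * stance_l
    hs_l <- hs_r[seq_len(n)] + 0.5 * stride   # left heel strikes
    to_r <- hs_r[seq_len(n)] + stance_r
    to_l <- hs_l + stance_l

    events <- rbind(
      data.frame(foot = "right", event_type = "heel_strike",
                 time_s = hs_r[seq_len(n + 1L)], is_turn = c(is_turn, FALSE)),
      data.frame(foot = "right", event_type = "toe_off", time_s = to_r,
                 is_turn = is_turn),
      data.frame(foot = "left", event_type = "heel_strike", time_s = hs_l,
                 is_turn = is_turn),
      data.frame(foot = "left", event_type = "toe_off", time_s = to_l,
                 is_turn = is_turn))
    events <- events[order(events$time_s), ]
    rownames(events) <- NULL

    t_samp <- seq(0, hs_r[n + 1L] - 1 / fs, by = 1 / fs)
    wr <- warp_phase(t_samp, hs_r, stance_r)
    # left side warp: pad with a virtual leading left cycle so early samples
    # (before the first left heel strike) get a sensible phase
    hs_l_pad <- c(hs_l[1L] - stride[1L], hs_l, hs_r[n + 1L] + 0.5 * stride[n])
    stance_l_pad <- c(stance_l[1L], stance_l, stance_l[n])
    wl <- warp_phase(t_samp, hs_l_pad, stance_l_pad)
    cyc_l <- pmin(pmax(wl$cycle - 1L, 1L), n)  # map padded index to cycle

    signals <- list()
    for (loc in locations) {
      tpl <- location_template(loc)
      sig <- switch(tpl$side,
        right = side_signal(wr$u, wr$cycle, tpl, stsr,
                            profile$asymmetry_gain, +1, is_turn),
        left = side_signal(wl$u, cyc_l, tpl, stsr,
                           profile$asymmetry_gain, -1, is_turn),
        both = 0.5 * (side_signal(wr$u, wr$cycle, tpl, stsr,
                                  profile$asymmetry_gain, +1, is_turn) +
                      side_signal(wl$u, cyc_l, tpl, stsr,
                                  profile$asymmetry_gain, -1, is_turn)))
      sig <- sig + tpl$dc
      if (profile$noise_sd > 0) {
        amp_scale <- rowSums(abs(tpl$amp))
        noise <- matrix(rnorm(length(sig)), 6, ncol(sig)) *
          (profile$noise_sd * amp_scale)
        sig <- sig + noise
      }
      rownames(sig) <- CHANNEL_NAMES
      signals[[loc]] <- sig
    }

    cycles <- data.frame(cycle = seq_len(n), t_start = hs_r[seq_len(n)],
                         stride_s = stride, stance_right_s = stance_r,
                         stance_left_s = stance_l, stsr_target = stsr,
                         is_turn = is_turn)
    structure(list(signals = signals, fs = fs, time_s = t_samp,
                   events = events, cycles = cycles,
                   profile = profile),
              class = "synthetic_recording")
  })
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("synthetic_recording '%s': %d cycles (%d turns), %.1f s at %g Hz, locations: %s\n",
              x$profile$id, nrow(x$cycles), sum(x$cycles$is_turn),
              max(x$time_s), x$fs, paste(names(x$signals), collapse = ", ")))
  invisible(x)
}

#' Generate a multi-participant synthetic gait study
#'
#' @param profiles List of [gait_profile] objects with distinct `id`s.
#' @param locations,fs Passed to [generate_recording].
#' @return Named list of `synthetic_recording`, one per profile.
#' @export
generate_study <- function(profiles, locations = GAIT_LOCATIONS, fs = 60) {
  if (length(profiles) == 0L) stopf("at least one gait_profile required")
  ids <- vapply(profiles, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate participant id '%s'",
                                ids[duplicated(ids)][1L])
  recs <- lapply(profiles, generate_recording, locations = locations, fs = fs)
  names(recs) <- ids
  recs
}

# Gait characteristics of an 11-person able-bodied reference cohort walking
# under rhythmic auditory cueing of stance-time symmetry: realized STSR range
# and cadence (mean +/- sd, steps/min) per participant.
REFERENCE_COHORT <- data.frame(
  id = paste0("P", 1:11),
  stsr_min = c(0.87, 0.90, 0.88, 0.90, 0.83, 0.83, 0.87, 0.89, 0.92, 0.88, 0.85),
  stsr_max = c(1.05, 1.13, 1.07, 1.07, 1.02, 1.04, 1.02, 1.03, 1.04, 1.05, 0.99),
  cadence_mean = c(103.33, 112.12, 112.59, 102.60, 104.88, 108.83, 97.49,
                   105.95, 107.94, 103.91, 101.90),
  cadence_sd = c(3.23, 3.28, 2.88, 3.37, 2.27, 2.60, 2.73, 2.40, 3.30, 2.50, 1.98))

#' Default profiles emulating an 11-participant symmetry-perturbation study
#'
#' Builds one [gait_profile] per participant of a reference able-bodied
#' cohort (11 individuals; per-participant STSR ranges and cadences).
#' Each schedule sweeps the participant's full STSR range in four passes with
#' small per-cycle jitter, emulating cueing trials that gradually shift
#' stance-time symmetry; cycle counts are drawn uniformly from 323 to 544.
#'
#' @param base_seed Integer seed controlling cycle counts, schedules, and all
#'   downstream waveform noise.
#' @param n_cycles_range Inclusive range cycle counts are drawn from.
#' @param noise_sd,asymmetry_gain,turn_every Passed to every profile.
#' @return List of 11 `gait_profile` objects.
#' @export
study_profiles <- function(base_seed = 1L, n_cycles_range = c(323L, 544L),
                           noise_sd = 0.05, asymmetry_gain = 1.0,
                           turn_every = 0L) {
  ref <- REFERENCE_COHORT
  with_seed(base_seed, {
    n_cycles <- sample(seq(n_cycles_range[1L], n_cycles_range[2L]),
                       nrow(ref), replace = TRUE)
    lapply(seq_len(nrow(ref)), function(i) {
      n <- n_cycles[i]
      lo <- ref$stsr_min[i]; hi <- ref$stsr_max[i]
      # four sweeps across the range (hi->lo alternating), plus jitter
      pass <- rep(seq_len(4L), length.out = n)
      frac <- (seq_len(n) - 1) %% ceiling(n / 4) / max(1, ceiling(n / 4) - 1)
      base <- ifelse(pass %% 2 == 1, hi - (hi - lo) * frac,
                     lo + (hi - lo) * frac)
      stsr <- pmin(pmax(base + rnorm(n, 0, 0.008), lo), hi)
      gait_profile(cadence_mean = ref$cadence_mean[i],
                   cadence_sd = ref$cadence_sd[i],
                   stsr_schedule = data.frame(cycle = seq_len(n), stsr = stsr),
                   n_cycles = n, noise_sd = noise_sd,
                   asymmetry_gain = asymmetry_gain, turn_every = turn_every,
                   seed = derive_seed(base_seed, i), id = ref$id[i])
    })
  })
}

#' Write a synthetic recording to CSV signals + JSON events
#'
#' One CSV per sensor location (`<id>_<location>.csv` with columns `time_s`,
#' `gyro_x`..`accel_z`) and one JSON event file (`<id>_events.json`).
#'
#' @param recording A `synthetic_recording`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "synthetic_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- recording$profile$id
  files <- character(0)
  for (loc in names(recording$signals)) {
    df <- data.frame(time_s = recording$time_s,
                     t(recording$signals[[loc]]))
    names(df) <- c("time_s", CHANNEL_NAMES)
    f <- file.path(dir, sprintf("%s_%s.csv", id, loc))
    write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, sprintf("%s_events.json", id))
  jsonlite::write_json(recording$events, f, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}

#' Read a recording written by [write_recording]
#'
#' @param dir Directory holding the CSV/JSON files.
#' @param id Participant identifier used in the file names.
#' @param locations Locations to load.
#' @param fs Sampling rate of the stored signals.
#' @return A list with `signals`, `time_s`, `events`, and `fs`, structured
#'   like a `synthetic_recording` (without the generating profile).
#' @export
read_recording <- function(dir, id, locations = GAIT_LOCATIONS, fs = 60) {
  signals <- list()
  time_s <- NULL
  for (loc in locations) {
    f <- file.path(dir, sprintf("%s_%s.csv", id, loc))
    if (!file.exists(f)) stopf("missing signal file '%s'", f)
    df <- read.csv(f)
    time_s <- df$time_s
    m <- t(as.matrix(df[, CHANNEL_NAMES]))
    rownames(m) <- CHANNEL_NAMES
    signals[[loc]] <- m
  }
  ev <- jsonlite::read_json(file.path(dir, sprintf("%s_events.json", id)),
                            simplifyVector = TRUE)
  structure(list(signals = signals, fs = fs, time_s = time_s, events = ev,
                 cycles = NULL, profile = list(id = id)),
            class = "synthetic_recording")
}
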