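# Filtering, gait-cycle segmentation from annotated events, STSR computation,
# and symmetry-level set construction.

#' Stance-time symmetry ratio
#'
#' STSR = right stance time / left stance time. A value of 1.0 indicates
#' perfect symmetry; values below 1 indicate shorter right stance.
#'
#' @param stance_right,stance_left Stance durations in seconds (> 0);
#'   vectorized.
#' @return Dimensionless ratio(s).
#' @examples
#' compute_stsr(0.60, 0.60)  # 1.0
#' compute_stsr(0.54, 0.60)  # 0.9
#' @export
compute_stsr <- function(stance_right, stance_left) {
  if (any(!is.finite(stance_right)) || any(!is.finite(stance_left)) ||
      any(stance_right <= 0) || any(stance_left <= 0)) {
    stopf("stance durations must be positive and finite")
  }
  stance_right / stance_left
}

# nth-order analog Butterworth lowpass mapped to digital coefficients by the
# bilinear transform with frequency prewarping. Returns list(b, a).
butter_lowpass <- function(order, cutoff, fs) {
  stopifnot(order >= 1, cutoff > 0, fs > 0, cutoff < fs / 2)
  wa <- 2 * fs * tan(pi * cutoff / fs)            # prewarped analog cutoff
  k <- seq_len(order)
  p <- wa * exp(1i * pi * (2 * k + order - 1) / (2 * order))  # analog poles
  zp <- (2 * fs + p) / (2 * fs - p)               # bilinear-mapped poles
  poly_from_roots <- function(r) {
    cf <- 1
    for (x in r) cf <- c(cf, 0) - c(0, cf * x)
    cf
  }
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))   # zeros at z = -1
  b <- b * sum(a) / sum(b)                        # unity DC gain
  list(b = b, a = a)
}

# Direct-form II transposed IIR filtering with explicit initial state.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(b)  # b, a padded to equal length by the caller
  z <- if (is.null(zi)) numeric(n - 1L) else zi
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    y[t] <- b[1L] * x[t] + z[1L]
    if (n > 2L) {
      for (j in seq_len(n - 2L)) {
        z[j] <- b[j + 1L] * x[t] + z[j + 1L] - a[j + 1L] * y[t]
      }
    }
    z[n - 1L] <- b[n] * x[t] - a[n] * y[t]
  }
  y
}

# Steady-state initial filter state for a unit step input, so filtfilt has
# no startup transient (same construction as scipy's lfilter_zi).
iir_zi <- function(b, a) {
  n <- length(b)
  if (n == 1L) return(numeric(0))
  comp_t <- matrix(0, n - 1L, n - 1L)          # companion(a) transposed
  comp_t[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp_t[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  rhs <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - t(comp_t), rhs)
}

#' Zero-phase Butterworth lowpass filter
#'
#' Applies an order-`order` Butterworth lowpass forward and backward
#' (filtfilt with odd-reflection padding), giving zero phase distortion and a
#' squared magnitude response. If `cutoff >= fs / 2` the requested filter is
#' not realizable at this sampling rate and the signal is returned unchanged
#' with a warning -- notably the common 40 Hz cutoff applied to 60 Hz IMU
#' data.
#'
#' @param signal Numeric vector, or a channels x T matrix (filtered per row).
#' @param fs Sampling rate in Hz.
#' @param cutoff Lowpass cutoff in Hz (> 0).
#' @param order Filter order (>= 1); default 4.
#' @return Filtered signal of the same shape.
#' @export
lowpass_filter <- function(signal, fs, cutoff = 40, order = 4L) {
  stopifnot(is_scalar_num(fs), fs > 0, is_scalar_num(order), order >= 1)
  if (!is_scalar_num(cutoff) || cutoff <= 0) stopf("cutoff must be > 0")
  if (any(!is.finite(signal))) stopf("non-finite values in signal")
  if (cutoff >= fs / 2) {
    warnf("cutoff %.1f Hz >= Nyquist (%.1f Hz); returning signal unfiltered",
          cutoff, fs / 2)
    return(signal)
  }
  coefs <- butter_lowpass(order, cutoff, fs)
  b <- coefs$b; a <- coefs$a
  len <- max(length(a), length(b))
  b <- c(b, numeric(len - length(b)))
  a <- c(a, numeric(len - length(a)))
  zi <- iir_zi(b, a)
  filt1 <- function(x) {
    n <- length(x)
    pad <- min(3L * (len - 1L), n - 1L)
    # odd reflection padding + steady-state initial conditions (filtfilt)
    xe <- c(2 * x[1L] - x[pad:1 + 1L], x, 2 * x[n] - x[n - seq_len(pad)])
    y <- iir_filter(b, a, xe, zi * xe[1L])
    y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
    y[pad + seq_len(n)]
  }
  if (is.matrix(signal)) {
    out <- t(apply(signal, 1L, filt1))
    dimnames(out) <- dimnames(signal)
    out
  } else {
    filt1(signal)
  }
}

#' Construct a gait cycle
#'
#' @param channels D x T numeric matrix of signal samples (T >= 2).
#' @param stance_right,stance_left Stance durations in seconds.
#' @param is_turn Logical turn flag.
#' @param index Source cycle index within the recording.
#' @return Object of class `gait_cycle` with computed `stsr`.
#' @export
gait_cycle <- function(channels, stance_right, stance_left, is_turn = FALSE,
                       index = NA_integer_) {
  channels <- as.matrix(channels)
  if (ncol(channels) < 2L) stopf("gait cycle must span at least 2 samples")
  if (any(!is.finite(channels))) stopf("non-finite samples in gait cycle")
  structure(list(channels = channels,
                 stsr = compute_stsr(stance_right, stance_left),
                 stance_right_s = stance_right, stance_left_s = stance_left,
                 is_turn = isTRUE(is_turn), index = as.integer(index)),
            class = "gait_cycle")
}

#' Segment a recording into gait cycles using annotated events
#'
#' Cycles run from one reference-foot heel strike to the next. Stance
#' durations come from the matching heel-strike-to-toe-off interval of each
#' foot within the cycle; STSR is computed per cycle. Cycles overlapping a
#' turn-flagged event are excluded.
#'
#' @param recording A `synthetic_recording` (or any list with `signals`,
#'   `time_s`, `fs`).
#' @param events Event data frame (`foot`, `event_type`, `time_s`,
#'   `is_turn`); defaults to `recording$events`.
#' @param reference_foot `"right"` (default) or `"left"`.
#' @param location Sensor location whose channels populate the cycles.
#' @param exclude_turns Drop turn-overlapping cycles (default `TRUE`).
#' @return List of [gait_cycle] objects.
#' @export
segment_cycles <- function(recording, events = recording$events,
                           reference_foot = c("right", "left"),
                           location = names(recording$signals)[1L],
                           exclude_turns = TRUE) {
  reference_foot <- match.arg(reference_foot)
  other_foot <- if (reference_foot == "right") "left" else "right"
  if (!location %in% names(recording$signals)) {
    stopf("location '%s' not present in recording", location)
  }
  ev <- events[order(events$time_s), ]
  hs_ref <- ev$time_s[ev$foot == reference_foot & ev$event_type == "heel_strike"]
  if (length(hs_ref) < 2L) stopf("need at least 2 %s heel strikes", reference_foot)
  to_ref <- ev$time_s[ev$foot == reference_foot & ev$event_type == "toe_off"]
  hs_oth <- ev$time_s[ev$foot == other_foot & ev$event_type == "heel_strike"]
  to_oth <- ev$time_s[ev$foot == other_foot & ev$event_type == "toe_off"]
  # a cycle counts as a turn if one of its own heel strikes is flagged
  # (toe-offs of a turn stance can spill into the following steady cycle)
  turn_flags <- if (is.null(ev$is_turn)) rep(FALSE, nrow(ev)) else
    as.logical(ev$is_turn)
  turn_times <- ev$time_s[turn_flags %in% TRUE &
                            ev$event_type == "heel_strike"]

  sig <- recording$signals[[location]]
  t_samp <- recording$time_s
  cycles <- list()
  n_turn_dropped <- 0L
  for (k in seq_len(length(hs_ref) - 1L)) {
    t0 <- hs_ref[k]; t1 <- hs_ref[k + 1L]
    to_r <- to_ref[to_ref > t0][1L]
    if (is.na(to_r) || to_r >= t1) {
      stopf("no %s toe-off found within cycle starting at %.3f s",
            reference_foot, t0)
    }
    hs_o <- hs_oth[hs_oth >= t0 & hs_oth < t1][1L]
    if (is.na(hs_o)) stopf("no %s heel strike within cycle starting at %.3f s",
                           other_foot, t0)
    to_o <- to_oth[to_oth > hs_o][1L]
    if (is.na(to_o)) stopf("no %s toe-off after heel strike at %.3f s",
                           other_foot, hs_o)
    st_ref <- to_r - t0
    st_oth <- to_o - hs_o
    is_turn <- length(turn_times) > 0 && any(turn_times >= t0 & turn_times < t1)
    if (exclude_turns && is_turn) {
      n_turn_dropped <- n_turn_dropped + 1L
      next
    }
    idx <- which(t_samp >= t0 & t_samp < t1)
    if (length(idx) < 2L) next
    st_r <- if (reference_foot == "right") st_ref else st_oth
    st_l <- if (reference_foot == "right") st_oth else st_ref
    cycles[[length(cycles) + 1L]] <-
      gait_cycle(sig[, idx, drop = FALSE], st_r, st_l, is_turn = is_turn,
                 index = k)
  }
  if (length(cycles) == 0L) {
    warnf("no usable gait cycles (%d excluded as turns)", n_turn_dropped)
  }
  cycles
}

#' Stack bilateral sensor channels into 12-channel cycles
#'
#' Concatenates the channel matrices of corresponding cycles from two sensor
#' locations (e.g. left and right upper leg) row-wise, yielding 12 x T
#' arrays; cycle metadata (STSR, stance times, turn flag) is taken from the
#' first input and must agree with the second.
#'
#' @param cycles_a,cycles_b Equal-length lists of [gait_cycle] with matching
#'   per-cycle lengths.
#' @return List of stacked [gait_cycle] objects.
#' @export
stack_bilateral <- function(cycles_a, cycles_b) {
  if (length(cycles_a) != length(cycles_b)) {
    stopf("cycle counts differ (%d vs %d)", length(cycles_a), length(cycles_b))
  }
  Map(function(a, b) {
    if (ncol(a$channels) != ncol(b$channels)) {
      stopf("cycle %d: lengths differ (%d vs %d samples)", a$index,
            ncol(a$channels), ncol(b$channels))
    }
    out <- a
    out$channels <- rbind(a$channels, b$channels)
    out
  }, cycles_a, cycles_b)
}

#' Construct a symmetry level
#'
#' @param label Level label (e.g. `"SL1"`).
#' @param cycles List of member [gait_cycle] objects.
#' @param range Optional enforced STSR range `c(min, max)`; defaults to the
#'   member range. All member STSRs must lie inside it.
#' @return Object of class `symmetry_level` with `mean_stsr` and `stsr`.
#' @export
symmetry_level <- function(label, cycles, range = NULL) {
  if (length(cycles) == 0L) stopf("symmetry level '%s' has no cycles", label)
  stsr <- vapply(cycles, function(c) c$stsr, numeric(1))
  if (is.null(range)) range <- c(min(stsr), max(stsr))
  if (any(stsr < range[1L] - 1e-12 | stsr > range[2L] + 1e-12)) {
    stopf("level '%s': member STSR outside stated range [%.3f, %.3f]",
          label, range[1L], range[2L])
  }
  structure(list(label = label, range = range, cycles = cycles, stsr = stsr,
                 mean_stsr = mean(stsr), n = length(cycles)),
            class = "symmetry_level")
}

#' @export
print.symmetry_level <- function(x, ...) {
  cat(sprintf("symmetry_level %s: %d cycles, STSR [%.3f, %.3f], mean %.3f\n",
              x$label, x$n, x$range[1L], x$range[2L], x$mean_stsr))
  invisible(x)
}

#' Partition gait cycles into three non-overlapping symmetry levels
#'
#' Splits non-turn cycles approximately evenly into three STSR ranges, with a
#' gap of at least `min_gap` between adjacent ranges (cycles falling into a
#' gap are discarded) and a minimum difference `min_mean_sep` between the
#' mean STSRs of adjacent levels. SL1 is the most asymmetric (lowest STSR)
#' range and SL3 the most symmetric, ranges ordered by STSR.
#'
#' @param cycles List of [gait_cycle] objects.
#' @param min_gap Minimum STSR gap between adjacent level ranges.
#' @param min_mean_sep Minimum difference between adjacent level mean STSRs.
#' @param balance_ratio Maximum allowed ratio of largest to smallest level
#'   size ("approximately even" split).
#' @param min_cycles_per_level Minimum member count per level.
#' @return List of three [symmetry_level] objects named SL1, SL2, SL3.
#' @export
partition_three_levels <- function(cycles, min_gap = 0.01,
                                   min_mean_sep = 0.03, balance_ratio = 1.5,
                                   min_cycles_per_level = 10L) {
  cycles <- Filter(function(c) !c$is_turn, cycles)
  stsr <- vapply(cycles, function(c) c$stsr, numeric(1))
  if (length(cycles) < 3L * min_cycles_per_level) {
    stopf("need at least %d non-turn cycles, have %d",
          3L * min_cycles_per_level, length(cycles))
  }
  cuts <- quantile(stsr, c(1, 2) / 3, names = FALSE)
  assign_levels <- function(cuts) {
    lo <- cuts - min_gap / 2; hi <- cuts + min_gap / 2
    lev <- ifelse(stsr <= lo[1L], 1L,
                  ifelse(stsr >= hi[1L] & stsr <= lo[2L], 2L,
                         ifelse(stsr >= hi[2L], 3L, NA_integer_)))
    lev
  }
  lev <- assign_levels(cuts)
  sizes <- tabulate(lev, 3L)
  if (any(sizes < min_cycles_per_level)) {
    stopf("STSR spread too small for three levels: sizes %s (best achievable with gap %.3f at cuts %.3f, %.3f)",
          paste(sizes, collapse = "/"), min_gap, cuts[1L], cuts[2L])
  }
  means <- vapply(1:3, function(l) mean(stsr[lev == l & !is.na(lev)]),
                  numeric(1))
  if (any(diff(means) < min_mean_sep)) {
    stopf("adjacent level mean STSRs separated by %s < required %.3f",
          paste(sprintf("%.4f", diff(means)), collapse = ", "), min_mean_sep)
  }
  if (max(sizes) / min(sizes) > balance_ratio) {
    stopf("level sizes %s exceed balance ratio %.2f",
          paste(sizes, collapse = "/"), balance_ratio)
  }
  out <- lapply(1:3, function(l) {
    symmetry_level(paste0("SL", l), cycles[which(!is.na(lev) & lev == l)])
  })
  names(out) <- c("SL1", "SL2", "SL3")
  out
}

# Split one level's cycles into two disjoint equal halves with matching STSR
# mean and sd; redraws up to max_retries.
split_level <- function(level, tol_mean = 0.005, tol_sd = 0.005,
                        max_retries = 200L, seed = 1L) {
  n <- length(level$cycles)
  if (n < 4L) stopf("level '%s' too small to split (%d cycles)", level$label, n)
  with_seed(seed, {
    cycles <- level$cycles
    if (n %% 2L == 1L) {
      drop <- sample.int(n, 1L)
      cycles <- cycles[-drop]
      n <- n - 1L
      message(sprintf("level %s: odd cycle count, dropped one cycle at random",
                      level$label))
    }
    stsr <- vapply(cycles, function(c) c$stsr, numeric(1))
    half <- n %/% 2L
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, half)
      m1 <- mean(stsr[idx]); m2 <- mean(stsr[-idx])
      s1 <- sd(stsr[idx]); s2 <- sd(stsr[-idx])
      if (abs(m1 - m2) <= tol_mean && abs(s1 - s2) <= tol_sd) {
        return(list(
          symmetry_level(level$label, cycles[idx]),
          symmetry_level(paste0(level$label, "*"), cycles[-idx])))
      }
    }
    stopf("level '%s': could not match split mean/sd within tolerance after %d draws",
          level$label, max_retries)
  })
}

#' Partition cycles into two symmetry levels, each split into matched halves
#'
#' First splits non-turn cycles into two non-overlapping STSR ranges (SL1 =
#' lower, SL2 = higher, separated by at least `min_gap`), then randomly
#' partitions each level into two disjoint equal-sized halves (SLX and SLX*)
#' whose STSR mean and standard deviation agree within tolerance, redrawing
#' up to `max_retries` times.
#'
#' @inheritParams partition_three_levels
#' @param tol_mean,tol_sd Maximum allowed |difference| in half mean / sd.
#' @param max_retries Redraw limit per level.
#' @param seed RNG seed for the random splits.
#' @return Named list of four [symmetry_level]: `SL1`, `SL1*`, `SL2`, `SL2*`.
#' @export
partition_two_levels_split <- function(cycles, min_gap = 0.01,
                                       min_mean_sep = 0.03,
                                       balance_ratio = 1.5,
                                       min_cycles_per_level = 20L,
                                       tol_mean = 0.005, tol_sd = 0.005,
                                       max_retries = 200L, seed = 1L) {
  cycles <- Filter(function(c) !c$is_turn, cycles)
  stsr <- vapply(cycles, function(c) c$stsr, numeric(1))
  if (length(cycles) < 2L * min_cycles_per_level) {
    stopf("need at least %d non-turn cycles, have %d",
          2L * min_cycles_per_level, length(cycles))
  }
  cut <- stats::median(stsr)
  in1 <- stsr <= cut - min_gap / 2
  in2 <- stsr >= cut + min_gap / 2
  sizes <- c(sum(in1), sum(in2))
  if (any(sizes < min_cycles_per_level)) {
    stopf("STSR spread too small for two levels: sizes %s",
          paste(sizes, collapse = "/"))
  }
  if (max(sizes) / min(sizes) > balance_ratio) {
    stopf("level sizes %s exceed balance ratio %.2f",
          paste(sizes, collapse = "/"), balance_ratio)
  }
  sl1 <- symmetry_level("SL1", cycles[in1])
  sl2 <- symmetry_level("SL2", cycles[in2])
  if (sl2$mean_stsr - sl1$mean_stsr < min_mean_sep) {
    stopf("two-level mean STSR separation %.4f < required %.3f",
          sl2$mean_stsr - sl1$mean_stsr, min_mean_sep)
  }
  h1 <- split_level(sl1, tol_mean, tol_sd, max_retries, derive_seed(seed, 1L))
  h2 <- split_level(sl2, tol_mean, tol_sd, max_retries, derive_seed(seed, 2L))
  out <- list(h1[[1L]], h1[[2L]], h2[[1L]], h2[[2L]])
  names(out) <- c("SL1", "SL1*", "SL2", "SL2*")
  out
}

#' Write a cycle manifest CSV
#'
#' @param levels Named list of [symmetry_level] objects (or a single list of
#'   [gait_cycle], written with level = NA).
#' @param file Output CSV path.
#' @return Invisibly, the manifest data frame.
#' @export
write_cycle_manifest <- function(levels, file) {
  if (length(levels) && inherits(levels[[1L]], "gait_cycle")) {
    levels <- list(structure(list(label = NA_character_, cycles = levels),
                             class = "symmetry_level"))
  }
  manifest <- do.call(rbind, lapply(levels, function(lv) {
    do.call(rbind, lapply(lv$cycles, function(c) {
      data.frame(cycle_id = c$index, stsr = c$stsr, level = lv$label,
                 n_samples = ncol(c$channels), is_turn = c$is_turn)
    }))
  }))
  rownames(manifest) <- NULL
  write.csv(manifest, file, row.names = FALSE)
  invisible(manifest)
}
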