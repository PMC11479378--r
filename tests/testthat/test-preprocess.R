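test_that("compute_stsr matches direct division and rejects bad input", {
  expect_identical(compute_stsr(0.60, 0.60), 1.0)
  expect_equal(compute_stsr(0.54, 0.60), 0.9)
  expect_equal(compute_stsr(0.60, 0.54), 0.60 / 0.54)
  withr::with_seed(1, {
    r <- runif(1000, 0.2, 1.5); l <- runif(1000, 0.2, 1.5)
    expect_identical(compute_stsr(r, l), r / l)
  })
  expect_error(compute_stsr(0, 0.6), "positive")
  expect_error(compute_stsr(0.6, -1), "positive")
  expect_error(compute_stsr(NA_real_, 0.6), "positive")
})

test_that("lowpass filter matches the Butterworth magnitude response", {
  # DC passes untouched
  const <- rep(2.5, 200)
  expect_equal(lowpass_filter(const, fs = 100, cutoff = 10), const,
               tolerance = 1e-8)
  # unrealizable cutoff (the 40 Hz / 60 Hz print) -> warn + pass-through
  x <- sin(2 * pi * 5 * seq(0, 2, by = 1 / 60))
  expect_warning(y <- lowpass_filter(x, fs = 60, cutoff = 40), "Nyquist")
  expect_identical(y, x)
  expect_error(lowpass_filter(x, fs = 60, cutoff = -1), "cutoff")
  expect_error(lowpass_filter(c(x, NA), fs = 60, cutoff = 10), "non-finite")

  # stop-band: 25 Hz sine through 10 Hz 4th-order filter; |H|^2 = 2.6e-4
  t <- seq(0, 4, by = 1 / 100)
  x25 <- sin(2 * pi * 25 * t)
  y25 <- lowpass_filter(x25, fs = 100, cutoff = 10, order = 4)
  expect_lt(sqrt(mean(y25^2)) / sqrt(mean(x25^2)), 0.05)

  # pass-band: 5 Hz sine, expected amplitude ratio (1+(5/10)^8)^-1 = 0.9961
  x5 <- sin(2 * pi * 5 * t)
  y5 <- lowpass_filter(x5, fs = 100, cutoff = 10, order = 4)
  core <- 50:350  # avoid edges
  ratio <- sqrt(mean(y5[core]^2) / mean(x5[core]^2))
  expect_equal(ratio, 1 / (1 + (5 / 10)^8), tolerance = 0.01)

  # matrices are filtered per channel
  m <- rbind(x25, x5)
  ym <- lowpass_filter(m, fs = 100, cutoff = 10, order = 4)
  expect_equal(dim(ym), dim(m))
  expect_equal(ym[2, ], y5, tolerance = 1e-12)
})

test_that("segmentation fenceposts, stance matching, and turn handling", {
  # 11 reference heel strikes -> 10 cycles, hand-built event table
  hs_r <- seq(0, 10); n <- 10
  ev <- rbind(
    data.frame(foot = "right", event_type = "heel_strike", time_s = hs_r,
               is_turn = FALSE),
    data.frame(foot = "right", event_type = "toe_off",
               time_s = hs_r[1:n] + 0.6, is_turn = FALSE),
    data.frame(foot = "left", event_type = "heel_strike",
               time_s = hs_r[1:n] + 0.5, is_turn = FALSE),
    data.frame(foot = "left", event_type = "toe_off",
               time_s = hs_r[1:n] + 0.5 + 0.55, is_turn = FALSE))
  rec <- list(signals = list(pelvis = matrix(rnorm(6 * 660), 6)),
              time_s = seq(0, 11 - 1 / 60, by = 1 / 60), fs = 60)
  cyc <- segment_cycles(rec, events = ev, location = "pelvis")
  expect_length(cyc, 10L)
  expect_equal(vapply(cyc, function(c) c$stsr, numeric(1)),
               rep(0.6 / 0.55, 10))

  # all cycles flagged as turns -> empty with a warning
  ev_turn <- ev
  ev_turn$is_turn <- TRUE
  expect_warning(none <- segment_cycles(rec, events = ev_turn,
                                        location = "pelvis"),
                 "no usable")
  expect_length(none, 0L)

  expect_error(segment_cycles(rec, events = ev[ev$foot == "right", ],
                              location = "pelvis"), "left heel strike")
  one_hs <- ev[ev$event_type == "heel_strike" & ev$time_s == 0, ]
  expect_error(segment_cycles(rec, events = one_hs, location = "pelvis"),
               "at least 2")
})

test_that("round trip: generator cycles are recovered by segmentation", {
  rec <- test_recording(stsr = 0.9, n_cycles = 25, noise_sd = 0.05)
  cyc <- segment_cycles(rec, location = "UL")
  expect_length(cyc, 25L)
  expect_equal(mean(vapply(cyc, function(c) c$stsr, numeric(1))), 0.9,
               tolerance = 0.01)
})

test_that("stack_bilateral concatenates channels and validates lengths", {
  rec <- test_recording(n_cycles = 8)
  ul <- segment_cycles(rec, location = "UL")
  ur <- segment_cycles(rec, location = "UR")
  st <- stack_bilateral(ul, ur)
  expect_equal(nrow(st[[1]]$channels), 12L)
  expect_equal(st[[3]]$stsr, ul[[3]]$stsr)

  self <- stack_bilateral(ul, ul)
  expect_identical(self[[1]]$channels[1:6, ], self[[1]]$channels[7:12, ])

  expect_error(stack_bilateral(ul, ur[-1]), "counts differ")
  short <- ul
  short[[2]]$channels <- short[[2]]$channels[, -1]
  expect_error(stack_bilateral(short, ur), "lengths differ")
})

test_that("three-level partition satisfies gap, separation, and balance", {
  # uniform STSR grid over [0.85, 1.05] (tertile-like split)
  cyc <- fake_cycles(seq(0.85, 1.05, length.out = 120))
  levs <- partition_three_levels(cyc)
  expect_named(levs, c("SL1", "SL2", "SL3"))
  expect_gte(levs$SL2$range[1] - levs$SL1$range[2], 0.01)
  expect_gte(levs$SL3$range[1] - levs$SL2$range[2], 0.01)
  expect_gte(levs$SL2$mean_stsr - levs$SL1$mean_stsr, 0.03)
  expect_gte(levs$SL3$mean_stsr - levs$SL2$mean_stsr, 0.03)
  sizes <- vapply(levs, function(l) l$n, integer(1))
  expect_lte(max(sizes) / min(sizes), 1.5)

  # every non-turn cycle lands in at most one level
  ids <- unlist(lapply(levs, function(l)
    vapply(l$cycles, function(c) c$index, integer(1))))
  expect_false(anyDuplicated(ids) > 0)

  # Participant-1-like spread [0.87, 1.05] also partitions cleanly
  cyc1 <- fake_cycles(seq(0.87, 1.05, length.out = 150))
  levs1 <- partition_three_levels(cyc1)
  expect_gte(levs1$SL2$mean_stsr - levs1$SL1$mean_stsr, 0.03)

  # degenerate input: no spread
  expect_error(partition_three_levels(fake_cycles(rep(1, 100))),
               "spread too small|sizes")
  # turn cycles are ignored
  cyc_t <- fake_cycles(seq(0.85, 1.05, length.out = 120),
                       is_turn = rep(c(FALSE, TRUE), 60))
  levs_t <- partition_three_levels(cyc_t, min_cycles_per_level = 5)
  expect_true(all(vapply(unlist(lapply(levs_t, `[[`, "cycles"),
                                recursive = FALSE),
                         function(c) !c$is_turn, logical(1))))
})

test_that("two-level split-half yields disjoint matched halves", {
  withr::with_seed(9, {
    stsr <- c(rnorm(200, 0.92, 0.015), rnorm(200, 1.0, 0.015))
  })
  stsr <- pmin(pmax(stsr, 0.85), 1.06)
  halves <- partition_two_levels_split(fake_cycles(stsr), seed = 4)
  expect_named(halves, c("SL1", "SL1*", "SL2", "SL2*"))
  for (pair in list(c("SL1", "SL1*"), c("SL2", "SL2*"))) {
    a <- halves[[pair[1]]]; b <- halves[[pair[2]]]
    expect_equal(a$n, b$n)
    expect_lte(abs(a$mean_stsr - b$mean_stsr), 0.005)
    expect_lte(abs(sd(a$stsr) - sd(b$stsr)), 0.005)
    ids_a <- vapply(a$cycles, function(c) c$index, integer(1))
    ids_b <- vapply(b$cycles, function(c) c$index, integer(1))
    expect_length(intersect(ids_a, ids_b), 0L)
  }
  # odd count in a level: one cycle dropped, with a message
  odd_level <- symmetry_level("SL1", fake_cycles(seq(0.90, 0.94,
                                                     length.out = 21)))
  expect_message(h <- hmmsm:::split_level(odd_level, seed = 2),
                 "dropped one cycle")
  expect_equal(h[[1]]$n, 10L)
  expect_equal(h[[2]]$n, 10L)
})

test_that("cycle manifest is written with one row per cycle", {
  dir <- withr::local_tempdir()
  cyc <- fake_cycles(seq(0.85, 1.05, length.out = 60))
  levs <- partition_three_levels(cyc, min_cycles_per_level = 5)
  f <- file.path(dir, "manifest.csv")
  m <- write_cycle_manifest(levs, f)
  expect_true(file.exists(f))
  expect_equal(nrow(m), sum(vapply(levs, function(l) l$n, integer(1))))
  expect_setequal(unique(m$level), c("SL1", "SL2", "SL3"))
})
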