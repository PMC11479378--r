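# Helpers building numeric comparison grids without any HMM training.
grid_from_values <- function(v) {
  # v: named vector with entries 11, 12, 13, 22, 23, 33
  g <- matrix(NA_real_, 3, 3)
  g[1, 1] <- v[["11"]]; g[2, 2] <- v[["22"]]; g[3, 3] <- v[["33"]]
  g[1, 2] <- g[2, 1] <- v[["12"]]
  g[1, 3] <- g[3, 1] <- v[["13"]]
  g[2, 3] <- g[3, 2] <- v[["23"]]
  g
}

ordered_grids <- function(n = 11, noise_sd = 0.02, seed = 1) {
  base <- c("11" = 0.95, "22" = 0.94, "33" = 0.95,
            "12" = 0.85, "23" = 0.85, "13" = 0.75)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      grid_from_values(base + rnorm(6, 0, noise_sd))
    })
  })
}

test_that("expected_differences enumerates the eight ordered hypotheses", {
  h <- expected_differences()
  expect_equal(nrow(h), 8L)
  expect_false(anyDuplicated(h$label) > 0)

  perfect <- grid_from_values(c("11" = 0.95, "22" = 0.94, "33" = 0.95,
                                "12" = 0.85, "23" = 0.85, "13" = 0.75))
  expect_true(all(expected_differences(perfect)$direction_correct))

  flat <- grid_from_values(c("11" = 0.9, "22" = 0.9, "33" = 0.9,
                             "12" = 0.9, "23" = 0.9, "13" = 0.9))
  expect_false(any(expected_differences(flat)$direction_correct))
  expect_error(expected_differences(matrix(NA_real_, 3, 3)), "missing")
})

test_that("RM-ANOVA agrees with stats::aov on random tables", {
  withr::with_seed(6, {
    for (i in 1:5) {
      m <- matrix(rnorm(8 * 6), 8, 6)
      res <- hmmsm:::rm_anova(m)
      df <- data.frame(y = as.vector(m),
                       subj = factor(rep(seq_len(8), 6)),
                       cond = factor(rep(seq_len(6), each = 8)))
      ref <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
      tab <- ref[["Error: subj:cond"]][[1]]
      expect_equal(res$F, tab[["F value"]][1], tolerance = 1e-10)
      expect_equal(res$p, tab[["Pr(>F)"]][1], tolerance = 1e-10)
    }
  })
})

test_that("validity analysis flags strong orderings and not flat data", {
  grids <- ordered_grids(n = 11, noise_sd = 0.02)
  res <- validity_analysis(grids)
  expect_equal(res$n_significant, 8L)
  expect_true(all(res$hypotheses$p_adj >= res$hypotheses$p_raw))
  expect_true(all(res$hypotheses$p_adj <= 1))
  expect_lt(res$rm_anova$p, 0.05)

  # permutation oracle (sign flips) for the strongest hypothesis
  h <- res$hypotheses
  d <- vapply(grids, function(g) g[1, 1] - g[1, 3], numeric(1))
  withr::with_seed(42, {
    t_obs <- mean(d) / (sd(d) / sqrt(length(d)))
    t_perm <- replicate(10000, {
      ds <- d * sample(c(-1, 1), length(d), replace = TRUE)
      mean(ds) / (sd(ds) / sqrt(length(ds)))
    })
    p_perm <- mean(abs(t_perm) >= abs(t_obs))
  })
  expect_lt(abs(h$p_raw[h$label == "S(1,1)>S(1,3)"] - p_perm), 0.01)

  # identical constant grids: zero-variance path, nothing significant
  flat <- replicate(5, grid_from_values(
    c("11" = 0.9, "22" = 0.9, "33" = 0.9,
      "12" = 0.9, "23" = 0.9, "13" = 0.9)), simplify = FALSE)
  res_flat <- validity_analysis(flat)
  expect_equal(res_flat$n_significant, 0L)
  expect_true(all(res_flat$hypotheses$zero_variance))
  expect_equal(res_flat$rm_anova$p, 1)

  expect_error(validity_analysis(grids[1:2]), "at least 3")
})

test_that("Bonferroni adjustment caps at one", {
  # grids built so one hypothesis has a high raw p
  grids <- ordered_grids(n = 6, noise_sd = 0.2, seed = 3)
  res <- validity_analysis(grids)
  expect_true(all(res$hypotheses$p_adj <= 1))
  expect_true(any(res$hypotheses$p_adj == 1))
})

test_that("reliability groups count 3 within / 4 between scores", {
  make_ens <- function(mu, label) {
    toy_ensemble(lapply(1:2, function(i)
      toy_hmm(list(mu + i * 0.01, mu + 8), list(1, 1))), label)
  }
  ens <- list("SL1" = make_ens(0.0, "SL1"), "SL1*" = make_ens(0.02, "SL1*"),
              "SL2" = make_ens(1.0, "SL2"), "SL2*" = make_ens(1.02, "SL2*"))
  gt <- reliability_groups(ens, kernel = "rational")
  expect_equal(as.vector(table(gt$group)[c("A", "B", "C", "D")]),
               c(3L, 4L, 4L, 3L))
  # symmetry of the measure: groups B and C hold the same score multiset
  expect_setequal(round(gt$score[gt$group == "B"], 12),
                  round(gt$score[gt$group == "C"], 12))
  # swapping SLX and SLX* leaves each group's score multiset unchanged
  swapped <- ens[c(2, 1, 4, 3)]
  names(swapped) <- names(ens)
  gs <- reliability_groups(swapped, kernel = "rational")
  for (g in c("A", "B", "C", "D")) {
    expect_setequal(round(gt$score[gt$group == g], 12),
                    round(gs$score[gs$group == g], 12))
  }
  expect_error(reliability_groups(ens[1:3]), "missing ensemble")
})

test_that("ICC(3,1) matches a brute-force ANOVA decomposition", {
  withr::with_seed(10, {
    for (i in 1:5) {
      m <- matrix(rnorm(5 * 3), 5, 3) + rnorm(5)
      res <- icc_consistency(m)
      df <- data.frame(y = as.vector(m),
                       row = factor(rep(1:5, 3)),
                       col = factor(rep(1:3, each = 5)))
      a <- anova(stats::lm(y ~ row + col, data = df))
      msr <- a["row", "Mean Sq"]; mse <- a["Residuals", "Mean Sq"]
      expect_equal(res$icc, (msr - mse) / (msr + 2 * mse), tolerance = 1e-10)
      expect_equal(res$msr, msr, tolerance = 1e-10)
      expect_equal(res$mse, mse, tolerance = 1e-10)
    }
  })
  # identical raters with row variance -> ICC exactly 1
  m1 <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  expect_equal(icc_consistency(m1)$icc, 1)
  # pure noise -> ICC near zero
  withr::with_seed(11, {
    m0 <- matrix(rnorm(50 * 3), 50, 3)
  })
  expect_lt(abs(icc_consistency(m0)$icc), 0.15)
  expect_error(icc_consistency(matrix(1, 1, 3)), ">= 2")
  expect_error(icc_consistency(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("ICC classification follows the stated thresholds", {
  fake <- function(icc) {
    # construct a table with exactly the requested consistency by scaling
    # row effects against noise (closed form: icc = vr / (vr + ve))
    withr::with_seed(12, {
      n <- 200; k <- 3
      vr <- icc; ve <- 1 - icc
      r <- rnorm(n, sd = sqrt(vr))
      matrix(r, n, k) + matrix(rnorm(n * k, sd = sqrt(ve)), n, k)
    })
  }
  expect_equal(icc_consistency(fake(0.95))$classification, "excellent")
  expect_equal(icc_consistency(fake(0.8))$classification, "good")
  expect_equal(icc_consistency(fake(0.6))$classification, "moderate")
  expect_equal(icc_consistency(fake(0.2))$classification, "poor")
})

test_that("SEM and MDC follow their defining formulas", {
  res <- sem_mdc(0.079, 0)
  expect_equal(res$sem, 0.079)
  expect_equal(round(res$mdc, 3), 0.219)
  expect_equal(round(sem_mdc(0.048, 0)$mdc, 3), 0.133)
  expect_equal(sem_mdc(0.5, 1), list(sem = 0, mdc = 0))
  s <- sem_mdc(0.2, 0.75)
  expect_equal(s$sem, 0.2 * sqrt(0.25))
  expect_equal(s$mdc, 1.96 * sqrt(2) * s$sem)
  expect_error(sem_mdc(0.1, 1.2), "<= 1")
  expect_error(sem_mdc(-0.1, 0.5))
})

test_that("reliability_analysis pools group tables into ICC/SEM/MDC", {
  # construct per-participant tables with strong participant effects
  withr::with_seed(13, {
    tables <- lapply(1:8, function(p) {
      base <- 0.7 + p * 0.02
      data.frame(
        group = c("A", "A", "A", "B", "B", "B", "B",
                  "C", "C", "C", "C", "D", "D", "D"),
        comparison = "x",
        score = c(base + rnorm(3, 0, 0.01),
                  base - 0.1 + rnorm(4, 0, 0.01),
                  base - 0.1 + rnorm(4, 0, 0.01),
                  base + rnorm(3, 0, 0.01)))
    })
  })
  res <- reliability_analysis(tables)
  expect_s3_class(res, "reliability_result")
  expect_gt(res$icc, 0.5)
  expect_equal(res$mdc, 1.96 * sqrt(2) * res$sem, tolerance = 1e-12)
  expect_equal(dim(res$table), c(8L * 4L, 3L))
  expect_equal(res$icc_between$k, 4L)
  expect_equal(res$icc_within$k, 3L)
})

test_that("split-half reliability is tighter than a 0.1-STSR level shift", {
  # one synthetic participant: between-half similarity within a level must
  # sit far above the between-level similarity at a 0.1 STSR separation
  rec <- generate_recording(
    gait_profile(cadence_mean = 105, cadence_sd = 2,
                 stsr_schedule = data.frame(
                   cycle = 1:160,
                   stsr = rep(c(0.90, 1.00), each = 80)),
                 n_cycles = 160, noise_sd = 0.05, seed = 21),
    locations = c("UL", "UR"))
  cyc <- test_cycles_12(rec)
  halves <- partition_two_levels_split(cyc, seed = 3)
  ens <- lapply(seq_along(halves), function(l) {
    train_ensemble(halves[[l]], n_models = 3, n_states = 2,
                   base_seed = 50 + l)
  })
  names(ens) <- names(halves)
  gt <- reliability_groups(ens, kernel = "rational")
  within1 <- gt$score[gt$group == "A"]
  between <- gt$score[gt$group == "B"]
  # group A scores agree pairwise within 0.05
  expect_lt(max(within1) - min(within1), 0.05)
  # within-half vs between-half gap smaller than the between-level effect
  expect_lt(max(within1) - min(within1), min(within1) - max(between))
  expect_gt(min(within1), max(between))
})

test_that("state sweep smoke test: factorial table, serialized outputs", {
  profs <- study_profiles(base_seed = 5, n_cycles_range = c(60L, 70L))[1:3]
  recs <- generate_study(profs, locations = "pelvis")
  dir <- withr::local_tempdir()
  res <- run_state_sweep(recs, states = 2L, locations = "pelvis",
                         n_models = 2L, base_seed = 9, out_dir = dir)
  expect_equal(nrow(res), 1L)
  expect_true(res$n_significant %in% 0:8)
  expect_true(file.exists(file.path(dir, "sweep_results.csv")))
  expect_true(file.exists(file.path(dir, "sweep_manifest.json")))
})
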