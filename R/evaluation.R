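# Validity (three-symmetry-level) and reliability (two-symmetry-level
# split-half) evaluation paradigms for the HMM-SM.

GRID_CONDITIONS <- c("1-1", "1-2", "1-3", "2-2", "2-3", "3-3")

#' Pairwise mean-similarity grid for one participant's three symmetry levels
#'
#' Trains one HMM ensemble per symmetry level and fills the symmetric 3 x 3
#' grid of mean ensemble similarities: within-level entries average the 45
#' unordered model pairs, between-level entries the 100 cross pairs.
#'
#' @param levels Named list of three [symmetry_level] (SL1..SL3).
#' @param n_states,n_models,topology,group_size,max_iter,tol,cov_reg_scale
#'   Training hyperparameters, see [train_ensemble].
#' @param tau,kernel Correspondence map, see [hmm_sm]. The drivers default
#'   to the `"rational"` kernel, which stays responsive at the divergence
#'   scales of trained gait models (see the methods vignette).
#' @param base_seed Master seed (per-level seeds derived from it).
#' @return Object of class `comparison_grid`: symmetric 3 x 3 matrix `grid`
#'   plus the level labels and mean STSRs.
#' @export
comparison_grid <- function(levels, n_states = 3L, n_models = 10L,
                            topology = "cyclic", group_size = 4L,
                            max_iter = 100L, tol = 1e-4,
                            cov_reg_scale = 1e-6, tau = 1,
                            kernel = "rational", base_seed = 1L) {
  stopifnot(length(levels) == 3L)
  ensembles <- lapply(seq_along(levels), function(l) {
    train_ensemble(levels[[l]], n_models = n_models, n_states = n_states,
                   topology = topology, group_size = group_size,
                   max_iter = max_iter, tol = tol,
                   cov_reg_scale = cov_reg_scale,
                   base_seed = derive_seed(base_seed, l))
  })
  g <- matrix(NA_real_, 3L, 3L,
              dimnames = list(names(levels), names(levels)))
  for (a in 1:3) {
    for (b in a:3) {
      s <- if (a == b) {
        ensemble_similarity(ensembles[[a]], tau = tau, kernel = kernel)
      } else {
        ensemble_similarity(ensembles[[a]], ensembles[[b]], tau = tau,
                            kernel = kernel)
      }
      g[a, b] <- g[b, a] <- s$value
    }
  }
  structure(list(grid = g,
                 mean_stsr = vapply(levels, function(l) l$mean_stsr,
                                    numeric(1))),
            class = "comparison_grid")
}

grid_value <- function(grid, a, b) {
  g <- if (inherits(grid, "comparison_grid")) grid$grid else grid
  g[a, b]
}

#' The eight expected ordered similarity differences
#'
#' For a measure that decreases as stance-time symmetry moves away from a
#' level's own range, similarity grids should satisfy eight ordered
#' relations: three anchored at each extreme level (e.g.
#' S(1,1) > S(1,2) > S(1,3) plus S(1,1) > S(1,3)) and two for the middle
#' level, whose two between-level comparisons carry no mutual expected
#' order. Each row reads "value at (a_row, a_col) exceeds value at
#' (b_row, b_col)".
#'
#' @param grid Optional [comparison_grid]; when supplied, observed
#'   differences and direction flags are appended.
#' @param hypotheses Optional replacement hypothesis table (same columns).
#' @return Data frame with columns `a_row`, `a_col`, `b_row`, `b_col`,
#'   `label`, and (given a grid) `diff`, `direction_correct`.
#' @export
expected_differences <- function(grid = NULL, hypotheses = NULL) {
  h <- hypotheses
  if (is.null(h)) {
    h <- data.frame(
      a_row = c(1, 1, 1, 3, 2, 3, 2, 2),
      a_col = c(1, 2, 1, 3, 3, 3, 2, 2),
      b_row = c(1, 1, 1, 2, 1, 1, 1, 2),
      b_col = c(2, 3, 3, 3, 3, 3, 2, 3))
    h$label <- sprintf("S(%d,%d)>S(%d,%d)", h$a_row, h$a_col, h$b_row, h$b_col)
  }
  if (!is.null(grid)) {
    g <- if (inherits(grid, "comparison_grid")) grid$grid else grid
    if (any(!is.finite(g))) stopf("comparison grid has missing cells")
    h$diff <- vapply(seq_len(nrow(h)), function(i) {
      g[h$a_row[i], h$a_col[i]] - g[h$b_row[i], h$b_col[i]]
    }, numeric(1))
    h$direction_correct <- h$diff > 0
  }
  h
}

# One-way repeated-measures ANOVA (subjects x conditions), no sphericity
# correction. Returns F, df, p.
rm_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  if (ms_err <= 0) {
    f <- if (ms_cond <= 0) NaN else Inf
  } else {
    f <- ms_cond / ms_err
  }
  p <- if (is.nan(f)) 1 else pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, p = p)
}

#' Three-symmetry-level validity analysis
#'
#' Given one similarity grid per participant, tests the eight expected
#' ordered differences: Shapiro-Wilk normality check on each hypothesis's
#' paired differences, a one-way repeated-measures ANOVA across the six
#' unique grid conditions with participants as subjects, then paired t-tests
#' per hypothesis with Bonferroni adjustment over the family of eight
#' (adjusted p = min(1, 8 x raw p)). A hypothesis counts as significant only
#' if its adjusted p is below `alpha` AND the mean difference has the
#' expected sign.
#'
#' @param grids List of [comparison_grid] (>= 3 participants).
#' @param alpha Significance level (default 0.05).
#' @param hypotheses Optional custom hypothesis table, see
#'   [expected_differences].
#' @return Object of class `validity_result`: hypothesis table with raw and
#'   adjusted p-values, Shapiro-Wilk p's, the RM-ANOVA, and
#'   `n_significant` out of 8.
#' @export
validity_analysis <- function(grids, alpha = 0.05, hypotheses = NULL) {
  if (length(grids) < 3L) stopf("need at least 3 participants, have %d",
                                length(grids))
  h <- expected_differences(hypotheses = hypotheses)
  n_h <- nrow(h)
  diffs <- vapply(seq_len(n_h), function(i) {
    vapply(grids, function(g) {
      grid_value(g, h$a_row[i], h$a_col[i]) -
        grid_value(g, h$b_row[i], h$b_col[i])
    }, numeric(1))
  }, numeric(length(grids)))

  cond_mat <- t(vapply(grids, function(g) {
    gm <- if (inherits(g, "comparison_grid")) g$grid else g
    c(gm[1, 1], gm[1, 2], gm[1, 3], gm[2, 2], gm[2, 3], gm[3, 3])
  }, numeric(6)))
  colnames(cond_mat) <- GRID_CONDITIONS
  anova_res <- rm_anova(cond_mat)

  res <- h
  res$mean_diff <- colMeans(diffs)
  res$shapiro_p <- apply(diffs, 2L, function(d) {
    if (sd(d) == 0) NA_real_ else shapiro.test(d)$p.value
  })
  res$p_raw <- apply(diffs, 2L, function(d) {
    if (sd(d) == 0) NA_real_ else t.test(d)$p.value
  })
  res$p_adj <- pmin(1, res$p_raw * n_h)
  res$direction_correct <- res$mean_diff > 0
  res$zero_variance <- apply(diffs, 2L, function(d) sd(d) == 0)
  res$significant <- !res$zero_variance & !is.na(res$p_adj) &
    res$p_adj < alpha & res$direction_correct
  structure(list(hypotheses = res, rm_anova = anova_res,
                 condition_means = colMeans(cond_mat),
                 n_significant = sum(res$significant), alpha = alpha,
                 n_participants = length(grids)),
            class = "validity_result")
}

#' @export
print.validity_result <- function(x, ...) {
  cat(sprintf("Three-level validity: %d/%d expected differences significant (alpha = %g, Bonferroni x%d)\n",
              x$n_significant, nrow(x$hypotheses), x$alpha,
              nrow(x$hypotheses)))
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.2f, p = %.3g\n", x$rm_anova$df1,
              x$rm_anova$df2, x$rm_anova$F, x$rm_anova$p))
  print(x$hypotheses[, c("label", "mean_diff", "p_adj", "significant")],
        digits = 3)
  invisible(x)
}

#' Split-half reliability comparison groups
#'
#' Given the four split-half ensembles of one participant (SL1, SL1*, SL2,
#' SL2*), computes all ten distinct mean ensemble similarities and arranges
#' them into four groups whose members should agree for a reliable measure:
#' group A = the three within-level-1 comparisons {(1,1), (1,1*), (1*,1*)},
#' group D = the within-level-2 analogues, and groups B and C = the four
#' between-level comparisons {(1,2), (1,2*), (1*,2), (1*,2*)} as the two
#' (numerically equal, by symmetry of the measure) off-diagonal blocks of
#' the 4 x 4 comparison arrangement.
#'
#' @param ensembles Named list of four [hmm_ensemble]: `SL1`, `SL1*`, `SL2`,
#'   `SL2*` (order as returned by [partition_two_levels_split]).
#' @param tau,kernel Correspondence map, see [hmm_sm].
#' @return Data frame with columns `group` (A/B/C/D), `comparison`, `score`.
#' @export
reliability_groups <- function(ensembles, tau = 1, kernel = "rational") {
  need <- c("SL1", "SL1*", "SL2", "SL2*")
  if (!all(need %in% names(ensembles))) {
    stopf("missing ensemble(s): %s",
          paste(setdiff(need, names(ensembles)), collapse = ", "))
  }
  pair_score <- function(a, b) {
    if (identical(a, b)) {
      ensemble_similarity(ensembles[[a]], tau = tau, kernel = kernel)$value
    } else {
      ensemble_similarity(ensembles[[a]], ensembles[[b]], tau = tau,
                          kernel = kernel)$value
    }
  }
  between <- c("SL1|SL2", "SL1|SL2*", "SL1*|SL2", "SL1*|SL2*")
  rows <- rbind(
    data.frame(group = "A",
               comparison = c("SL1|SL1", "SL1|SL1*", "SL1*|SL1*")),
    data.frame(group = "B", comparison = between),
    data.frame(group = "C", comparison = between),
    data.frame(group = "D",
               comparison = c("SL2|SL2", "SL2|SL2*", "SL2*|SL2*")))
  parts <- strsplit(rows$comparison, "|", fixed = TRUE)
  cache <- list()
  rows$score <- vapply(parts, function(p) {
    key <- paste(sort(p), collapse = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- pair_score(p[[1L]], p[[2L]])
    }
    cache[[key]]
  }, numeric(1))
  rows
}

#' ICC(3,1): two-way mixed-effects, consistency, single measurement
#'
#' Computes \eqn{ICC(3,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)} from the
#' two-way ANOVA decomposition of a complete targets x raters table, with
#' the F-based 95% confidence interval, and classifies reliability as poor
#' (< 0.5), moderate (0.5-0.75), good (0.75-0.9) or excellent (> 0.9).
#'
#' @param table Numeric matrix, rows = targets (n >= 2), columns = raters /
#'   repeated measurements (k >= 2), complete.
#' @param alpha CI level is `1 - alpha`.
#' @return List with `icc`, `ci` (length 2), `classification`, `F`, `msr`,
#'   `mse`, `n`, `k`.
#' @export
icc_consistency <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 2L || k < 2L) stopf("need >= 2 targets and >= 2 raters (got %d x %d)",
                              n, k)
  if (any(!is.finite(table))) stopf("table must be complete and finite")
  grand <- mean(table)
  ss_r <- k * sum((rowMeans(table) - grand)^2)
  ss_c <- n * sum((colMeans(table) - grand)^2)
  ss_e <- sum((table - grand)^2) - ss_r - ss_c
  msr <- ss_r / (n - 1L)
  mse <- ss_e / ((n - 1L) * (k - 1L))
  icc <- if (msr + (k - 1) * mse <= 0) NaN else
    (msr - mse) / (msr + (k - 1) * mse)
  if (mse > 0) {
    f_obs <- msr / mse
    df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
    fl <- f_obs / qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    f_obs <- Inf; ci <- c(icc, icc)
  }
  cls <- if (is.nan(icc)) NA_character_
         else if (icc < 0.5) "poor"
         else if (icc < 0.75) "moderate"
         else if (icc <= 0.9) "good"
         else "excellent"
  list(icc = icc, ci = ci, classification = cls, F = f_obs, msr = msr,
       mse = mse, n = n, k = k)
}

#' Standard error of measurement and minimal detectable change
#'
#' \eqn{SEM = SD \sqrt{1 - ICC}} and \eqn{MDC_{95} = 1.96 \sqrt{2}\, SEM}.
#'
#' @param scores_sd Between-target standard deviation of the scores (>= 0).
#' @param icc Intraclass correlation in \[0, 1\].
#' @return List with `sem` and `mdc`.
#' @examples
#' sem_mdc(0.079, 0)$mdc  # 0.219 after rounding to 3 decimals
#' @export
sem_mdc <- function(scores_sd, icc) {
  stopifnot(is_scalar_num(scores_sd), scores_sd >= 0, is_scalar_num(icc))
  if (icc > 1) stopf("icc must be <= 1")
  sem <- scores_sd * sqrt(1 - icc)
  list(sem = sem, mdc = 1.96 * sqrt(2) * sem)
}

#' Two-symmetry-level reliability analysis across participants
#'
#' Pools each participant's [reliability_groups] scores into targets x
#' raters tables and reports ICC(3,1), SEM and MDC95. Within-level groups (A,
#' D) contribute 3 repeated scores per cell and between-level groups (B, C)
#' 4, so the two families are analyzed at their own k and additionally
#' pooled into a single balanced table by truncating between-level cells to
#' their first 3 scores (fixed comparison order). SEM uses the pooled
#' between-target SD of the cell-mean scores.
#'
#' @param group_tables List (one per participant) of data frames from
#'   [reliability_groups].
#' @param alpha CI level is `1 - alpha`.
#' @return Object of class `reliability_result`: `icc` (pooled), `ci`,
#'   `classification`, `sem`, `mdc`, `icc_within`, `icc_between`, and the
#'   pooled measurement `table`.
#' @export
reliability_analysis <- function(group_tables, alpha = 0.05) {
  if (length(group_tables) < 2L) stopf("need >= 2 participants")
  cell_rows <- function(groups, kmax = NULL) {
    do.call(rbind, lapply(seq_along(group_tables), function(p) {
      gt <- group_tables[[p]]
      do.call(rbind, lapply(groups, function(g) {
        s <- gt$score[gt$group == g]
        if (!is.null(kmax)) s <- s[seq_len(kmax)]
        matrix(s, nrow = 1L,
               dimnames = list(sprintf("P%d.%s", p, g), NULL))
      }))
    }))
  }
  tab_within <- cell_rows(c("A", "D"))
  tab_between <- cell_rows(c("B", "C"))
  tab_pooled <- cell_rows(c("A", "B", "C", "D"), kmax = 3L)
  icc_w <- icc_consistency(tab_within, alpha)
  icc_b <- icc_consistency(tab_between, alpha)
  icc_p <- icc_consistency(tab_pooled, alpha)
  sd_pooled <- sd(rowMeans(tab_pooled))
  sm <- sem_mdc(sd_pooled, max(0, icc_p$icc))
  structure(list(icc = icc_p$icc, ci = icc_p$ci,
                 classification = icc_p$classification,
                 sem = sm$sem, mdc = sm$mdc,
                 icc_within = icc_w, icc_between = icc_b,
                 table = tab_pooled, alpha = alpha),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Two-level reliability: ICC(3,1) = %.3f [%.2f, %.2f] (%s), SEM = %.3f, MDC95 = %.3f\n",
              x$icc, x$ci[1L], x$ci[2L], x$classification, x$sem, x$mdc))
  cat(sprintf("  within-level family ICC = %.3f, between-level family ICC = %.3f\n",
              x$icc_within$icc, x$icc_between$icc))
  invisible(x)
}

# Resolve a location spec like "UL+UR" into segmented (possibly stacked)
# cycles for one recording.
cycles_for_location <- function(recording, location,
                                reference_foot = "right") {
  parts <- strsplit(location, "+", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  if (length(parts) == 1L) {
    segment_cycles(recording, reference_foot = reference_foot,
                   location = parts)
  } else if (length(parts) == 2L) {
    stack_bilateral(
      segment_cycles(recording, reference_foot = reference_foot,
                     location = parts[[1L]]),
      segment_cycles(recording, reference_foot = reference_foot,
                     location = parts[[2L]]))
  } else {
    stopf("location spec '%s' must name one sensor or a 'A+B' pair", location)
  }
}

#' End-to-end three-level validity study on a set of recordings
#'
#' Segments each recording at the requested sensor location(s), partitions
#' the cycles into three symmetry levels, trains per-level HMM ensembles,
#' builds the per-participant similarity grids, and runs
#' [validity_analysis].
#'
#' @param recordings Named list of recordings (see [generate_study]).
#' @param location Sensor spec: one of `"pelvis"`, `"UL"`, `"UR"`, `"LL"`,
#'   `"LR"`, or a stacked pair like `"UL+UR"`.
#' @param n_states,n_models,tau,kernel,base_seed,... Passed to
#'   [comparison_grid].
#' @param alpha Passed to [validity_analysis].
#' @return List with the `validity_result`, the per-participant `grids`, and
#'   the configuration.
#' @export
validity_study <- function(recordings, location = "UL+UR", n_states = 3L,
                           n_models = 10L, tau = 1, kernel = "rational",
                           base_seed = 1L, alpha = 0.05, ...) {
  grids <- lapply(seq_along(recordings), function(i) {
    cycles <- cycles_for_location(recordings[[i]], location)
    levels <- partition_three_levels(cycles)
    comparison_grid(levels, n_states = n_states, n_models = n_models,
                    tau = tau, kernel = kernel,
                    base_seed = derive_seed(base_seed, i), ...)
  })
  names(grids) <- names(recordings)
  list(result = validity_analysis(grids, alpha = alpha), grids = grids,
       config = list(location = location, n_states = n_states,
                     n_models = n_models, tau = tau, kernel = kernel,
                     base_seed = base_seed, alpha = alpha))
}

#' End-to-end two-level split-half reliability study
#'
#' For each recording: partitions cycles into two symmetry levels, splits
#' each into matched halves, trains four ensembles, computes the
#' [reliability_groups] scores, and pools everything into
#' [reliability_analysis].
#'
#' @inheritParams validity_study
#' @return List with the `reliability_result`, per-participant group tables,
#'   and the configuration.
#' @export
reliability_study <- function(recordings, location = "UL+UR", n_states = 3L,
                              n_models = 10L, tau = 1, kernel = "rational",
                              base_seed = 1L, alpha = 0.05, ...) {
  tables <- lapply(seq_along(recordings), function(i) {
    cycles <- cycles_for_location(recordings[[i]], location)
    halves <- partition_two_levels_split(cycles,
                                         seed = derive_seed(base_seed, i))
    ensembles <- lapply(seq_along(halves), function(l) {
      train_ensemble(halves[[l]], n_models = n_models, n_states = n_states,
                     base_seed = derive_seed(base_seed, i * 10L + l), ...)
    })
    names(ensembles) <- names(halves)
    reliability_groups(ensembles, tau = tau, kernel = kernel)
  })
  names(tables) <- names(recordings)
  list(result = reliability_analysis(tables, alpha = alpha),
       tables = tables,
       config = list(location = location, n_states = n_states,
                     n_models = n_models, tau = tau, kernel = kernel,
                     base_seed = base_seed, alpha = alpha))
}

#' Factorial sweep over HMM state counts and sensor configurations
#'
#' Runs the three-level validity analysis (and optionally the two-level
#' reliability analysis) for every combination of `states` and `locations`,
#' collecting the significant-difference count and ICC/SEM/MDC per
#' configuration.
#'
#' @param recordings Named list of recordings.
#' @param states Integer vector of HMM state counts (study default 2-5).
#' @param locations Character vector of sensor specs (study default: five
#'   single locations plus `"UL+UR"` and `"LL+LR"`).
#' @param reliability Also run the reliability paradigm per configuration.
#' @param n_models,tau,base_seed,alpha As in [validity_study].
#' @param out_dir Optional directory for results CSVs and a JSON manifest.
#' @return Data frame with one row per (location, states) configuration.
#' @export
run_state_sweep <- function(recordings, states = 2:5,
                            locations = c("pelvis", "UL", "UR", "LL", "LR",
                                          "UL+UR", "LL+LR"),
                            reliability = FALSE, n_models = 10L, tau = 1,
                            kernel = "rational", base_seed = 1L,
                            alpha = 0.05, out_dir = NULL) {
  conf <- expand.grid(location = locations, n_states = states,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(conf)), function(i) {
    loc <- conf$location[i]; ns <- conf$n_states[i]
    v <- validity_study(recordings, location = loc, n_states = ns,
                        n_models = n_models, tau = tau, kernel = kernel,
                        base_seed = derive_seed(base_seed, i), alpha = alpha)
    row <- data.frame(location = loc, n_states = ns,
                      n_significant = v$result$n_significant,
                      rm_anova_p = v$result$rm_anova$p)
    if (reliability) {
      r <- reliability_study(recordings, location = loc, n_states = ns,
                             n_models = n_models, tau = tau, kernel = kernel,
                             base_seed = derive_seed(base_seed, 1000L + i),
                             alpha = alpha)
      row$icc <- r$result$icc
      row$sem <- r$result$sem
      row$mdc <- r$result$mdc
    }
    row
  })
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(res, file.path(out_dir, "sweep_results.csv"), row.names = FALSE)
    jsonlite::write_json(list(states = states, locations = locations,
                              n_models = n_models, tau = tau,
                              base_seed = base_seed, alpha = alpha,
                              n_participants = length(recordings),
                              package_version =
                                as.character(utils::packageVersion("hmmsm"))),
                         file.path(out_dir, "sweep_manifest.json"),
                         auto_unbox = TRUE)
  }
  res
}
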