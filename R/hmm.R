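# Left-to-right Gaussian-emission HMMs trained by expectation-maximization
# on shuffled concatenations of gait cycles.

#' Build training sequences from a symmetry level
#'
#' Shuffles the level's gait cycles with the given seed, then concatenates
#' consecutive groups of `group_size` cycles along the time axis into D x T
#' training sequences. Leftover cycles (fewer than `group_size`) are dropped;
#' each cycle is used at most once per call.
#'
#' @param level A [symmetry_level] (or plain list of [gait_cycle]).
#' @param group_size Cycles per sequence (default 4).
#' @param seed Shuffle seed.
#' @return List of `training_sequence` objects (fields `data` = D x T
#'   matrix, `cycle_ids`).
#' @export
build_sequences <- function(level, group_size = 4L, seed = 1L) {
  if (!is_scalar_num(group_size) || group_size < 1L) {
    stopf("group_size must be >= 1")
  }
  cycles <- if (inherits(level, "symmetry_level")) level$cycles else level
  n <- length(cycles)
  if (n < group_size) stopf("level has %d cycles, fewer than group_size %d",
                            n, group_size)
  with_seed(seed, {
    ord <- sample.int(n)
    n_seq <- n %/% group_size
    lapply(seq_len(n_seq), function(s) {
      ids <- ord[(s - 1L) * group_size + seq_len(group_size)]
      structure(list(data = do.call(cbind,
                                    lapply(cycles[ids],
                                           function(c) c$channels)),
                     cycle_ids = vapply(cycles[ids], function(c) c$index,
                                        integer(1))),
                class = "training_sequence")
    })
  })
}

#' Left-to-right transition topology mask
#'
#' Allowed transitions are self-transitions and one-step forward moves. In
#' `"cyclic"` mode (the default) the last state additionally wraps to the
#' first, so a single state chain can traverse the several concatenated gait
#' cycles in one training sequence; `"strict"` is the terminating chain.
#'
#' @param n_states Number of states.
#' @param topology `"cyclic"` or `"strict"`.
#' @return n x n 0/1 mask matrix.
#' @export
lr_mask <- function(n_states, topology = c("cyclic", "strict")) {
  topology <- match.arg(topology)
  m <- diag(1, n_states)
  for (i in seq_len(n_states - 1L)) m[i, i + 1L] <- 1
  if (topology == "cyclic" && n_states > 1L) m[n_states, 1L] <- 1
  m
}

# Per-state Gaussian log-density of rows of X (T x D) given cached cholesky.
gauss_logdens <- function(X, mean, chol_cov) {
  d <- length(mean)
  z <- backsolve(chol_cov, t(X) - mean, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(chol_cov))) + colSums(z^2))
}

seq_data <- function(s) {
  m <- if (inherits(s, "training_sequence")) s$data else s
  if (!is.matrix(m)) stopf("sequences must be matrices or training_sequence")
  t(m)  # -> T x D
}

#' Fit a left-to-right Gaussian-emission HMM by expectation-maximization
#'
#' Full-covariance Gaussian emissions; the transition matrix is restricted to
#' the left-to-right [lr_mask] topology and the initial distribution is a
#' point mass on state 1 (training sequences start at a heel strike).
#' Parameters are initialized from a k-means partition of the pooled samples
#' with clusters ordered by their mean position within a sequence, then
#' refined by Baum-Welch until the absolute log-likelihood change falls
#' below `tol` or `max_iter` is reached. Ill-conditioned covariances are
#' regularized with a diagonal ridge of `cov_reg_scale` times each channel's
#' pooled variance (absolute floor 1e-6 for degenerate zero-variance input);
#' well-conditioned M steps are left exact so the EM log-likelihood is
#' monotone.
#'
#' @param sequences List of training sequences (D x T matrices or
#'   `training_sequence` objects).
#' @param n_states Number of hidden states (>= 2; the study sweep uses 2-5).
#' @param topology Passed to [lr_mask].
#' @param max_iter,tol EM stopping rule.
#' @param cov_reg_scale Relative covariance ridge.
#' @param seed Seed for the k-means initialization.
#' @return Object of class `gaussian_hmm`: `n_states`, `A`, `mask`,
#'   `emissions` (list of [gaussian_emission]), `init`, `loglik_trace`,
#'   `converged`, `seed`, `dim`.
#' @export
fit_hmm <- function(sequences, n_states, topology = c("cyclic", "strict"),
                    max_iter = 100L, tol = 1e-4, cov_reg_scale = 1e-6,
                    seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(is_scalar_num(n_states), n_states >= 2L)
  n_states <- as.integer(n_states)
  seqs <- lapply(sequences, seq_data)
  d <- ncol(seqs[[1L]])
  if (any(vapply(seqs, ncol, integer(1)) != d)) {
    stopf("sequences have inconsistent channel counts")
  }
  total_t <- sum(vapply(seqs, nrow, integer(1)))
  if (total_t < n_states * (d + 1L)) {
    stopf("too few samples (%d) for %d states in %d dimensions", total_t,
          n_states, d)
  }
  pooled <- do.call(rbind, seqs)
  var_vec <- apply(pooled, 2L, var)
  mean_var <- mean(var_vec)
  # per-channel relative ridge: channels mix units (deg/s vs g), so a scalar
  # ridge on the mean variance would swamp the low-amplitude channels
  cov_reg <- ifelse(var_vec > 0, cov_reg_scale * var_vec, 1e-6)
  mask <- lr_mask(n_states, topology)
  pi0 <- c(1, numeric(n_states - 1L))

  # --- initialization: k-means on pooled samples, states ordered by mean
  # within-sequence position so state 1 sits near the heel strike
  init <- with_seed(seed, {
    frac <- unlist(lapply(seqs, function(s) seq_len(nrow(s)) / nrow(s)))
    keep <- if (nrow(pooled) > 5000L) sample.int(nrow(pooled), 5000L) else
      seq_len(nrow(pooled))
    distinct <- nrow(unique(pooled[keep, , drop = FALSE]))
    if (distinct >= n_states) {
      km <- suppressWarnings(kmeans(pooled[keep, , drop = FALSE], n_states,
                                    nstart = 3L, iter.max = 25L))
      cl <- km$cluster
    } else {
      cl <- cut(frac[keep], n_states, labels = FALSE)
    }
    ord <- order(vapply(seq_len(n_states),
                        function(k) mean(frac[keep][cl == k]), numeric(1)))
    lapply(seq_len(n_states), function(k) {
      rows <- pooled[keep, , drop = FALSE][cl == ord[k], , drop = FALSE]
      mu <- if (nrow(rows)) colMeans(rows) else colMeans(pooled)
      sig <- if (nrow(rows) > d) stats::cov(rows) else
        diag(pmax(var_vec, 1e-6), nrow = d)
      gaussian_emission(mu, sig + diag(cov_reg, nrow = d))
    })
  })
  emissions <- init
  A <- mask / rowSums(mask)

  safe_chol <- function(sig) {
    r <- tryCatch(chol(sig), error = function(e) NULL)
    jitter <- mean(cov_reg)
    while (is.null(r)) {
      jitter <- max(jitter * 10, 1e-8)
      r <- tryCatch(chol(sig + diag(jitter, nrow(sig))),
                    error = function(e) NULL)
      if (jitter > 1e6 * (mean_var + 1)) stopf("covariance irreparably singular")
    }
    r
  }

  lens <- vapply(seqs, nrow, integer(1))
  pooled_t <- t(pooled)
  loglik_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # cache per-state cholesky-derived pieces for the batched E pass
    mu_mat <- do.call(rbind, lapply(emissions, function(e) e$mean))
    chols <- lapply(emissions, function(e) safe_chol(e$cov))
    minv <- do.call(rbind, lapply(chols, function(r) {
      t(backsolve(r, diag(d)))  # lower-triangular t(R^{-1})
    }))
    logdet <- vapply(chols, function(r) 2 * sum(log(diag(r))), numeric(1))
    es <- .hmm_em_pass(pooled_t, lens, mu_mat, minv, logdet, A, pi0)
    ll <- es$loglik
    loglik_trace <- c(loglik_trace, ll)
    if (iter > 1L && abs(ll - loglik_trace[iter - 1L]) < tol) {
      converged <- TRUE
    }
    # M step
    denom <- pmax(es$g_sum, 1e-10)
    mu_new <- es$mu_acc / denom
    emissions <- lapply(seq_len(n_states), function(k) {
      m2 <- matrix(es$S_acc[k, , ], d, d)
      m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]  # mirror upper triangle
      sig <- m2 / denom[k] - tcrossprod(mu_new[k, ])
      sig <- (sig + t(sig)) / 2
      # ridge only when needed: an unconditional ridge would break the
      # exact EM monotonicity guarantee
      ill <- any(diag(sig) < cov_reg) ||
        is.null(tryCatch(chol(sig), error = function(e) NULL))
      if (ill) sig <- sig + diag(cov_reg, nrow = d)
      gaussian_emission(mu_new[k, ], sig)
    })
    a_new <- es$xi * mask
    rs <- rowSums(a_new)
    zero_rows <- rs <= 0
    if (any(zero_rows)) {
      a_new[zero_rows, ] <- mask[zero_rows, , drop = FALSE]
      rs <- rowSums(a_new)
    }
    A <- a_new / rs
    if (converged) break
  }
  if (!converged) {
    # model returned anyway; flagged for the caller
    attr(loglik_trace, "note") <- "max_iter reached before tolerance"
  }
  structure(list(n_states = n_states, A = A, mask = mask,
                 emissions = emissions, init = pi0,
                 loglik_trace = loglik_trace, converged = converged,
                 topology = topology, seed = as.integer(seed), dim = d),
            class = "gaussian_hmm")
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("gaussian_hmm: %d states (%s left-to-right), %d channels, %s after %d EM iterations (loglik %.2f)\n",
              x$n_states, x$topology, x$dim,
              if (x$converged) "converged" else "not converged",
              length(x$loglik_trace), tail(x$loglik_trace, 1L)))
  invisible(x)
}

#' Train an ensemble of HMMs on one symmetry level
#'
#' Trains `n_models` HMMs, each on training sequences rebuilt from a fresh
#' shuffle of the level's gait cycles (seed derived from `base_seed` and the
#' model index), mirroring the ten-model-per-level protocol with sequence
#' order reshuffled between training sessions.
#'
#' @param level A [symmetry_level].
#' @param n_models Ensemble size (default 10).
#' @param n_states,topology,group_size,max_iter,tol,cov_reg_scale Passed to
#'   [build_sequences] and [fit_hmm].
#' @param base_seed Master seed; the ensemble is reproducible from it.
#' @return Object of class `hmm_ensemble` (fields `models`, `label`,
#'   `n_states`, `base_seed`).
#' @export
train_ensemble <- function(level, n_models = 10L, n_states = 3L,
                           topology = "cyclic", group_size = 4L,
                           max_iter = 100L, tol = 1e-4,
                           cov_reg_scale = 1e-6, base_seed = 1L) {
  stopifnot(n_models >= 1L)
  models <- lapply(seq_len(n_models), function(m) {
    sd_m <- derive_seed(base_seed, m)
    seqs <- build_sequences(level, group_size = group_size, seed = sd_m)
    fit_hmm(seqs, n_states = n_states, topology = topology,
            max_iter = max_iter, tol = tol, cov_reg_scale = cov_reg_scale,
            seed = sd_m)
  })
  structure(list(models = models,
                 label = if (inherits(level, "symmetry_level")) level$label
                         else NA_character_,
                 n_states = as.integer(n_states),
                 base_seed = as.integer(base_seed)),
            class = "hmm_ensemble")
}

#' @export
print.hmm_ensemble <- function(x, ...) {
  cat(sprintf("hmm_ensemble '%s': %d models x %d states\n", x$label,
              length(x$models), x$n_states))
  invisible(x)
}

#' Sample observations from a Gaussian-emission HMM
#'
#' Used for parameter-recovery checks: draws a state path from the
#' transition matrix and initial distribution, then Gaussian observations.
#'
#' @param hmm A [gaussian_hmm] (any object with `A`, `init`, `emissions`).
#' @param n_obs Sequence length.
#' @param seed RNG seed.
#' @return List with `data` (D x T matrix) and `states` (length-T path).
#' @export
simulate_hmm <- function(hmm, n_obs, seed = 1L) {
  with_seed(seed, {
    n <- length(hmm$emissions)
    states <- integer(n_obs)
    states[1L] <- sample.int(n, 1L, prob = hmm$init)
    for (t in seq_len(n_obs - 1L)) {
      states[t + 1L] <- sample.int(n, 1L, prob = hmm$A[states[t], ])
    }
    d <- length(hmm$emissions[[1L]]$mean)
    chols <- lapply(hmm$emissions, function(e) chol(e$cov))
    obs <- vapply(seq_len(n_obs), function(t) {
      e <- hmm$emissions[[states[t]]]
      e$mean + drop(t(chols[[states[t]]]) %*% rnorm(d))
    }, numeric(d))
    list(data = matrix(obs, nrow = d), states = states)
  })
}

#' Serialize / restore a trained HMM as JSON
#'
#' @param hmm A [gaussian_hmm].
#' @param file Path to write (or read).
#' @return `hmm_to_json` invisibly returns the file; `hmm_from_json` returns
#'   the restored [gaussian_hmm].
#' @export
hmm_to_json <- function(hmm, file) {
  payload <- list(n_states = hmm$n_states, A = hmm$A, mask = hmm$mask,
                  init = hmm$init, topology = hmm$topology, seed = hmm$seed,
                  dim = hmm$dim, converged = hmm$converged,
                  loglik_trace = as.numeric(hmm$loglik_trace),
                  emissions = lapply(hmm$emissions, function(e) {
                    list(mean = e$mean, cov = e$cov)
                  }))
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(file)
}

#' @rdname hmm_to_json
#' @export
hmm_from_json <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = FALSE)
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r)
    as.numeric(unlist(r))))
  structure(list(n_states = as.integer(p$n_states), A = as_mat(p$A),
                 mask = as_mat(p$mask),
                 emissions = lapply(p$emissions, function(e) {
                   gaussian_emission(as.numeric(unlist(e$mean)),
                                     as_mat(e$cov))
                 }),
                 init = as.numeric(unlist(p$init)),
                 loglik_trace = as.numeric(unlist(p$loglik_trace)),
                 converged = isTRUE(p$converged), topology = p$topology,
                 seed = as.integer(p$seed), dim = as.integer(p$dim)),
            class = "gaussian_hmm")
}
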