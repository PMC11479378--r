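# Shared fixtures: everything is generated in code at test time.

# Small recording with both upper-leg sensors; constant or swept STSR.
test_recording <- function(stsr = 0.9, n_cycles = 40, noise_sd = 0.03,
                           seed = 7L, locations = c("UL", "UR"),
                           turn_every = 0L, cadence_sd = 2) {
  generate_recording(
    gait_profile(cadence_mean = 105, cadence_sd = cadence_sd,
                 stsr_schedule = stsr, n_cycles = n_cycles,
                 noise_sd = noise_sd, turn_every = turn_every, seed = seed),
    locations = locations)
}

# Stacked 12-channel cycles from a recording.
test_cycles_12 <- function(rec) {
  stack_bilateral(segment_cycles(rec, location = "UL"),
                  segment_cycles(rec, location = "UR"))
}

# Synthetic gait cycles with prescribed STSR values and tiny dummy signals;
# fast stand-ins for partition tests that do not need realistic waveforms.
fake_cycles <- function(stsr_values, is_turn = FALSE, t_c = 4L) {
  is_turn <- rep_len(is_turn, length(stsr_values))
  lapply(seq_along(stsr_values), function(i) {
    s <- stsr_values[i]
    gait_cycle(matrix(seq_len(2L * t_c), nrow = 2L),
               stance_right = 0.6 * s, stance_left = 0.6,
               is_turn = is_turn[i], index = i)
  })
}

# Hand-built two-state Gaussian HMM (no training) for similarity tests.
toy_hmm <- function(means, vars, a_self = 0.9) {
  n <- length(means)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a[i, i] <- a_self
    a[i, if (i < n) i + 1L else 1L] <- 1 - a_self
  }
  structure(list(n_states = n, A = a, mask = lr_mask(n),
                 emissions = Map(gaussian_emission, means, vars),
                 init = c(1, numeric(n - 1L)), loglik_trace = numeric(0),
                 converged = TRUE, topology = "cyclic", seed = 0L,
                 dim = length(means[[1L]])),
            class = "gaussian_hmm")
}

toy_ensemble <- function(models, label = "SL1") {
  structure(list(models = models, label = label,
                 n_states = if (length(models)) models[[1L]]$n_states else 0L,
                 base_seed = 0L),
            class = "hmm_ensemble")
}

# Random SPD covariance matrix.
random_spd <- function(d, scale = 1) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) / d * scale + diag(0.1 * scale, d)
}

# Brute-force HMM posterior quantities by enumerating all state paths.
# Independent oracle for the scaled forward-backward implementation.
enumerate_fb <- function(logB, A, pi) {
  t_len <- nrow(logB); n <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), t_len)))
  logw <- apply(paths, 1L, function(z) {
    lw <- log(pi[z[1L]]) + logB[1L, z[1L]]
    for (t in seq_len(t_len - 1L)) {
      lw <- lw + log(A[z[t], z[t + 1L]]) + logB[t + 1L, z[t + 1L]]
    }
    lw
  })
  m <- max(logw)
  w <- exp(logw - m)
  loglik <- m + log(sum(w))
  w <- w / sum(w)
  gamma <- matrix(0, t_len, n)
  xi <- matrix(0, n, n)
  for (p in seq_len(nrow(paths))) {
    z <- paths[p, ]
    for (t in seq_len(t_len)) gamma[t, z[t]] <- gamma[t, z[t]] + w[p]
    for (t in seq_len(t_len - 1L)) {
      xi[z[t], z[t + 1L]] <- xi[z[t], z[t + 1L]] + w[p]
    }
  }
  list(gamma = gamma, xi = xi, loglik = loglik)
}
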