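# HMM-SM: similarity between two Gaussian-emission HMMs from the sparsity of
# their state-correspondence matrix.

#' Symmetric Kullback-Leibler divergence between two multivariate Gaussians
#'
#' Computes the arithmetic mean of the two directed KL divergences,
#' \eqn{\frac{1}{2}[KL(g_1 \| g_2) + KL(g_2 \| g_1)]}, using the closed form
#' for multivariate normal distributions. The mean (rather than the sum) keeps
#' the default correspondence temperature `tau = 1` interpretable; the summed
#' variant is recoverable by doubling `tau`.
#'
#' @param g1,g2 Gaussian emissions: lists with elements `mean` (length-D
#'   numeric) and `cov` (D x D symmetric positive-definite matrix). Scalars
#'   are accepted for D = 1.
#' @return Non-negative scalar divergence; exactly 0 for identical Gaussians.
#' @examples
#' symmetric_kl(gaussian_emission(0, 1), gaussian_emission(1, 1))  # 0.5
#' @export
symmetric_kl <- function(g1, g2) {
  g1 <- as_gaussian_emission(g1)
  g2 <- as_gaussian_emission(g2)
  d <- length(g1$mean)
  if (length(g2$mean) != d) {
    stopf("emission dimensions differ (%d vs %d)", d, length(g2$mean))
  }
  kl_dir <- function(p, q, label) {
    cq <- tryCatch(chol(q$cov), error = function(e) NULL)
    if (is.null(cq)) stopf("covariance of emission '%s' is not SPD", label)
    cp <- tryCatch(chol(p$cov), error = function(e) NULL)
    if (is.null(cp)) stopf("covariance of emission '%s' is not SPD", label)
    iq <- chol2inv(cq)
    dm <- q$mean - p$mean
    tr <- sum(iq * p$cov)  # tr(Sigma_q^{-1} Sigma_p)
    maha <- drop(crossprod(dm, iq %*% dm))
    logdet_q <- 2 * sum(log(diag(cq)))
    logdet_p <- 2 * sum(log(diag(cp)))
    0.5 * (tr + maha - d + logdet_q - logdet_p)
  }
  max(0, 0.5 * (kl_dir(g1, g2, "g2") + kl_dir(g2, g1, "g1")))
}

#' Construct a Gaussian emission
#'
#' @param mean Numeric mean vector (length D).
#' @param cov D x D covariance matrix, or a scalar/vector of variances.
#' @return An object of class `gaussian_emission`.
#' @export
gaussian_emission <- function(mean, cov) {
  mean <- as.numeric(mean)
  d <- length(mean)
  if (!is.matrix(cov)) {
    cov <- diag(rep_len(as.numeric(cov), d), nrow = d)
  }
  if (!all(dim(cov) == d)) stopf("cov must be %d x %d", d, d)
  if (any(!is.finite(mean)) || any(!is.finite(cov))) {
    stopf("non-finite emission parameters")
  }
  structure(list(mean = mean, cov = (cov + t(cov)) / 2),
            class = "gaussian_emission")
}

as_gaussian_emission <- function(x) {
  if (inherits(x, "gaussian_emission")) return(x)
  if (is.list(x) && !is.null(x$mean) && !is.null(x$cov)) {
    return(gaussian_emission(x$mean, x$cov))
  }
  stopf("cannot interpret object of class '%s' as a Gaussian emission",
        paste(class(x), collapse = "/"))
}

#' State-correspondence matrix between two HMMs
#'
#' Element \eqn{q_{ij} = \exp(-\tau \, d_{sKL}(b_a[i], b_b[j]))} measures how
#' similar state i of the first model is to state j of the second, mapping the
#' symmetric KL divergence of their Gaussian emissions into (0, 1]. Identical
#' emissions give exactly 1.
#'
#' @param hmm_a,hmm_b Trained [gaussian_hmm] objects (or plain lists with an
#'   `emissions` element) with matching emission dimension.
#' @param tau Positive temperature of the divergence-to-similarity map.
#' @param kernel Divergence-to-similarity map. `"exponential"` is
#'   \eqn{q = e^{-\tau d}}, the default for the low-level contract;
#'   `"rational"` is \eqn{q = 1/(1 + \tau d)}, which responds over the full
#'   dynamic range of gait-model divergences (see the methods vignette:
#'   between-state divergences of trained 12-channel gait HMMs are O(100),
#'   which drives every exponential off-diagonal to exactly 0 in double
#'   precision and saturates the sparsity score at 1).
#' @return M x M' matrix of class `correspondence_matrix` (M = states of
#'   `hmm_a`, M' = states of `hmm_b`).
#' @export
correspondence_matrix <- function(hmm_a, hmm_b, tau = 1,
                                  kernel = c("exponential", "rational")) {
  stopifnot(is_scalar_num(tau), tau > 0)
  kernel <- match.arg(kernel)
  ea <- emissions_of(hmm_a)
  eb <- emissions_of(hmm_b)
  q <- matrix(NA_real_, length(ea), length(eb))
  for (i in seq_along(ea)) {
    for (j in seq_along(eb)) {
      d <- symmetric_kl(ea[[i]], eb[[j]])
      q[i, j] <- if (kernel == "exponential") exp(-tau * d) else
        1 / (1 + tau * d)
    }
  }
  structure(q, class = c("correspondence_matrix", "matrix"))
}

emissions_of <- function(x) {
  if (inherits(x, "gaussian_hmm")) return(x$emissions)
  if (is.list(x) && !is.null(x$emissions)) {
    return(lapply(x$emissions, as_gaussian_emission))
  }
  if (is.list(x) && all(vapply(x, function(e) is.list(e) &&
                               !is.null(e$mean), logical(1)))) {
    return(lapply(x, as_gaussian_emission))
  }
  stopf("expected a gaussian_hmm or a list of emissions")
}

#' Normalized Gini sparsity index
#'
#' The Gini sparsity of the magnitude profile of `u` (Hurley-Rickard form on
#' the ascending-sorted vector), rescaled by its maximum attainable value
#' \eqn{1 - 1/N} so that a uniform vector scores exactly 0 and a one-hot
#' vector exactly 1. Scale-invariant: `H(c*u) == H(u)` for any c > 0.
#'
#' @param u Non-negative numeric vector, length >= 2, not all zeros.
#' @return Sparsity in \[0, 1\].
#' @examples
#' normalized_gini(c(0.25, 0.25, 0.25, 0.25))  # 0
#' normalized_gini(c(1, 0, 0, 0))              # 1
#' normalized_gini(c(3, 1))                    # 0.5
#' @export
normalized_gini <- function(u) {
  u <- as.numeric(u)
  n <- length(u)
  if (n < 2L) stopf("need at least 2 entries, got %d", n)
  if (any(!is.finite(u))) stopf("non-finite entries in u")
  if (any(u < 0)) stopf("negative entries in u")
  s <- sum(u)
  if (s <= 0) stopf("all-zero vector has undefined sparsity")
  us <- sort(u)
  k <- seq_len(n)
  gini <- 1 - 2 * sum((us / s) * ((n - k + 0.5) / n))
  gini / (1 - 1 / n)
}

#' HMM similarity measure (HMM-SM)
#'
#' Similarity between two Gaussian-emission HMMs based on the sparsity of
#' their state-correspondence matrix Q:
#' \deqn{S(\lambda_a \| \lambda_b) = \frac{1}{2}\left[\frac{1}{M}\sum_i
#'   H(r_i) + \frac{1}{M'}\sum_j H(c_j)\right]}
#' where \eqn{r_i}, \eqn{c_j} are the rows and columns of Q and H is the
#' [normalized_gini] index. Two models whose states match one-to-one with
#' well-separated emissions approach S = 1; models with identical emissions in
#' every state give a uniform Q and S = 0. Only the emissions enter Q; the
#' transition matrix influences S only through training.
#'
#' @inheritParams correspondence_matrix
#' @return Object of class `hmm_similarity`: list with `value` in \[0, 1\],
#'   `row_sparsity`, `col_sparsity`, and the `q` matrix.
#' @export
hmm_sm <- function(hmm_a, hmm_b, tau = 1,
                   kernel = c("exponential", "rational")) {
  q <- correspondence_matrix(hmm_a, hmm_b, tau = tau, kernel = kernel)
  hmm_sm_from_q(q)
}

hmm_sm_from_q <- function(q) {
  row_h <- apply(q, 1L, normalized_gini)
  col_h <- apply(q, 2L, normalized_gini)
  structure(list(value = 0.5 * (mean(row_h) + mean(col_h)),
                 row_sparsity = mean(row_h), col_sparsity = mean(col_h),
                 q = q),
            class = "hmm_similarity")
}

#' @export
print.hmm_similarity <- function(x, ...) {
  cat(sprintf("HMM-SM similarity: %.4f (row sparsity %.4f, col sparsity %.4f, Q %d x %d)\n",
              x$value, x$row_sparsity, x$col_sparsity, nrow(x$q), ncol(x$q)))
  invisible(x)
}

#' Mean HMM-SM between (or within) ensembles of trained HMMs
#'
#' Between two distinct ensembles, averages the pair score over all
#' cross-model pairs (10 x 10 = 100 for the default ensemble size). Within a
#' single ensemble (pass the same object twice, or omit `ens_b`), averages
#' over all unordered distinct pairs (45 for 10 models); a model is never
#' compared with itself.
#'
#' @param ens_a,ens_b [hmm_ensemble] objects (or plain lists of
#'   [gaussian_hmm]); `ens_b` defaults to `ens_a` (within-ensemble mode).
#' @param tau,kernel Correspondence map, passed to [hmm_sm].
#' @return Object of class `ensemble_similarity`: list with mean `value`,
#'   per-pair `scores` data frame, `within` flag and the two ensemble labels.
#' @export
ensemble_similarity <- function(ens_a, ens_b = ens_a, tau = 1,
                                kernel = c("exponential", "rational")) {
  kernel <- match.arg(kernel)
  ma <- models_of(ens_a); mb <- models_of(ens_b)
  if (length(ma) == 0L || length(mb) == 0L) stopf("empty ensemble")
  within <- identical_ensembles(ens_a, ens_b)
  if (within) {
    idx <- which(upper.tri(matrix(0, length(ma), length(ma))), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_along(ma), col = seq_along(mb)))
  }
  scores <- vapply(seq_len(nrow(idx)), function(k) {
    hmm_sm(ma[[idx[k, 1L]]], mb[[idx[k, 2L]]], tau = tau,
           kernel = kernel)$value
  }, numeric(1))
  structure(list(value = mean(scores),
                 scores = data.frame(pair_i = idx[, 1L], pair_j = idx[, 2L],
                                     score = scores),
                 within = within,
                 label_a = label_of(ens_a), label_b = label_of(ens_b)),
            class = "ensemble_similarity")
}

models_of <- function(x) {
  if (inherits(x, "hmm_ensemble")) return(x$models)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "gaussian_hmm"))) {
    return(x)
  }
  stopf("expected an hmm_ensemble or list of gaussian_hmm models")
}

label_of <- function(x) {
  if (inherits(x, "hmm_ensemble") && !is.null(x$label)) x$label else NA_character_
}

identical_ensembles <- function(a, b) {
  isTRUE(all.equal(models_of(a), models_of(b), tolerance = 0))
}

#' @export
print.ensemble_similarity <- function(x, ...) {
  mode <- if (x$within) "within-ensemble" else "between-ensemble"
  cat(sprintf("Mean HMM-SM (%s, %d pairs): %.4f\n", mode, nrow(x$scores),
              x$value))
  invisible(x)
}

#' Write all pairwise ensemble comparisons to CSV
#'
#' @param comparisons Named list of `ensemble_similarity` objects.
#' @param pair_file,summary_file Output CSV paths; either may be `NULL`.
#' @return Invisibly, the summary data frame of mean scores per level pair.
#' @export
write_comparisons <- function(comparisons, pair_file = NULL,
                              summary_file = NULL) {
  pairs <- do.call(rbind, lapply(comparisons, function(cmp) {
    cbind(data.frame(level_a = cmp$label_a, level_b = cmp$label_b),
          cmp$scores)
  }))
  summary <- do.call(rbind, lapply(comparisons, function(cmp) {
    data.frame(level_a = cmp$label_a, level_b = cmp$label_b,
               n_pairs = nrow(cmp$scores), mean_score = cmp$value)
  }))
  rownames(pairs) <- rownames(summary) <- NULL
  if (!is.null(pair_file)) write.csv(pairs, pair_file, row.names = FALSE)
  if (!is.null(summary_file)) write.csv(summary, summary_file, row.names = FALSE)
  invisible(summary)
}
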