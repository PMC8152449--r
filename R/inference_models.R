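#' Minimum log2 fold-change
#'
#' Summarizes the evidence for differential expression between two
#' posterior (or approximate-posterior) sample sets: per transcript,
#' `delta` is the largest effect size with 90% posterior probability that
#' the absolute log2 fold change exceeds it, i.e. the 10th percentile of
#' `|log2(x_a / x_b)|` over draws paired by index. `direction` is the sign
#' of the median log2 ratio.
#'
#' @param samples_a,samples_b `draws x n` matrices of expression draws with
#'   equal draw counts (paired by draw index).
#' @return data.frame with columns `delta` (nonnegative, bits) and
#'   `direction` (-1, 0 or 1).
#' @export
min_log2_fc <- function(samples_a, samples_b) {
  if (!is.matrix(samples_a) || !is.matrix(samples_b) ||
      nrow(samples_a) == 0L || nrow(samples_b) == 0L) {
    stop("min_log2_fc: need nonempty sample matrices")
  }
  if (!all(dim(samples_a) == dim(samples_b))) {
    stop("min_log2_fc: sample sets must have matching dimensions")
  }
  lr <- log2(samples_a) - log2(samples_b)
  delta <- apply(abs(lr), 2L, stats::quantile, probs = 0.1, names = FALSE)
  direction <- sign(apply(lr, 2L, stats::median))
  data.frame(delta = delta, direction = direction)
}

#' Bayesian regression for differential transcript expression
#'
#' Fits, per transcript, a log-normal observation model with a linear
#' predictor: `log2 x = design %*% beta + noise`, `beta ~ Normal(0, 5^2)`,
#' residual scale `tau ~ half-Normal(1)`, where the per-sample latent
#' expression `x` is integrated over each sample's approximate likelihood.
#' Inference is a multiple-imputation Gibbs sampler: every sweep imputes
#' `x` for each sample from its fitted approximation, then draws `beta`
#' from its conjugate normal conditional and `tau` from a grid-evaluated
#' half-Normal conditional. Uncertainty in read assignment therefore
#' propagates into the effect-size posteriors.
#'
#' @param approxes list of `approx_likelihood` objects, one per sample.
#' @param design numeric `samples x covariates` matrix (include an
#'   intercept column explicitly); must have full column rank.
#' @param iterations,burn Gibbs sweeps in total and discarded.
#' @param seed integer seed.
#' @param coef index of the effect covariate summarized by `tail_prob`
#'   (default the last column).
#' @param effect_threshold effect size (bits) for the tail probability
#'   `P(|beta_coef| > effect_threshold)`.
#' @return an object of class `regression_fit`: list with `beta_mean`,
#'   `beta_sd` (covariates x transcripts), `tail_prob` and `delta_mean`
#'   (posterior mean effect) for the chosen covariate, `tau_mean`,
#'   `design`, `transcript_ids`.
#' @export
regression_fit <- function(approxes, design, iterations = 400L,
                           burn = 100L, seed = 1L,
                           coef = ncol(design), effect_threshold = 0.5) {
  design <- as.matrix(design)
  k <- nrow(design)
  p <- ncol(design)
  if (length(approxes) != k) {
    stop("regression_fit: need one approximation per design row")
  }
  if (qr(design)$rank < p) {
    stop("regression_fit: design matrix is rank deficient")
  }
  n <- approxes[[1L]]$n
  set.seed(seed)
  xtx <- crossprod(design)
  prior_prec <- diag(1 / 25, p)
  tau_grid <- exp(seq(log(0.01), log(4), length.out = 80L))
  log_tau_prior <- -tau_grid^2 / 2 + log(tau_grid)  # half-normal, log grid
  tau <- rep(1, n)
  beta <- matrix(0, nrow = p, ncol = n)
  keep <- iterations - burn
  eff_draws <- matrix(0, nrow = keep, ncol = n)
  beta_sum <- matrix(0, nrow = p, ncol = n)
  beta_sq <- matrix(0, nrow = p, ncol = n)
  tau_sum <- numeric(n)
  for (it in seq_len(iterations)) {
    ymat <- matrix(0, nrow = k, ncol = n)
    for (s in seq_len(k)) {
      ymat[s, ] <- log2(approx_sample(approxes[[s]], 1L))
    }
    xty <- crossprod(design, ymat)            # p x n
    for (j in seq_len(n)) {
      prec <- xtx / tau[j]^2 + prior_prec
      ch <- chol(prec)
      mean_j <- backsolve(ch, forwardsolve(t(ch), xty[, j] / tau[j]^2))
      beta[, j] <- mean_j + backsolve(ch, stats::rnorm(p))
    }
    resid <- ymat - design %*% beta
    ssr <- colSums(resid^2)
    lp <- -k * log(tau_grid)
    logw <- outer(lp, rep(1, n)) -
      outer(1 / (2 * tau_grid^2), ssr) + log_tau_prior
    logw <- sweep(logw, 2L, apply(logw, 2L, max))
    wts <- exp(logw)
    wts <- sweep(wts, 2L, colSums(wts), `/`)
    u <- stats::runif(n)
    idx <- colSums(apply(wts, 2L, cumsum) < rep(u, each = length(tau_grid))) + 1L
    tau <- tau_grid[pmin(idx, length(tau_grid))]
    if (it > burn) {
      r <- it - burn
      eff_draws[r, ] <- beta[coef, ]
      beta_sum <- beta_sum + beta
      beta_sq <- beta_sq + beta^2
      tau_sum <- tau_sum + tau
    }
  }
  beta_mean <- beta_sum / keep
  beta_sd <- sqrt(pmax(beta_sq / keep - beta_mean^2, 0))
  structure(
    list(beta_mean = beta_mean, beta_sd = beta_sd,
         delta_mean = beta_mean[coef, ],
         tail_prob = colMeans(abs(eff_draws) > effect_threshold),
         tau_mean = tau_sum / keep, design = design,
         transcript_ids = approxes[[1L]]$transcript_ids),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "regression_fit: %d transcripts, %d samples, %d covariates\n",
    ncol(x$beta_mean), nrow(x$design), nrow(x$beta_mean)))
  invisible(x)
}

#' Convert expression proportions to TPM
#'
#' Transcripts per million: expression divided by effective length,
#' renormalized to sum to 1e6.
#'
#' @param x expression vector or `draws x n` matrix on the simplex.
#' @param effective_lengths positive per-transcript effective lengths.
#' @return TPM values with the shape of `x`.
#' @export
tpm_from_expression <- function(x, effective_lengths) {
  if (is.matrix(x)) {
    r <- sweep(x, 2L, effective_lengths, `/`)
    sweep(r, 1L, rowSums(r), `/`) * 1e6
  } else {
    r <- x / effective_lengths
    r / sum(r) * 1e6
  }
}

#' Posterior-averaged Spearman coexpression
#'
#' For each draw index, converts every sample's expression draw to TPM,
#' adds a pseudocount, computes the transcript-by-transcript Spearman
#' correlation across samples (average ranks for ties), and returns the
#' element-wise average over draws. Passing a single point estimate per
#' sample (one-row matrices) reduces to plain point-estimate Spearman
#' correlation. Transcripts with zero variance across samples in a draw
#' get correlation 0 for that draw (diagonal stays 1).
#'
#' @param sample_sets list (one element per sample) of `draws x n`
#'   expression matrices.
#' @param draws number of draw indices to average over (default 20, capped
#'   at the available draws).
#' @param pseudocount_tpm pseudocount added on the TPM scale (default 0.1).
#' @param effective_lengths per-transcript effective lengths.
#' @return an `n x n` symmetric correlation matrix with unit diagonal.
#' @export
coexpression_spearman <- function(sample_sets, draws = 20L,
                                  pseudocount_tpm = 0.1,
                                  effective_lengths) {
  k <- length(sample_sets)
  if (k < 3L) stop("coexpression_spearman: need at least 3 samples")
  sample_sets <- lapply(sample_sets, function(m) {
    if (!is.matrix(m)) matrix(m, nrow = 1L) else m
  })
  avail <- min(vapply(sample_sets, nrow, integer(1L)))
  draws <- min(draws, avail)
  n <- ncol(sample_sets[[1L]])
  acc <- matrix(0, n, n)
  for (d in seq_len(draws)) {
    m <- t(vapply(sample_sets, function(ss) {
      tpm_from_expression(ss[d, ], effective_lengths)
    }, numeric(n))) + pseudocount_tpm
    cc <- suppressWarnings(stats::cor(m, method = "spearman"))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    acc <- acc + cc
  }
  acc / draws
}
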