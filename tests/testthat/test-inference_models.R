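test_that("minimum log2 fold-change matches its quantile definition", {
  set.seed(71)
  a <- matrix(rbeta(3000, 2, 5), ncol = 3) / 4
  expect_true(all(min_log2_fc(a, a)$delta == 0))

  # constant twofold ratio: exactly 1 bit
  b <- a / 2
  b <- cbind(b, 1 - rowSums(b))
  a2 <- cbind(a, 1 - rowSums(a))
  res <- min_log2_fc(a2, b)
  expect_equal(res$delta[1:3], rep(1, 3), tolerance = 1e-12)
  expect_equal(res$direction[1:3], rep(1, 3))

  # Gaussian log2 ratios: delta -> 2 + 0.5 * qnorm(0.1)
  lr <- rnorm(10000, 2, 0.5)
  xa <- matrix(2^lr, ncol = 1)
  xb <- matrix(1, nrow = 10000, ncol = 1)
  d <- min_log2_fc(xa, xb)$delta
  th <- 2 + 0.5 * qnorm(0.1)
  expect_lt(abs(d - th), 3 * 0.5 / sqrt(10000) / dnorm(qnorm(0.1)) * 0.3 + 0.03)

  # monotonicity: doubling one transcript's a-draws shifts its median
  # ratio by exactly 1 bit and its delta by at most 1
  d0 <- min_log2_fc(a2, b)
  a3 <- a2
  a3[, 2] <- a3[, 2] * 2
  d1 <- min_log2_fc(a3, b)
  expect_lte(d1$delta[2] - d0$delta[2], 1 + 1e-12)
  expect_error(min_log2_fc(matrix(1, 0, 1), matrix(1, 0, 1)), "nonempty")
})

test_that("regression recovers known effects and is permutation invariant", {
  ex <- simulate_two_condition(n_genes = 12L, depth = 8000L,
                               n_per_group = 3L, frac_de = 0.25,
                               effect_bits = 1.5, seed = 21)
  aps <- lapply(seq_along(ex$samples), function(s) {
    fit_approximation(ex$samples[[s]], fit_config(steps = 300L, seed = 100 + s),
                      effective_lengths = ex$effective_lengths)
  })
  design <- cbind(1, ex$design$condition)
  fit <- regression_fit(aps, design, seed = 22)
  lab <- ex$true_effects != 0
  expect_gt(auroc(fit$tail_prob + fit$beta_sd[2, ] * 0, lab), 0.8)
  # recovered signs agree with the truth for strong effects
  strong <- which(abs(ex$true_effects) > 0 & fit$tail_prob > 0.9)
  if (length(strong) > 0) {
    expect_true(all(sign(fit$delta_mean[strong]) ==
                      sign(ex$true_effects[strong])))
  }

  # permuting samples together with design rows leaves summaries unchanged
  perm <- c(4L, 1L, 5L, 2L, 6L, 3L)
  fitp <- regression_fit(aps[perm], design[perm, , drop = FALSE], seed = 23)
  expect_lt(median(abs(fit$delta_mean - fitp$delta_mean)), 0.2)

  expect_error(regression_fit(aps, cbind(1, 1)[rep(1, 6), ], seed = 1),
               "rank")
})

test_that("transcripts with no reads anywhere get effect intervals covering 0", {
  # transcript 3 never receives a read in any sample
  mats <- lapply(1:4, function(s) {
    compat_from_dense(rbind(c(1, 0, 0), c(0, 1, 0)),
                      weights = c(40L + 5L * s, 60L - 5L * s))
  })
  aps <- lapply(seq_along(mats), function(s) {
    fit_approximation(mats[[s]], fit_config(steps = 300L, seed = 30 + s))
  })
  design <- cbind(1, c(0, 0, 1, 1))
  fit <- regression_fit(aps, design, seed = 31)
  lo <- fit$beta_mean[2, 3] - 2 * fit$beta_sd[2, 3]
  hi <- fit$beta_mean[2, 3] + 2 * fit$beta_sd[2, 3]
  expect_true(lo < 0 && hi > 0)
})

test_that("coexpression matrix has correlation structure and degeneracy handling", {
  set.seed(72)
  k <- 6L
  base <- runif(4, 0.1, 0.3)
  sets <- lapply(1:k, function(s) {
    # transcripts: 1 constant, 2 and 3 identical trajectories, 4 noise
    v <- c(0.25, base[2] * (1 + 0.1 * s), base[2] * (1 + 0.1 * s),
           runif(1, 0.1, 0.3))
    m <- matrix(rep(v / sum(v), 5), nrow = 5, byrow = TRUE)
    m
  })
  cc <- coexpression_spearman(sets, draws = 5L, pseudocount_tpm = 0.1,
                              effective_lengths = rep(1000, 4))
  expect_equal(cc[2, 3], 1)
  expect_true(isSymmetric(cc))
  expect_equal(diag(cc), rep(1, 4))
  expect_true(all(cc >= -1 & cc <= 1))
  expect_error(coexpression_spearman(sets[1:2], 5L, 0.1, rep(1000, 4)),
               "3 samples")
  # TPM conversion: length-normalized and scaled to 1e6
  tpm <- tpm_from_expression(c(0.5, 0.5), c(1000, 2000))
  expect_equal(sum(tpm), 1e6)
  expect_equal(tpm[1] / tpm[2], 2)
})

test_that("constant transcripts get zero correlation by convention", {
  sets <- lapply(1:5, function(s) {
    matrix(c(0.25, 0.25 + 0.02 * s, 0.5 - 0.02 * s), nrow = 1)
  })
  # transcript 1 constant across samples: zero variance in ranks
  cc <- coexpression_spearman(sets, draws = 1L, pseudocount_tpm = 0,
                              effective_lengths = rep(1, 3))
  expect_equal(cc[1, 2], 0)
  expect_equal(cc[1, 3], 0)
})
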