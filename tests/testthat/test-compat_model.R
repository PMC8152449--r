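test_that("log-likelihood matches brute-force evaluation", {
  # single unambiguous read
  c1 <- compat_from_dense(matrix(c(1, 0), nrow = 1))
  expect_equal(log_likelihood(c1, c(0.3, 0.7)), log(0.3))

  # rows constant across transcripts: flat in x
  cflat <- compat_from_dense(matrix(0.2, nrow = 3, ncol = 2))
  expect_equal(log_likelihood(cflat, c(0.5, 0.5)), 3 * log(0.2))
  expect_equal(log_likelihood(cflat, c(0.9, 0.1)), 3 * log(0.2))

  # three reads, explicit product of mixture sums
  c3 <- compat_from_dense(rbind(c(1, 0), c(0, 1), c(0.5, 0.5)))
  expect_equal(log_likelihood(c3, c(0.5, 0.5)), log(0.5 * 0.5 * 0.5))

  # dense brute force on random sparse instances
  set.seed(41)
  for (rep in 1:8) {
    m <- sample(2:10, 1)
    n <- sample(2:10, 1)
    mat <- matrix(runif(m * n) * rbinom(m * n, 1, 0.6), m, n)
    mat[cbind(seq_len(m), sample(n, m, replace = TRUE))] <- runif(m, 0.1, 1)
    x <- clamp_simplex_test(rexp(n))
    cm <- compat_from_dense(mat)
    brute <- sum(log(as.vector(mat %*% x)))
    expect_equal(log_likelihood(cm, x), brute, tolerance = 1e-10)
  }

  expect_error(log_likelihood(c1, c(0.2, 0.3, 0.5)), "length")
  expect_error(compat_from_dense(rbind(c(1, 0), c(0, 0))), "positive entry")
})

test_that("identical rows collapse losslessly into weights", {
  mat <- rbind(c(1, 0), c(0.5, 0.5), c(1, 0), c(0.5, 0.5), c(1, 0))
  cm <- read_compat(Matrix::Matrix(mat, sparse = TRUE))
  expect_equal(nrow(cm$p), 2L)
  expect_equal(sort(cm$weights), c(2L, 3L))
  expect_equal(cm$m, 5L)
  un <- read_compat(Matrix::Matrix(mat, sparse = TRUE), collapse = FALSE)
  x <- c(0.4, 0.6)
  expect_equal(log_likelihood(cm, x), log_likelihood(un, x))
})

test_that("EM maximum likelihood: closed forms, boundary, monotonicity", {
  # all reads unambiguous: x = counts / m exactly
  cm <- compat_from_dense(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                          weights = c(5L, 3L, 2L))
  expect_equal(as.vector(ml_estimate(cm)), c(0.5, 0.3, 0.2),
               tolerance = 1e-9)

  # boundary maximizer: grid-search oracle on the 2-simplex
  cb <- compat_from_dense(rbind(c(1, 0), c(0.5, 0.5)))
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  ll_grid <- log(grid) + log(0.5)
  x_grid <- grid[which.max(ll_grid)]
  em <- as.vector(ml_estimate(cb))
  expect_gte(em[1], x_grid)
  expect_lt(em[1], 1)

  # symmetric instance stays symmetric
  cs <- compat_from_dense(rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(as.vector(ml_estimate(cs)), c(0.5, 0.5))

  # log-likelihood trace is monotone non-decreasing on a random instance
  e <- simulate_transcriptome(n_genes = 8L, depth = 5000L, seed = 4)
  fit <- ml_estimate(e$compat)
  trace <- attr(fit, "loglik_trace")
  expect_true(all(diff(trace) > -1e-8))
})

test_that("Gibbs sampler: protocol arithmetic, conjugate closed form, reproducibility", {
  cm <- compat_from_dense(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                          weights = c(30L, 15L, 5L))
  run <- gibbs_sample(cm, chains = 2L, burn_in = 100L, iterations = 5000L,
                      thin = 5L, seed = 9)
  expect_equal(nrow(run$draws[[1]]), 1000L)

  # zero ambiguity: marginals are exactly Dirichlet(1 + counts)
  al <- 1 + c(30, 15, 5)
  a0 <- sum(al)
  g <- gibbs_pooled(run)
  m_th <- al / a0
  v_th <- al * (a0 - al) / (a0^2 * (a0 + 1))
  se <- sqrt(v_th / nrow(g))
  expect_lt(max(abs(colMeans(g) - m_th) / se), 3)
  v_emp <- apply(g, 2, var)
  se_v <- apply(sweep(g, 2, colMeans(g))^2, 2, sd) / sqrt(nrow(g))
  expect_lt(max(abs(v_emp - v_th) / se_v), 3.5)

  # identical seed => identical draws; draws live on the open simplex
  run2 <- gibbs_sample(cm, chains = 2L, burn_in = 100L, iterations = 5000L,
                       thin = 5L, seed = 9)
  expect_identical(run$draws, run2$draws)
  expect_true(all(g > 0 & g < 1))
  expect_lt(max(abs(rowSums(g) - 1)), 1e-8)

  expect_error(gibbs_sample(cm, iterations = 1001L, thin = 25L),
               "divisible")
})

test_that("Gibbs mean matches quadrature of the normalized likelihood (n = 2)", {
  cm <- two_transcript_instance(60L, 40L)
  q <- two_transcript_quadrature(60, 40)
  run <- gibbs_sample(cm, chains = 4L, burn_in = 500L, iterations = 5000L,
                      thin = 5L, seed = 10)
  g <- gibbs_pooled(run, 1000L)
  se <- sd(g[, 1]) / sqrt(nrow(g))
  expect_lt(abs(mean(g[, 1]) - q["mean"]) / se, 3)
})
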