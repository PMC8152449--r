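test_that("forward transformation matches hand-computed breaks", {
  tr2 <- polya_tree(2L, 3L, 1:2)
  fw <- ptt_forward(tr2, 0.25)
  expect_equal(fw$x, c(0.25, 0.75))

  # balanced n = 4 with even breaks is uniform
  tr4 <- polya_tree(left = c(2L, 4L, 6L), right = c(3L, 5L, 7L),
                    leaf_to_transcript = 1:4)
  expect_equal(ptt_forward(tr4, c(0.5, 0.5, 0.5))$x, rep(0.25, 4))
})

test_that("forward agrees with a naive recursive oracle and conserves mass", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    tr <- baseline_tree(n, "random", seed = 400 + rep)
    y <- runif(n - 1, 0.02, 0.98)
    u1 <- runif(1, 0.2, 3)
    fw <- ptt_forward(tr, y, u1)
    expect_equal(fw$x, recursive_ptt(tr, y, u1), tolerance = 1e-12)
    expect_lt(abs(sum(fw$x) - u1), 1e-10)
    # children sum to parents at every internal node
    expect_lt(max(abs(fw$u[tr$left] + fw$u[tr$right] -
                        fw$u[seq_len(n - 1)])), 1e-10)
  }
})

test_that("inverse recovers break fractions and round-trips", {
  tr2 <- polya_tree(2L, 3L, 1:2)
  expect_equal(ptt_inverse(tr2, c(0.25, 0.75))$y, 0.25)
  tr4 <- polya_tree(left = c(2L, 4L, 6L), right = c(3L, 5L, 7L),
                    leaf_to_transcript = 1:4)
  expect_equal(ptt_inverse(tr4, rep(0.25, 4))$y, rep(0.5, 3))

  set.seed(12)
  for (n in c(5, 50, 1000)) {
    tr <- baseline_tree(n, "random", seed = n)
    x <- as.vector(clamp_simplex_test(rexp(n)))
    y <- ptt_inverse(tr, x)$y
    expect_lt(max(abs(ptt_forward(tr, y)$x - x)), 1e-10)
    yy <- runif(n - 1, 0.05, 0.95)
    expect_lt(max(abs(ptt_inverse(tr, ptt_forward(tr, yy)$x)$y - yy)), 1e-10)
  }
})

test_that("log-Jacobian equals the internal-node product and matches finite differences", {
  tr2 <- polya_tree(2L, 3L, 1:2)
  expect_equal(ptt_log_jacobian(ptt_forward(tr2, 0.3)$u, 2L), 0)
  tr4 <- polya_tree(left = c(2L, 4L, 6L), right = c(3L, 5L, 7L),
                    leaf_to_transcript = 1:4)
  expect_equal(ptt_log_jacobian(ptt_forward(tr4, c(0.5, 0.5, 0.5))$u, 4L),
               log(0.25))

  set.seed(13)
  for (n in 2:8) {
    tr <- baseline_tree(n, "random", seed = 700 + n)
    y <- runif(n - 1, 0.1, 0.9)
    u1 <- runif(1, 0.5, 2)
    fw <- ptt_forward(tr, y, u1)
    expect_equal(ptt_log_jacobian(fw$u, n),
                 fd_log_det_jacobian(tr, y, u1),
                 tolerance = 1e-5)
  }
})

test_that("tree validation rejects malformed trees", {
  expect_error(polya_tree(2L, 2L, 1:2), "children")
  # node 3 is given node 2 as a child: indices must increase downward
  expect_error(polya_tree(c(3L, 5L, 2L), c(4L, 6L, 7L), 1:4), "exceed")
  expect_error(polya_tree(2L, 3L, c(1L, 1L)), "permutation")
  # degenerate n = 1 tree is the identity
  tr1 <- polya_tree(integer(0), integer(0), 1L)
  expect_equal(ptt_forward(tr1, numeric(0), u1 = 1)$x, 1)
  expect_equal(ptt_log_jacobian(1, 1L), 0)
})

test_that("HierarchicalBeta reproduces Dirichlet regardless of topology", {
  # n = 2: x1 is exactly Beta(a, b)
  tr2 <- polya_tree(2L, 3L, 1:2)
  x <- hierarchical_beta_sample(tr2, c(2, 5), 10000, seed = 21)
  expect_gt(ks.test(x[, 1], pbeta, 2, 5)$p.value, 0.01)

  # n = 3, flat alpha: marginals are Beta(1, 2)
  tr3 <- baseline_tree(3L, "random", seed = 5)
  x3 <- hierarchical_beta_sample(tr3, c(1, 1, 1), 10000, seed = 22)
  for (j in 1:3) {
    expect_gt(ks.test(x3[, j], pbeta, 1, 2)$p.value, 0.01)
  }

  # n = 5, two different topologies: moments match Dirichlet closed forms
  al <- c(0.8, 2.5, 1.2, 4, 1.7)
  a0 <- sum(al)
  m_th <- al / a0
  v_th <- al * (a0 - al) / (a0^2 * (a0 + 1))
  for (s in c(31, 32)) {
    tr <- baseline_tree(5L, "random", seed = s)
    x5 <- hierarchical_beta_sample(tr, al, 20000, seed = 23)
    se_m <- sqrt(v_th / 20000)
    expect_lt(max(abs(colMeans(x5) - m_th) / se_m), 3)
    v_emp <- apply(x5, 2, var)
    se_v <- apply(sweep(x5, 2, colMeans(x5))^2, 2, sd) / sqrt(20000)
    expect_lt(max(abs(v_emp - v_th) / se_v), 3)
  }

  # empirical marginal CDFs under two topologies agree (two-sample KS)
  xa <- hierarchical_beta_sample(baseline_tree(5L, "random", seed = 41),
                                 al, 10000, seed = 24)
  xb <- hierarchical_beta_sample(baseline_tree(5L, "random", seed = 42),
                                 al, 10000, seed = 25)
  for (j in 1:5) {
    expect_gt(suppressWarnings(ks.test(xa[, j], xb[, j])$p.value), 0.01)
  }
})

test_that("zero-ambiguity likelihood is Dirichlet: HierarchicalBeta matches Gibbs moments", {
  e <- simulate_transcriptome(n_genes = 6L, isoforms_per_gene = 2L,
                              depth = 3000L, ambiguity = 0, seed = 3)
  counts <- unambiguous_counts(e$compat)
  run <- gibbs_sample(e$compat, chains = 4L, burn_in = 200L,
                      iterations = 4000L, thin = 4L, seed = 7)
  g <- gibbs_pooled(run)
  hb <- hierarchical_beta_sample(jaccard_cluster_tree(e$compat),
                                 1 + counts, nrow(g), seed = 8)
  se <- sqrt(apply(g, 2, var) / nrow(g) + apply(hb, 2, var) / nrow(hb))
  expect_lt(max(abs(colMeans(g) - colMeans(hb)) / se), 3)
})
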