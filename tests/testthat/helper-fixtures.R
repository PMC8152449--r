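# shared fixture builders (all generated in code; no stored data)

# tiny compatibility object from a dense matrix
compat_from_dense <- function(mat, weights = NULL, collapse = FALSE) {
  read_compat(Matrix::Matrix(mat, sparse = TRUE), weights = weights,
              collapse = collapse)
}

# the canonical ambiguous two-transcript instance: unambiguous reads on
# transcript 1 plus reads compatible with both at equal probability
two_transcript_instance <- function(w_unambig = 60L, w_ambig = 40L) {
  compat_from_dense(rbind(c(1, 0), c(0.5, 0.5)),
                    weights = c(w_unambig, w_ambig))
}

# quadrature of the normalized two-transcript likelihood on a 1e-4 grid:
# returns mean and sd of x1
two_transcript_quadrature <- function(w_unambig, w_ambig) {
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  lp <- w_unambig * log(grid) + w_ambig * log(0.5 * grid + 0.5 * (1 - grid))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m <- sum(w * grid)
  c(mean = m, sd = sqrt(sum(w * grid^2) - m^2))
}

# per-transcript read counts of a zero-ambiguity compat (unit rows)
unambiguous_counts <- function(compat) {
  counts <- integer(compat$n)
  sets <- compat_sets(compat)
  for (j in seq_len(compat$n)) {
    counts[j] <- sum(compat$weights[sets[[j]]])
  }
  counts
}

# normalize a positive vector onto the simplex interior
clamp_simplex_test <- function(v) {
  v <- pmax(v, 1e-8)
  v / sum(v)
}

# area under the ROC curve from scores and binary labels
auroc <- function(score, label) {
  r <- rank(score)
  np <- sum(label)
  (sum(r[label]) - np * (np + 1) / 2) / (np * sum(!label))
}

# naive recursive forward stick-breaking, independent of the package's
# iterative implementation (oracle for ptt_forward)
recursive_ptt <- function(tree, y, u1 = 1) {
  n <- tree$n
  x <- numeric(n)
  recurse <- function(node, u) {
    if (node >= n) {
      x[tree$leaf_to_transcript[node - (n - 1L)]] <<- u
      return(invisible(NULL))
    }
    recurse(tree$left[node], y[node] * u)
    recurse(tree$right[node], (1 - y[node]) * u)
  }
  recurse(1L, u1)
  x
}

# finite-difference log |det J| of the general map (u1, y) -> x
fd_log_det_jacobian <- function(tree, y, u1, h = 1e-6) {
  n <- tree$n
  f <- function(par) ptt_forward(tree, par[-1L], par[1L])$x
  p0 <- c(u1, y)
  jm <- matrix(0, n, n)
  for (k in seq_len(n)) {
    pp <- p0
    pm <- p0
    pp[k] <- pp[k] + h
    pm[k] <- pm[k] - h
    jm[, k] <- (f(pp) - f(pm)) / (2 * h)
  }
  as.numeric(determinant(jm)$modulus)
}
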