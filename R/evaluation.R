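#' Wilcoxon signed-rank goodness of fit
#'
#' The marginal goodness-of-fit protocol: per transcript, the i-th exact
#' draw is paired with the i-th approximate draw and a Wilcoxon signed-rank
#' test is applied to the differences (zeros dropped per the standard
#' convention; all-zero differences give p = 1). Since the two sample sets
#' are independent, a perfect approximation yields uniform p-values;
#' departures skew the distribution toward small values, and the overall
#' skew measures how badly the approximation fits.
#'
#' @param exact_draws,approx_draws `draws x n` matrices with equal draw
#'   counts (conventionally 1000 each).
#' @return an object of class `gof_report`: list with `p_values`,
#'   `quantiles` (1st, 25th, 50th, 75th, 99th percentiles), `median_p`,
#'   `frac_below_01` (fraction of transcripts with p < 0.01).
#' @export
wilcoxon_gof <- function(exact_draws, approx_draws) {
  if (!all(dim(exact_draws) == dim(approx_draws))) {
    stop("wilcoxon_gof: sample sets must have equal draw counts")
  }
  n <- ncol(exact_draws)
  p_values <- vapply(seq_len(n), function(j) {
    d <- exact_draws[, j] - approx_draws[, j]
    d <- d[d != 0]
    if (length(d) == 0L) return(1)
    suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1L))
  structure(
    list(p_values = p_values,
         quantiles = stats::quantile(p_values,
                                     c(0.01, 0.25, 0.5, 0.75, 0.99)),
         median_p = stats::median(p_values),
         frac_below_01 = mean(p_values < 0.01)),
    class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("gof_report: median p = %.3f, %.1f%% below 0.01\n",
              x$median_p, 100 * x$frac_below_01))
  print(signif(x$quantiles, 3))
  invisible(x)
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Convergence diagnostic comparing within-chain and between-chain
#' variance: each chain is split in half and, per transcript, R-hat is
#' `sqrt(((N-1)/N * W + B/N) / W)` with `W` the mean within-sequence
#' variance and `B` the between-sequence variance of the means (N the
#' split-chain length). Values near 1 indicate convergence. Transcripts
#' whose draws are constant across all chains are reported as 1 and
#' flagged.
#'
#' @param run a `gibbs_run` (or a list of `draws x n` chain matrices).
#' @return numeric vector of per-transcript R-hat values with attribute
#'   `flagged` (logical; degenerate constant chains).
#' @export
rhat <- function(run) {
  chains <- if (inherits(run, "gibbs_run")) run$draws else run
  if (length(chains) < 2L) stop("rhat: need at least 2 chains")
  per <- nrow(chains[[1L]])
  if (per < 2L) stop("rhat: need at least 2 draws per chain")
  half <- per %/% 2L
  splits <- list()
  for (ch in chains) {
    splits[[length(splits) + 1L]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1L]] <- ch[(half + 1L):(2L * half), ,
                                        drop = FALSE]
  }
  means <- vapply(splits, colMeans, numeric(ncol(chains[[1L]])))
  vars <- vapply(splits, function(s) apply(s, 2L, stats::var),
                 numeric(ncol(chains[[1L]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  w <- rowMeans(vars)
  b <- half * apply(means, 1L, stats::var)
  flagged <- w <= 0
  r <- rep(1, length(w))
  ok <- !flagged
  r[ok] <- sqrt(((half - 1) / half * w[ok] + b[ok] / half) / w[ok])
  attr(r, "flagged") <- flagged
  r
}

#' Error in minimum log2 fold-change introduced by an approximation
#'
#' Per transcript, the minimum log2 fold-change computed from approximate
#' draws minus the one computed from exact draws; positive values mean the
#' approximation overestimates the effect size (a false-positive risk),
#' negative values an underestimate.
#'
#' @param exact_a,exact_b exact (Gibbs) draw matrices for two samples.
#' @param approx_a,approx_b approximate draw matrices, same draw counts.
#' @return numeric vector of per-transcript errors (bits).
#' @export
min_lfc_error <- function(exact_a, exact_b, approx_a, approx_b) {
  min_log2_fc(approx_a, approx_b)$delta - min_log2_fc(exact_a, exact_b)$delta
}
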