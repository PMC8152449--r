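#' Read-transcript compatibility data
#'
#' Wraps the sparse matrix of conditional read probabilities `p_j(r_i)`
#' (rows = reads or read-equivalence groups, columns = transcripts) that is
#' the sufficient data for the transcript-mixture likelihood. Identical rows
#' are optionally collapsed into one row with an integer multiplicity
#' weight; collapsing is exact (the likelihood is unchanged) because the
#' likelihood only depends on each distinct compatibility pattern and its
#' count.
#'
#' @param p sparse (or dense) nonnegative matrix, `rows x transcripts`;
#'   coerced to `Matrix::dgCMatrix`.
#' @param weights positive integer multiplicity per row (default all 1).
#' @param collapse collapse identical rows, summing weights (default TRUE).
#' @param transcript_ids optional character transcript identifiers.
#' @return an object of class `read_compat` with fields `p` (collapsed
#'   sparse matrix), `weights`, `m` (total read count, `sum(weights)`),
#'   `n` (transcript count) and `transcript_ids`.
#' @export
read_compat <- function(p, weights = NULL, collapse = TRUE,
                        transcript_ids = NULL) {
  p <- methods::as(methods::as(p, "CsparseMatrix"), "generalMatrix")
  if (nrow(p) < 1L || ncol(p) < 1L) stop("read_compat: need m, n >= 1")
  if (any(!is.finite(p@x)) || any(p@x < 0)) {
    stop("read_compat: entries must be finite and nonnegative")
  }
  if (is.null(weights)) weights <- rep(1L, nrow(p))
  if (length(weights) != nrow(p) || any(weights < 1)) {
    stop("read_compat: weights must be positive, one per row")
  }
  weights <- as.integer(round(weights))
  # drop explicit zeros so the stored support is the positive support
  p <- Matrix::drop0(p)
  rs <- Matrix::rowSums(p)
  if (any(rs <= 0)) {
    stop("read_compat: every row must have at least one positive entry")
  }
  if (collapse) {
    key <- row_pattern_keys(p)
    grp <- match(key, unique(key))
    if (max(grp) < nrow(p)) {
      w <- as.integer(rowsum(weights, grp)[, 1L])
      first <- which(!duplicated(grp))
      p <- p[first, , drop = FALSE]
      weights <- w
    }
  }
  if (!is.null(transcript_ids) && length(transcript_ids) != ncol(p)) {
    stop("read_compat: transcript_ids length must equal transcript count")
  }
  structure(
    list(p = p, weights = weights, m = sum(weights), n = ncol(p),
         transcript_ids = transcript_ids),
    class = "read_compat")
}

# string keys identifying distinct sparse row patterns
row_pattern_keys <- function(p) {
  pt <- methods::as(Matrix::t(p), "CsparseMatrix")
  ptr <- pt@p
  vapply(seq_len(ncol(pt)), function(i) {
    idx <- if (ptr[i + 1L] > ptr[i]) (ptr[i] + 1L):ptr[i + 1L] else integer(0)
    paste(pt@i[idx], signif(pt@x[idx], 15L), sep = ":", collapse = ";")
  }, character(1L))
}

#' @export
print.read_compat <- function(x, ...) {
  cat(sprintf(
    "read_compat: %d reads in %d equivalence rows over %d transcripts\n",
    x$m, nrow(x$p), x$n))
  invisible(x)
}

check_expression_vec <- function(x, n) {
  if (length(x) != n) stop("expression vector has wrong length")
  if (any(x <= 0) || any(x >= 1)) {
    stop("expression vector must lie strictly inside (0,1)")
  }
  if (abs(sum(x) - 1) > 1e-8) stop("expression vector must sum to 1")
  invisible(x)
}

# clamp a nonnegative vector to the open simplex interior and renormalize
clamp_simplex <- function(x, eps = 1e-12) {
  x <- pmin(pmax(x, eps), 1 - eps)
  x / sum(x)
}

#' Mixture log-likelihood of an expression vector
#'
#' Evaluates `sum_i w_i * log(sum_j x_j p_j(r_i))` over the sparse row
#' support, with a log-sum-exp fallback for rows whose mixture mass
#' underflows in the direct computation.
#'
#' @param compat a [read_compat] object.
#' @param x expression vector on the open simplex, length `compat$n`.
#' @return the log-likelihood (a single real).
#' @export
log_likelihood <- function(compat, x) {
  check_expression_vec(x, compat$n)
  s <- as.vector(compat$p %*% x)
  lo <- log(s)
  bad <- which(!is.finite(lo))
  if (length(bad) > 0L) {
    pt <- methods::as(Matrix::t(compat$p[bad, , drop = FALSE]),
                      "CsparseMatrix")
    ptr <- pt@p
    for (k in seq_along(bad)) {
      idx <- if (ptr[k + 1L] > ptr[k]) (ptr[k] + 1L):ptr[k + 1L] else integer(0)
      terms <- log(x[pt@i[idx] + 1L]) + log(pt@x[idx])
      mx <- max(terms)
      lo[bad[k]] <- mx + log(sum(exp(terms - mx)))
    }
  }
  sum(compat$weights * lo)
}

#' Maximum-likelihood expression by EM
#'
#' The classic mixture EM update `x_j <- sum_i w_i x_j p_j(r_i) / (m *
#' sum_k x_k p_k(r_i))`, started from the uniform vector, iterated until the
#' maximum absolute component change drops below `tol` or `max_iter` is
#' reached. Iterates are clamped to the open simplex interior
#' (`[1e-12, 1-1e-12]`, renormalized) so the result never contains exact
#' zeros. The log-likelihood sequence is monotone non-decreasing, which is
#' recorded in the returned trace.
#'
#' @param compat a [read_compat] object.
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter maximum EM iterations.
#' @return the ML expression vector, with attributes `loglik_trace`
#'   (log-likelihood after each iteration) and `iterations`.
#' @export
ml_estimate <- function(compat, tol = 1e-9, max_iter = 1000L) {
  n <- compat$n
  w <- compat$weights
  m <- compat$m
  x <- rep(1 / n, n)
  trace <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    s <- as.vector(compat$p %*% x)
    x_new <- x * as.vector(Matrix::crossprod(compat$p, w / s)) / m
    x_new <- clamp_simplex(x_new)
    trace[it] <- log_likelihood(compat, x_new)
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < tol || it >= max_iter) break
  }
  attr(x, "loglik_trace") <- trace
  attr(x, "iterations") <- it
  x
}

#' Reference Gibbs sampler for the normalized likelihood
#'
#' Data-augmented Gibbs sampler targeting the normalized likelihood, i.e.
#' the posterior over expression under a uniform Dirichlet(1,...,1) prior:
#' read assignments are drawn per row support with probability proportional
#' to `x_j p_j(r_i)`, then `x | assignments ~ Dirichlet(1 + counts)`. Each
#' chain is initialized from an independent uniform Dirichlet draw; chain
#' `c` uses the RNG seed `seed + 1000 * (c - 1)`. The defaults follow the
#' standard protocol of 8 chains, 2000 burn-in iterations, 25000 sampling
#' iterations with every 25th draw retained (1000 retained draws per
#' chain).
#'
#' @param compat a [read_compat] object.
#' @param chains number of independent chains.
#' @param burn_in discarded leading iterations per chain.
#' @param iterations post-burn-in iterations per chain; must be divisible by
#'   `thin`.
#' @param thin retain every `thin`-th draw.
#' @param seed master integer seed.
#' @return an object of class `gibbs_run`: list with `draws` (per-chain
#'   `iterations/thin x n` matrices), `chains`, `burn_in`, `iterations`,
#'   `thin`, `seed`.
#' @export
gibbs_sample <- function(compat, chains = 8L, burn_in = 2000L,
                         iterations = 25000L, thin = 25L, seed = 1L) {
  if (iterations %% thin != 0L) {
    stop("gibbs_sample: iterations must be divisible by thin")
  }
  spec <- gibbs_groups(compat)
  draws <- vector("list", chains)
  for (c in seq_len(chains)) {
    set.seed(seed + 1000L * (c - 1L))
    draws[[c]] <- gibbs_chain_cpp(
      compat$n, as.integer(iterations), as.integer(burn_in),
      as.integer(thin), spec$base_counts, spec$grp_ptr, spec$grp_cols,
      spec$grp_p, spec$grp_w)
  }
  structure(
    list(draws = draws, chains = chains, burn_in = burn_in,
         iterations = iterations, thin = thin, seed = seed),
    class = "gibbs_run")
}

# Split rows into unambiguous (fixed assignment counts) and ambiguous
# groups laid out in flat arrays for the C++ kernel.
gibbs_groups <- function(compat) {
  pt <- methods::as(Matrix::t(compat$p), "CsparseMatrix")
  ptr <- pt@p
  supp <- diff(ptr)
  base_counts <- integer(compat$n)
  amb <- which(supp > 1L)
  una <- which(supp == 1L)
  if (length(una) > 0L) {
    cols <- pt@i[ptr[una] + 1L] + 1L
    tab <- rowsum(compat$weights[una], cols)
    base_counts[as.integer(rownames(tab))] <- as.integer(tab[, 1L])
  }
  grp_ptr <- c(0L, cumsum(supp[amb]))
  idx <- unlist(lapply(amb, function(i) (ptr[i] + 1L):ptr[i + 1L]),
                use.names = FALSE)
  list(base_counts = base_counts,
       grp_ptr = as.integer(grp_ptr),
       grp_cols = if (length(idx)) pt@i[idx] else integer(0),
       grp_p = if (length(idx)) pt@x[idx] else numeric(0),
       grp_w = as.integer(compat$weights[amb]))
}

#' Pool retained Gibbs draws across chains
#'
#' @param run a `gibbs_run`.
#' @param count optional number of pooled draws to return (taken evenly
#'   across the interleaved chains); default all.
#' @return a `draws x n` matrix.
#' @export
gibbs_pooled <- function(run, count = NULL) {
  pooled <- do.call(rbind, run$draws)
  # interleave chains so any prefix mixes all chains
  per <- nrow(run$draws[[1L]])
  ord <- as.vector(t(matrix(seq_len(nrow(pooled)), nrow = per)))
  pooled <- pooled[ord, , drop = FALSE]
  if (!is.null(count)) {
    take <- round(seq(1L, nrow(pooled), length.out = count))
    pooled <- pooled[take, , drop = FALSE]
  }
  pooled
}

#' @export
print.gibbs_run <- function(x, ...) {
  cat(sprintf(
    "gibbs_run: %d chains x %d retained draws (burn-in %d, thin %d)\n",
    x$chains, nrow(x$draws[[1L]]), x$burn_in, x$thin))
  invisible(x)
}
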