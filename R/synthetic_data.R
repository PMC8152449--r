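#' Synthetic transcriptome with controlled read ambiguity
#'
#' Generates a ground-truth expression vector and a sparse read-transcript
#' compatibility matrix that emulates the sparse-mixture structure of real
#' RNA-Seq: transcripts are partitioned into genes, and reads are ambiguous
#' only among isoforms of one gene (most reads being compatible with a
#' small number of transcripts). Expression is drawn from a log-normal
#' prior and normalized to the simplex. Each gene owns a small dictionary
#' of equivalence-class patterns: the per-isoform unit-indicator singleton
#' patterns plus up to `3k` random multi-isoform subsets (for a gene with
#' `k` isoforms), each with one fixed vector of relative conditional
#' probabilities drawn uniformly from \[0.2, 1\]. Every read picks a
#' transcript proportional to the true expression, then with probability
#' `ambiguity` (when its gene has an eligible multi pattern) lands in a
#' random multi pattern containing that transcript, and otherwise in the
#' transcript's singleton pattern. Reads sharing a pattern collapse
#' losslessly into one weighted compatibility row.
#'
#' With `ambiguity = 0` every row is a unit indicator and the normalized
#' likelihood is exactly `Dirichlet(1 + counts)`; when all genes have at
#' least two isoforms the expected fraction of multi-transcript rows equals
#' `ambiguity`.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer vector of candidate isoform counts,
#'   sampled uniformly per gene (a single value gives a fixed count).
#' @param depth total number of reads.
#' @param ambiguity probability in \[0,1\] that a read from a multi-isoform
#'   gene receives a multi-transcript row.
#' @param seed integer seed.
#' @param expr_sdlog sd of the log-normal expression prior (log scale).
#' @return an object of class `synthetic_experiment`: list with `compat`
#'   (a [read_compat]), `truth_x`, `gene_map`, `transcript_ids`,
#'   `effective_lengths`, `n`, `seed`.
#' @export
simulate_transcriptome <- function(n_genes = 40L, isoforms_per_gene = 2:4,
                                   depth = 20000L, ambiguity = 0.5,
                                   seed = 1L, expr_sdlog = 1) {
  set.seed(seed)
  ann <- make_annotation(n_genes, isoforms_per_gene, expr_sdlog)
  compat <- draw_compat(ann, ann$truth_x, depth, ambiguity)
  structure(
    list(compat = compat, truth_x = ann$truth_x, gene_map = ann$gene_map,
         transcript_ids = ann$transcript_ids,
         effective_lengths = ann$effective_lengths, n = ann$n, seed = seed),
    class = "synthetic_experiment")
}

# Gene/isoform structure, ground-truth expression and the pattern
# dictionary. Consumes RNG state.
make_annotation <- function(n_genes, isoforms_per_gene, expr_sdlog = 1) {
  k <- if (length(isoforms_per_gene) == 1L) {
    rep(as.integer(isoforms_per_gene), n_genes)
  } else {
    sample(as.integer(isoforms_per_gene), n_genes, replace = TRUE)
  }
  n <- sum(k)
  gene_map <- rep(seq_len(n_genes), k)
  transcript_ids <- sprintf("T%04d", seq_len(n))
  truth_x <- exp(stats::rnorm(n, 0, expr_sdlog))
  truth_x <- truth_x / sum(truth_x)
  effective_lengths <- round(stats::runif(n, 500, 3000))
  patterns <- make_patterns(gene_map, n_genes)
  list(n = n, gene_map = gene_map, transcript_ids = transcript_ids,
       truth_x = truth_x, effective_lengths = effective_lengths,
       patterns = patterns)
}

# Pattern dictionary: list with cols/p per pattern plus, per transcript,
# the ids of multi patterns containing it.
make_patterns <- function(gene_map, n_genes) {
  n <- length(gene_map)
  cols <- lapply(seq_len(n), function(j) j)          # singletons first
  pvals <- lapply(seq_len(n), function(j) 1)
  multi_of <- vector("list", n)
  for (g in seq_len(n_genes)) {
    members <- which(gene_map == g)
    kk <- length(members)
    if (kk < 2L) next
    subsets <- all_multi_subsets(kk)
    n_pat <- min(length(subsets), 3L * kk)
    take <- if (length(subsets) > n_pat) sample(length(subsets), n_pat)
            else seq_along(subsets)
    for (s in take) {
      idx <- members[subsets[[s]]]
      cols[[length(cols) + 1L]] <- idx
      pvals[[length(pvals) + 1L]] <- stats::runif(length(idx), 0.2, 1)
      pid <- length(cols)
      for (j in idx) multi_of[[j]] <- c(multi_of[[j]], pid)
    }
  }
  list(cols = cols, p = pvals, multi_of = multi_of)
}

all_multi_subsets <- function(k) {
  out <- list()
  for (size in 2:k) {
    cc <- utils::combn(k, size)
    for (i in seq_len(ncol(cc))) out[[length(out) + 1L]] <- cc[, i]
  }
  out
}

# Draw reads given expression x and a pattern dictionary; returns a
# collapsed read_compat. Consumes RNG state.
draw_compat <- function(ann, x, depth, ambiguity) {
  n <- ann$n
  pat <- ann$patterns
  cnt <- as.integer(stats::rmultinom(1L, depth, x))
  w <- integer(length(pat$cols))
  for (j in seq_len(n)) {
    if (cnt[j] == 0L) next
    pool <- pat$multi_of[[j]]
    a <- if (ambiguity > 0 && length(pool) > 0L) {
      stats::rbinom(1L, cnt[j], ambiguity)
    } else 0L
    w[j] <- w[j] + (cnt[j] - a)
    if (a > 0L) {
      if (length(pool) == 1L) {
        w[pool] <- w[pool] + a
      } else {
        add <- as.integer(stats::rmultinom(1L, a,
                                           rep(1 / length(pool),
                                               length(pool))))
        w[pool] <- w[pool] + add
      }
    }
  }
  keep <- which(w > 0L)
  ii <- rep(seq_along(keep), lengths(pat$cols[keep]))
  jj <- unlist(pat$cols[keep], use.names = FALSE)
  xx <- unlist(pat$p[keep], use.names = FALSE)
  p <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(keep), n))
  read_compat(p, weights = w[keep], collapse = FALSE,
              transcript_ids = ann$transcript_ids)
}

#' Two-condition synthetic experiment with known differential expression
#'
#' Builds one gene/isoform annotation, selects a fraction of transcripts as
#' differentially expressed with log2 shifts of `+-effect_bits`, adds
#' per-sample biological noise `Normal(0, biovar_sd)` on the log2 scale,
#' renormalizes each sample to the simplex, and draws an independent
#' compatibility matrix per sample (all samples share the same
#' equivalence-class pattern dictionary, as they would share an
#' annotation).
#'
#' @inheritParams simulate_transcriptome
#' @param n_per_group samples per condition.
#' @param frac_de fraction of transcripts differentially expressed.
#' @param effect_bits absolute log2 effect size of DE transcripts.
#' @param biovar_sd per-sample biological noise sd, log2 scale.
#' @return an object of class `synthetic_experiment` with `samples` (list
#'   of per-sample [read_compat]), `truth` (per-sample expression),
#'   `true_effects` (per-transcript signed log2 effects), `design`
#'   (data.frame with a 0/1 `condition` column) plus the annotation fields.
#' @export
simulate_two_condition <- function(n_genes = 40L, isoforms_per_gene = 2:4,
                                   depth = 20000L, ambiguity = 0.5,
                                   n_per_group = 3L, frac_de = 0.1,
                                   effect_bits = 1, biovar_sd = 0.2,
                                   seed = 1L, expr_sdlog = 1) {
  set.seed(seed)
  ann <- make_annotation(n_genes, isoforms_per_gene, expr_sdlog)
  n <- ann$n
  n_de <- round(frac_de * n)
  true_effects <- numeric(n)
  if (n_de > 0L) {
    de <- sample(n, n_de)
    true_effects[de] <- sample(c(-1, 1), n_de, replace = TRUE) * effect_bits
  }
  condition <- rep(c(0L, 1L), each = n_per_group)
  samples <- vector("list", length(condition))
  truth <- vector("list", length(condition))
  for (s in seq_along(condition)) {
    l2 <- log2(ann$truth_x) + true_effects * condition[s] +
      stats::rnorm(n, 0, biovar_sd)
    xs <- 2^l2
    xs <- xs / sum(xs)
    truth[[s]] <- xs
    samples[[s]] <- draw_compat(ann, xs, depth, ambiguity)
  }
  structure(
    list(samples = samples, truth = truth, true_effects = true_effects,
         design = data.frame(condition = condition),
         gene_map = ann$gene_map, transcript_ids = ann$transcript_ids,
         effective_lengths = ann$effective_lengths, n = n, seed = seed),
    class = "synthetic_experiment")
}

#' Multi-sample cohort with known coexpressed transcript pairs
#'
#' Generates a cohort of samples from one annotation in which selected
#' cross-gene transcript pairs share a latent per-sample factor: for a pair
#' with loading `lambda`, both members' log2 expression gains
#' `lambda * f_s` with `f_s ~ Normal(0,1)`, on top of independent
#' `Normal(0, biovar_sd)` noise. On the log2 scale the generating Pearson
#' correlation of a pair is `lambda^2 / (lambda^2 + biovar_sd^2)` and the
#' implied Spearman correlation is `(6/pi) * asin(rho/2)`; both are
#' returned. Within-gene isoform pairs have no shared factor and serve as
#' null pairs whose reads are nonetheless highly ambiguous.
#'
#' @inheritParams simulate_two_condition
#' @param n_samples cohort size.
#' @param n_cor_pairs number of coexpressed cross-gene pairs.
#' @param cor_loading shared-factor loading `lambda` (log2 scale).
#' @return an object of class `synthetic_experiment` with `samples`,
#'   `truth`, `cor_pairs` (two-column matrix of transcript indices),
#'   `rho_pearson_log2`, `rho_spearman` and the annotation fields.
#' @export
simulate_cohort <- function(n_genes = 30L, isoforms_per_gene = 2:3,
                            depth = 20000L, ambiguity = 0.5,
                            n_samples = 12L, n_cor_pairs = 8L,
                            cor_loading = 1, biovar_sd = 0.3,
                            seed = 1L, expr_sdlog = 1) {
  set.seed(seed)
  ann <- make_annotation(n_genes, isoforms_per_gene, expr_sdlog)
  n <- ann$n
  if (2L * n_cor_pairs > n_genes) {
    stop("simulate_cohort: need at least 2 * n_cor_pairs genes")
  }
  pair_genes <- sample(n_genes, 2L * n_cor_pairs)
  cor_pairs <- matrix(0L, nrow = n_cor_pairs, ncol = 2L)
  for (p in seq_len(n_cor_pairs)) {
    g1 <- which(ann$gene_map == pair_genes[2L * p - 1L])
    g2 <- which(ann$gene_map == pair_genes[2L * p])
    cor_pairs[p, ] <- c(g1[sample(length(g1), 1L)],
                        g2[sample(length(g2), 1L)])
  }
  rho <- cor_loading^2 / (cor_loading^2 + biovar_sd^2)
  samples <- vector("list", n_samples)
  truth <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    l2 <- log2(ann$truth_x) + stats::rnorm(n, 0, biovar_sd)
    f <- stats::rnorm(n_cor_pairs)
    for (p in seq_len(n_cor_pairs)) {
      # replace independent noise with shared factor + noise for members
      l2[cor_pairs[p, ]] <- log2(ann$truth_x[cor_pairs[p, ]]) +
        cor_loading * f[p] + stats::rnorm(2L, 0, biovar_sd)
    }
    xs <- 2^l2
    xs <- xs / sum(xs)
    truth[[s]] <- xs
    samples[[s]] <- draw_compat(ann, xs, depth, ambiguity)
  }
  structure(
    list(samples = samples, truth = truth, cor_pairs = cor_pairs,
         rho_pearson_log2 = rho, rho_spearman = (6 / pi) * asin(rho / 2),
         gene_map = ann$gene_map, transcript_ids = ann$transcript_ids,
         effective_lengths = ann$effective_lengths, n = n, seed = seed),
    class = "synthetic_experiment")
}
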