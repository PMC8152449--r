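# ptlik — approximate RNA-Seq transcript likelihoods via Pólya tree transformations

Transcript-level RNA-Seq quantification is a sparse mixture problem: with
relative expression $x \in \Delta^{n-1}$ and per-transcript read
distributions $p_j$, the likelihood of $m$ reads is

$$P(r \mid x) = \prod_{i=1}^{m} \sum_{j=1}^{n} x_j\, p_j(r_i),$$

and because isoforms and paralogs share sequence, many reads are
ambiguous. Most pipelines collapse this likelihood to a point estimate and
treat the estimate as observed, discarding the assignment uncertainty that
matters most exactly where isoforms are hard to tell apart. `ptlik` keeps
the uncertainty: it fits, per sample, a compact approximation $q(x;\phi)$
to the normalized likelihood by KL minimization, built by pushing a
mean-field reparameterized base distribution (logit-normal,
logit-skew-normal or Kumaraswamy) through a *Pólya tree transformation* —
a hierarchical stick-breaking bijection from break fractions
$(0,1)^{n-1}$ to the simplex defined by a full binary tree. The tree is
chosen by greedy Jaccard clustering of read-compatibility sets so the
family mirrors the data's subcompositional independence; its Jacobian
determinant is just the product of internal-node stick lengths, so the
fitted $q$ is evaluable, differentiable and sampleable in $O(n)$. Two
exact anchors back the construction: with Beta breaks parameterized by
subtree sums the family *is* the Dirichlet for any topology, and with zero
read ambiguity the normalized likelihood is exactly
Dirichlet(1 + counts).

The package is for computational biologists and methods developers who
want posterior-honest downstream analysis — differential transcript
expression, fold-change bounds, coexpression — without hauling the read
data through every model. It includes the exact reference machinery (EM
maximum likelihood, a C++-backed data-augmented Gibbs sampler, split
R-hat), compositional baselines (alr, mlr, balanced ilr), the
goodness-of-fit protocol (per-transcript Wilcoxon signed-rank against
Gibbs draws), a Bayesian regression and posterior-averaged Spearman
coexpression, and a synthetic-data generator with known ground truth.
Input is a MatrixMarket read–transcript compatibility matrix plus TSV
metadata; fitted approximations serialize to a small JSON container.

## Worked example

```r
library(ptlik)

exper  <- simulate_transcriptome(n_genes = 10, depth = 10000,
                                 ambiguity = 0.5, seed = 42)
exper$compat
#> read_compat: 10000 reads in 66 equivalence rows over 27 transcripts

approx <- fit_approximation(exper$compat, fit_config(seed = 1))
approx
#> approx_likelihood: 27 transcripts, logit_skew_normal base, tree method jaccard

# exact reference: data-augmented Gibbs on the normalized likelihood
run <- gibbs_sample(exper$compat, chains = 4, burn_in = 500,
                    iterations = 5000, thin = 5, seed = 2)
max(rhat(run))
#> [1] 1.0019

# marginal goodness of fit: near-uniform p-values = near-exact fit
wilcoxon_gof(gibbs_pooled(run, 1000), approx_sample(approx, 1000, seed = 3))
#> gof_report: median p = 0.622, 0.0% below 0.01
#>     1%    25%    50%    75%    99%
#> 0.0899 0.3800 0.6220 0.8550 0.9690

draws <- approx_sample(approx, 1000, seed = 4)
round(rbind(estimate = colMeans(draws)[1:5], truth = exper$truth_x[1:5]), 4)
#>            [,1]   [,2]   [,3]   [,4]   [,5]
#> estimate 0.0121 0.0768 0.0055 0.0199 0.0064
#> truth    0.0086 0.0786 0.0051 0.0193 0.0056
```

The `gof_report` line is the package's core diagnostic: 1000 Gibbs draws
(the exact normalized likelihood) against 1000 approximation draws,
per-transcript signed-rank tests — a perfect approximation gives uniform
p-values, so a median near 0.5 with a thin sub-0.01 tail means the
approximation is statistically indistinguishable from the exact posterior
at this resolution. The final table shows posterior-mean expression
tracking the simulated ground truth.

A command-line pipeline wraps the same functions
(`inst/cli/ptlik simulate | fit | sample | gibbs | gof | diffexp |
coexpr`); see `?run_cli`.

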