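---
title: "Methods: the annofine fine-mapping model, its estimation, and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the annofine fine-mapping model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annofine)
```

# The probabilistic model

A fine-mapping locus is a contiguous region around a GWAS hit with `m`
SNPs, a vector `z` of marginal Wald Z-scores, an LD matrix `Σ` of
pairwise Pearson correlations (in-sample or from a reference panel), and
a binary annotation matrix whose first column is the all-ones baseline.
Writing `c` for the binary causal-configuration vector and `λ` for the
vector of non-centrality parameters (NCPs; the expected Z-score of a
causal SNP), the Z-scores are modelled as

$$ z \mid c \sim \mathrm{MVN}\!\left(\Sigma(\lambda \circ c),\, \Sigma\right), $$

the standard multivariate-normal representation of marginal association
statistics under LD: a causal SNP's expected signal leaks into its
neighbours in proportion to their correlation with it. Causal status is
a priori independent across SNPs with a logistic link to annotations,

$$ P(c_j = 1) = \frac{1}{1 + \exp(\gamma^\top a_j)}, $$

and the locus likelihood sums over all configurations with at most
`max_causals` causal SNPs. Two modelling commitments are worth making
explicit:

* **NCPs are fixed, not estimated.** One Z-score per SNP cannot identify
  both causal status and effect size; the model would be over-specified.
  The default rule uses the observed Z when `|z| > 3.7` and
  `sign(z) · 3.7` otherwise (3.7 being roughly the Wald statistic at
  p = 1e-4); a truly causal SNP that reached genome-wide follow-up
  should not look weaker than that. `ncp_strategy` also offers the raw
  observed Z and the locus-maximum variant for comparison.
* **Sign convention of `γ`.** With `p = 1/(1+exp(γᵀa))`, a *negative*
  annotation coefficient means enrichment. This orientation reproduces
  the calibration used throughout the package: coefficients
  (4.62, −2.15) with a third of SNPs annotated give prior probabilities
  0.0098 outside and 0.0780 inside the annotation — an 8.0-fold
  enrichment — and ~0.0325 on average, i.e. about one expected causal
  per 31-SNP locus. Reported `log2_relprob` is
  `log2( p(a=1) / p(a=0) )`, so enrichment is positive in output tables.

All likelihood values are computed *relative to the null MVN density*:
the log Bayes factor of a configuration has the closed form
`λ_c' z − ½ λ_c' Σ λ_c`, touching only causal rows and columns of `Σ`.
The null constant cancels in posteriors, EM updates and likelihood-ratio
tests, so no `m × m` determinants are ever formed.

# Estimation

`finemap()` maximizes the product of locus likelihoods over `γ` by EM:

* **E-step** (`e_step()`): posterior probabilities over enumerated
  configurations by Bayes' theorem, then per-SNP marginals by summing
  configurations containing each SNP. Configuration Bayes factors do not
  depend on `γ` and are computed once per locus.
* **M-step** (`m_step()`): the expected complete-data log-likelihood in
  `γ` is a logistic regression with soft labels (the current
  posteriors), a concave problem solved by L-BFGS-B with the analytic
  gradient `Aᵀ(E − p)`.

Initialization sets the baseline to `log(m̄ − 1)` — one expected causal
per locus of mean size `m̄`, matching the regime the simulator encodes —
and annotation coefficients to 0. Convergence requires both the change
in total log-likelihood below `em_tol` (default 1e-4) and the max-norm
change in `γ` below `gamma_tol` (default 1e-3); a likelihood decrease
beyond numerical tolerance raises an error rather than being silently
accepted. The M-step carries an L2 penalty of `1e-6 · ‖γ‖²` purely to
keep separable cases (an annotation covering no high-posterior SNP)
finite; at estimable configurations its effect is far below estimation
noise.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `max_causals` | 2 | configurations per locus grow as `Σ C(m,k)`; 2 captures most multi-causal signal at tractable cost, 3 is feasible for moderate loci |
| `ncp_threshold` | 3.7 | NCP floor on the Z scale (≈ p = 1e-4) |
| `ld_ridge` | 1e-3 | `Σ ← (Σ + εI)/(1+ε)`; reference-panel LD with more SNPs than samples is rank-deficient, and the MVN density needs a positive-definite matrix. Applied before every likelihood evaluation |
| `em_tol`, `gamma_tol` | 1e-4, 1e-3 | joint convergence rule (see above) |
| `enum_cap` | 5e6 | hard cap on enumerated configurations per locus; exceeding it errors with advice to lower `max_causals` |
| `rho` (credible sets) | 0.9 | fraction of total posterior mass captured |

Ties in every ranking (credible sets, utility sweeps) are broken by
posterior descending, then `|z|` descending, then SNP id — determinism
matters for reproducible pipelines and for tests.

# Credible sets, enrichment inference, follow-up selection

`credible_set()` takes the *minimal* prefix of posterior-ranked SNPs
whose summed posterior reaches `ρ ×` (total posterior mass), either
globally across loci or per locus (then unioned). The total mass is the
literal sum of per-SNP posteriors, not normalized by an expected causal
count.

`annotation_lrt()` compares converged fits with and without one
annotation: `2·(LL_alt − LL_null)` against chi-square df = 1. Because EM
is iterative, a fixed initialization protocol is used for both fits (the
alternative warm-starts from the null's baseline coefficient); tiny
negative statistics from tolerance effects are clipped to zero and
flagged. `bootstrap_se()` resamples entire loci with replacement —
loci, not SNPs, are the independent units — refits, and reports plain
per-coefficient standard deviations. `marginal_scan()` runs the
single-annotation fit for each candidate annotation and sorts by
p-value; `select_annotations()` keeps the best record per replicate
group before taking the top k.

`utility_curve()` scores follow-up designs by `U = B·Nc − C·Nt`. In
expectation mode (`Nc` = sum of selected posteriors) the optimum is
exactly the set of SNPs with posterior above `C/B`; with simulator truth
supplied, `Nc` counts true causals instead.

# The simulator

`simulate_finemap()` generates complete studies with known truth. Its
defaults *are* the study conditions the rest of the package is
calibrated and tested against:

* 100 loci; SNP counts uniform on 25–60 (10 Kb-scale loci after common
  filtering; `maf_min = 0.01`);
* one synthetic annotation covering 1/3 of SNPs (random assignment by
  default, contiguous blocks optional);
* logistic prior coefficients (4.62, −2.15), or any target enrichment
  via `enrichment_gamma()`; `target_causals` recalibrates the baseline
  by bisection so the expected causal count is fixed (typically one per
  locus) while the enrichment is held;
* LD from an AR(1) profile (`0.9^|j−k|`), constant blocks, or a
  user-supplied haplotype panel (`haplotype_file`), the latter being the
  route to realistic human LD;
* Z-scores either by full forward simulation — Gaussian-copula
  haplotypes, dosages standardized, phenotype with total variance
  explained `h2 = 0.25` split equally among all causal SNPs (signs
  Rademacher; a gamma-distributed heterogeneous-effect option exists),
  Wald statistics from marginal OLS in `n_individuals = 10000` — or
  directly from the MVN model with causal NCPs drawn N(5, 0.2²)
  (`z_mode = "mvn_direct"`), the standard route for large loci.

All randomness flows from one seed through per-stage substreams
(layout/LD, annotations, causal draws, effects/noise), so truth tables
are bit-reproducible.

**What the simulator does and does not emulate.** It reproduces the
statistical structure the model cares about — LD-convolved signals,
annotation-structured causal placement, multi-causal loci, fixed
heritability — but AR(1)/block LD is far smoother than human LD, allele
frequencies are drawn independently of annotation status, and there is
no genotyping error, imputation noise, or case-control ascertainment.
Passing tests therefore demonstrate correctness of the machinery and
calibration under the model's own assumptions, not performance on any
particular real data set; for realistic LD, supply a haplotype panel.

# Numerical choices and degenerate inputs

* LD matrices are symmetrized, checked to `|r| ≤ 1`, and
  ridge-regularized before factorization; the Cholesky factor is
  computed once per locus and reused across configurations and EM
  iterations.
* Log-sum-exp is used for every configuration sum; priors enter via
  `log1p(-p)` so near-zero priors are safe.
* Missing Z-scores are rejected, not imputed — the model has no
  missingness mechanism; zero-variance genotype columns are an error
  naming the offending SNPs.
* `sign(0)` is defined as +1 in the NCP rule.
* A locus whose configuration space exceeds `enum_cap` errors instead
  of silently truncating.

# Design choices where the design was open

* **Coordinates.** SNP positions are 1-based (VCF-style); annotation
  intervals are 0-based half-open (BED-style). A SNP at position `p`
  lies in `[start, end)` iff `start ≤ p−1 < end`, so `p = end` is the
  last covered base. Intersection is delegated to
  GenomicRanges/IRanges.
* **LD provenance** (reference panel vs in-sample) is the caller's
  choice; the package only computes Pearson correlation on whatever
  matrix it is given, and likewise requires the caller to supply
  allele-consistent signs between `z` and the LD matrix.
* **The 3.7 constant** is kept as the operative threshold (its p-value
  gloss is only a mnemonic).
* **LRT protocol under EM multi-modality.** EM is not guaranteed
  unimodal; a single fixed initialization protocol (null fit from the
  default start, alternative warm-started from the null) makes the test
  statistic well-defined and, empirically, chi-square calibrated.
* **Bootstrap SDs** are plain percentile SDs, not BCa.
* **ABF prior variance** for the single-causal baseline defaults to
  `W = 10` on the Z² scale; at a single locus the induced ranking is
  identical to p-value ranking for any `W`, so the choice only affects
  absolute posterior values.

# Problem sizes used by the test suite

The package's calibration checks run at desk scale, chosen once as
conditions a single core handles comfortably while keeping Monte-Carlo
error informative: the causal-yield check uses 200 replicates of the
100-locus default; LRT null calibration uses 200 replicates of 50 loci
with 10–25 SNPs; enrichment recovery uses 50 replicates at each of five
log2-enrichment points in [−3, 3] with the 100-locus default. These
stochastic checks draw Z-scores with `z_mode = "mvn_direct"`; the
forward genotype route is covered by its own unit tests and, on matched
small configurations, gives concordant downstream behaviour.

# Known limitations

* Effect sizes have no prior distribution — NCPs are plugged in from
  the observed Z-scores; a fully Bayesian treatment of `λ` is out of
  scope.
* At strong depletion (log2 enrichment near −3) the annotation
  coefficient's MLE is heavy-tailed: replicates that draw few annotated
  causal variants border on separation, which the deliberately tiny L2
  penalty does not mask. Means over replicates remain unbiased within
  Monte-Carlo error, but individual estimates can be extreme; the
  bootstrap SDs surface this.
* Truncating configurations at `max_causals = 2` slightly flattens
  posteriors at loci truly carrying 3+ causal variants; raise
  `max_causals` when loci are small enough to afford it.
* Multi-allelic variants must be split or filtered upstream; there is
  no summary-statistic imputation or liftover.
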