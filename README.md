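# annofine — annotation-aware statistical fine-mapping

GWAS association signals rarely point at the causal variant: linkage
disequilibrium (LD) spreads a causal effect over dozens of correlated
SNPs, and many trait-associated loci carry more than one causal variant.
`annofine` is an R package for statistical fine-mapping from summary
statistics. It computes per-SNP posterior probabilities of causality at
each associated locus while (i) allowing multiple causal variants per
locus and (ii) learning, across loci, how binary functional annotations
(coding exons, DNase hypersensitivity sites, chromatin states, ...)
shift the prior probability that a SNP is causal. It is aimed at
statistical geneticists prioritizing variants for functional follow-up
from GWAS Z-scores, an LD reference, and annotation tracks.

## The model

For a locus with `m` SNPs, let `z` be the vector of marginal Wald
Z-scores, `Σ` the LD (Pearson correlation) matrix, and `c ∈ {0,1}^m` a
causal configuration. Conditional on `c`,

    z | c  ~  MVN( Σ (λ ∘ c), Σ )

where `λ` holds per-SNP non-centrality parameters (NCPs, the
standardized effect sizes). NCPs are fixed, not estimated: by default
`λ_j = z_j` when `|z_j| > 3.7` and `sign(z_j) · 3.7` otherwise
(estimating them would over-specify the model). Causal status is a priori
independent Bernoulli with a logistic link to the SNP's annotation vector
`a_j` (leading baseline 1):

    P(c_j = 1) = 1 / (1 + exp(γ' a_j))

so a negative annotation coefficient means causal variants are enriched
in that annotation. The locus likelihood sums `P(z | c) P(c | γ)` over
all configurations with at most `max_causals` members (default 2). The
coefficient vector `γ` is estimated by maximum likelihood across loci
with an EM algorithm whose M-step is a soft-label logistic regression
(L-BFGS with analytic gradients); posteriors come from the E-step, and
Bayes factors reduce to the closed form `λ_c' z − ½ λ_c' Σ λ_c`, so no
dense determinant work is needed.

Around the fit, the package provides ρ-level credible sets (the minimal
set of posterior-ranked SNPs holding a ρ fraction of posterior mass),
likelihood-ratio tests and locus-bootstrap standard errors for
annotation enrichment, a marginal annotation scan with top-k selection,
single-causal (approximate Bayes factor), p-value and
iterative-conditioning baselines, recall-per-SNPs-selected benchmarking
curves, a benefit-to-cost utility optimizer (`U = B·Nc − C·Nt`, optimal
inclusion threshold `C/B`), and a simulator that generates complete
synthetic fine-mapping studies with known ground truth.

## Worked example

```r
library(annofine)

sim <- simulate_finemap(
  sim_config(n_loci = 20, snps_per_locus = c(15, 30),
             z_mode = "mvn_direct", target_causals = 20),
  seed = 42)
fit <- finemap(sim$loci)
summary(fit)
#> Baseline prior probability of causality: 0.02531
#> Annotation effects:
#>  annotation gamma_hat prior_in prior_out log2_relprob frequency
#>  functional    -1.534   0.1074   0.02531        2.086    0.3275
#> Total relative log-likelihood: 334.9064 | EM iterations: 13

credible_set(fit, 0.9)
#> 90% credible set (global): 47 SNPs capturing 18.969 of 21.040 total posterior mass

marginal_scan(sim$loci)
#>   annotation gamma_hat log2_relprob frequency lrt_stat    p_value error
#> 1 functional  -1.53383     2.085855 0.3275434 5.261186 0.02180615  <NA>

utility_curve(fit$snp_table$posterior, B = 1, C = 0.1,
              snp_id = fit$snp_table$snp_id, z = fit$snp_table$zscore)
#> <utility_curve> R = 10 (expectation mode): max utility 14.324 at 44 SNPs (18.72 causals)
```

The data were generated with an annotation covering a third of the SNPs
and an 8-fold causal enrichment; the fit recovers a negative coefficient
(enrichment) of −1.53, i.e. a 2^2.09 ≈ 4.2-fold higher prior inside the
annotation, with LRT p = 0.022 from these 20 loci. The 90% credible set
compresses 403 SNPs to 47, and at a benefit-to-cost ratio of 10 the
utility-optimal follow-up set is the 44 SNPs with posterior above 0.1,
expected to contain 18.7 of the ~21 causal variants.

A command-line front end with the same functionality is installed at
`exec/annofine` (subcommands `simulate`, `fit`, `scan`, `select`,
`credible`, `benchmark`, `utility`); every run writes a JSON manifest of
its resolved parameters.

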