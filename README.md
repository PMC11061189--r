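# snpool

Pooled (multiplexed) single-nuclei RNA-seq experiments tag each sample with a
hashtag oligonucleotide (HTO) before pooling, then must assign every sequenced
nucleus back to its sample. When HTO staining is weak — common with long-banked
fresh-frozen tissue — a large fraction of nuclei get no confident hashtag call
and are thrown away. `snpool` implements an integrated demultiplexing strategy
that combines hashtag calls with genotype-based donor deconvolution from sparse
per-cell SNP allele counts, plus the downstream analyses that depend on
trustworthy sample assignment in a tumor-versus-normal study design:

- **Synthetic pools with ground truth** — a seeded generator emulating
  multi-sample pools (2–4 samples, doublets, weak/variable HTO staining,
  donor-discriminating SNPs at sparse coverage, cell-type marker programs,
  composition-confounded expression), so every stage is validated against
  known labels.
- **HTO demultiplexing** — CLR normalization per tag, k-medoids background
  identification, a method-of-moments negative-binomial background fit, and
  positive calls above its 0.99 quantile; nuclei are singlets, doublets or
  negatives.
- **Genotype demultiplexing** — for each nucleus, binomial likelihoods of its
  alternate-allele counts under every donor hypothesis, with per-SNP success
  probability ε + (1 − 2ε)·g for dosage g ∈ {0, ½, 1}; doublet hypotheses use
  the mean dosage of the pair, priors (1 − δ)/K per singlet and δ/C(K,2) per
  pair, and a posterior threshold τ defines confident assignment.
- **Integration** — keep concordant calls, drop discordant ones, rescue
  HTO-negative/doublet nuclei with confident genotype singlets, and account
  for the yield of each route.
- **Annotation and enrichment** — SNN/Louvain clustering, marker-based cell
  typing (classical brain markers ship with the package), expression-matched
  module (stemness) scores, and single-cell gene-set scoring by a
  variance-adjusted Mahalanobis statistic (S = Σ x²/v per set) calibrated
  against a gene-permutation gamma null, with BH-FDR binary enrichment calls
  and per-cluster rank-sum differential enrichment.
- **Cell-type-adjusted differential expression** — per-gene quasi-Poisson
  GLMs (log link, size-factor offset, Wald t with Pearson dispersion) of each
  tumor type against non-tumor nuclei, with and without a major-cell-type
  covariate, and model comparison (adjusted-only / unadjusted-only /
  sign-discordant genes).
- **Direction concordance** — across T tumor-type contrasts, the expected
  proportion of genes moving the same direction in all T is 2/2^T (3.13% for
  T = 6) under the direction-permutation null; observed concordance is tested
  with a one-sample proportion test, and hypergeometric over-representation
  links concordant genes to pathways.

## Worked example

Simulate a degraded-staining pool (4 samples × 1,000 nuclei, 50% staining
efficiency, 5% doublets, 50 SNPs at mean depth 2) and demultiplex it both
ways:

```r
library(snpool)

cfg <- sim_config(n_samples_per_pool = 4, n_nuclei_per_sample = 1000,
                  hto_stain_efficiency = 0.5, doublet_rate = 0.05,
                  n_snps = 50, snp_depth_mean = 2, seed = 42)
sim <- simulate_pool(cfg)

hto <- classify_hto(sim$dataset$hto, sim$dataset$tag_map, seed = 42)
gt  <- assign_genotype(sim$dataset$allele, sim$dataset$genotypes,
                       eps = 0.01, delta = 0.05, tau = 0.9)
integrated <- integrate_calls(hto, gt)
summarize_yield(integrated, hto, gt)
#> demux_summary: kept 3873 nuclei (HTO-only method: 1993 , genotype-only method: 3803 )
#>   gain over HTO-only: +94.3%; over genotype-only: +1.8%
#>   CONCORDANT         1865
#>   HTO_ONLY           99
#>   GENOTYPE_RESCUE    1909
#>   DISCORDANT_DROP    29
#>   BOTH_UNDETERMINED  98
```

With only half the nuclei stained, the hashtag-only route keeps 1,993 of
4,000 nuclei; genotype rescue nearly doubles the yield (+94.3%) while
discarding the 29 nuclei the two methods disagree on. `sim$truth` carries
the true sample of origin, so accuracy of every route can be measured
directly.

The concordance statistics work from any per-type differential-expression
table; on the printed counts of a six-tumor-type comparison:

```r
expected_concordance(6)      # 2 / 2^6
#> [1] 0.03125
r <- proportion_test(340, 558, expected_concordance(6))
r$p_display
#> [1] "< 2.2e-16"
```

340 of 558 genes (60.9%) moving the same direction in all six contrasts is
far beyond the 3.13% expected under the direction-permutation null.

A complete run — simulate → QC → demultiplex → integrate → annotate →
enrich → DE (adjusted and unadjusted) → concordance — is one call:

```r
run_pipeline(run_config(seed = 1), "runs/demo")
```

which writes one CSV/JSON report per stage plus a log of per-stage counts
and seeds; reruns with the same config are byte-identical.

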