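# comorbnet

Comorbidity-pattern discovery in sex- and age-stratified disease networks.

## The problem

Chronic diseases cluster: patients who carry an index condition (here,
atopic dermatitis as the motivating case) accumulate comorbidities in
non-random combinations, and those combinations shift with sex and age.
`comorbnet` implements a network approach to finding them from routinely
coded diagnosis data:

1. **Records to matrices.** Long-format diagnosis records (patient, sex,
   age band, code) are filtered to chronic conditions and grouped into
   clinical categories through user-supplied lookup tables, yielding one
   binary patient x disease matrix per sex x age-band stratum. Age uses
   the five bands 0-2, 3-10, 11-17, 18-65, >65 years; with both sexes
   present this gives ten strata.
2. **Matrices to networks.** Within each stratum, diseases with prevalence
   > 1% become nodes. For every disease pair the package estimates the
   **tetrachoric correlation** — the correlation ρ of the latent bivariate
   normal assumed to underlie the two present/absent indicators — by
   maximum likelihood over the 2x2 table, with thresholds fixed at the
   marginal probits and cell probabilities from a built-in bivariate-normal
   orthant core:

   P(X > h, Y > k; ρ) = Q(h)Q(k) + (1/2π) ∫₀^ρ φ₂(h, k; r) dr.

   An edge joins a pair when the likelihood-ratio test of H₀: ρ = 0
   rejects at p < 0.01 (positive correlations only, by default); the edge
   weight is ρ̂.
3. **Networks to patterns.** Communities of each weighted network are
   extracted by an in-package **Louvain** implementation maximizing
   Newman-Girvan modularity
   Q = (1/2m) Σᵢⱼ (wᵢⱼ − sᵢsⱼ/2m) [cᵢ = cⱼ],
   with an exact brute-force oracle for small graphs backing it in the
   tests. Each community is a candidate comorbidity pattern, reported with
   its member diseases by prevalence and its strongest internal
   correlations.

Because real EHR cohorts of this kind cannot be shared, the package ships a
**synthetic cohort generator**: a latent multivariate Gaussian with a
planted block-correlation structure, thresholded at prevalence-matching
quantiles. The tetrachoric estimator is exactly the inverse of this
generator, so the whole chain can be validated end to end against known
ground truth.

## Worked example

A published AD cohort reports 50,801 patients, 46.3% men, with 5.9% of
patients aged 0-2. Reproducing the demographic table from its raw counts:

```r
library(comorbnet)
counts <- read.delim(system.file("extdata", "table1_demographics.tsv",
                                 package = "comorbnet"))
summarize_demographics(counts = counts)
#>   characteristic level n_total pct_total n_men pct_men n_women pct_women
#> 1            sex   Men   23522      46.3 23522   100.0       0       0.0
#> 2            sex Women   27279      53.7     0     0.0   27279     100.0
#> 3       age_band   0-2    3005       5.9  1605     6.8    1400       5.1
#> 4       age_band  3-10   17797      35.0  8954    38.1    8843      32.4
#> ...
```

A tetrachoric correlation from a 2x2 table — margins 1/2 and joint
presence 1/3 identify ρ = 0.5 exactly through the closed form
1/3 = 1/4 + arcsin(ρ)/(2π):

```r
estimate_tetrachoric(contingency_table(400, 200, 200, 400))
#> Tetrachoric correlation (maximum likelihood)
#>   rho = 0.5000 (se 0.0370)
#>   thresholds: tau_a = 0.0000, tau_b = 0.0000
#>   H0 rho = 0: LRT = 135.9192, p = 2.08e-31
```

And the full pipeline on a synthetic cohort with three planted disease
blocks (24 diseases, both sexes x five age bands):

```r
diseases <- do.call(rbind, lapply(1:24, function(i)
  disease_spec(sprintf("D%02d", i), prevalence = 0.05 + 0.2 * ((i-1) %% 8) / 7,
               block_id = (i-1) %/% 8 + 1)))
strata <- expand.grid(sex = c("M","F"), age_band = age_bands(),
                      stringsAsFactors = FALSE)
strata$n_patients <- 5000
spec <- cohort_spec(strata, diseases, rho_within = 0.5, seed = 11)
res <- run_pipeline(run_config(cohort = spec, seed = 11, out_dir = "out"))
#> stratum M:0-2: 24 nodes, 85 edges, 3 patterns, Q = 0.6609  (and 9 more)
```

The run writes one GraphML + GEXF network and one partition TSV per
stratum, a demographics CSV, and a per-pattern report; the three detected
patterns per stratum coincide with the planted blocks (adjusted Rand
index 1.0).

The `analysis/` directory contains the same workflow as four numbered
scripts (simulate → networks → patterns → demographics) writing their
tables under `results/`.

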