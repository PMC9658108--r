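---
title: "Comorbidity patterns from stratified disease networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity patterns from stratified disease networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

This vignette documents the statistical model behind `comorbnet`, the
parameters that matter, the design choices that were genuinely open, and
what the synthetic-cohort validation does and does not establish about real
data.

## The model

### Latent-threshold view of binary diagnoses

Every analysis in the package rests on one model: each patient's binary
disease indicators are thresholded latent Gaussians. For a pair of diseases
$(A, B)$, the latent vector $(X, Y)$ is standard bivariate normal with
correlation $\rho$; disease $A$ is present when $X > \tau_A$, where
$\tau_A = \Phi^{-1}(1 - p_A)$ and $p_A$ is the marginal prevalence. The
**tetrachoric correlation** is this $\rho$, and it is what edge weights
measure: the association of the underlying liabilities, free of the
attenuation that plagues product-moment correlations of rare binary traits.

The cell probabilities of the observed 2x2 table are orthant masses. The
package computes them with its own core, using the classical
single-integral reduction

$$P(X > h, Y > k;\ \rho) = Q(h)\,Q(k) + \frac{1}{2\pi} \int_0^{\rho}
\frac{\exp\!\left(-\frac{h^2 - 2 r h k + k^2}{2(1 - r^2)}\right)}
{\sqrt{1 - r^2}}\, dr,$$

after the substitution $r = \sin\theta$, which removes the endpoint
singularity and makes the integrand bounded and smooth. A fixed-order
Gauss-Legendre rule (order 64) then delivers absolute accuracy far below
the contracted $10^{-8}$ over $|\rho| \le 0.999$; at $h = k = 0$ the
substituted integrand is constant, so the quadrature reproduces the
closed form $1/4 + \arcsin(\rho)/(2\pi)$ exactly. That closed form doubles
as an independent check in the test suite.

### Estimation

`estimate_tetrachoric()` is the standard two-step tetrachoric estimator:
thresholds are fixed at the marginal probits (profiled out, keeping the
optimization one-dimensional), and $\rho$ maximizes the multinomial
log-likelihood of the four cells. Optimization is Brent search on
$[-0.999, 0.999]$ followed by a safeguarded Newton polish on the analytic
score — the derivative of the orthant probability with respect to $\rho$
is the bivariate normal density (Plackett's identity), so the score is
available in closed form and the gradient at the returned optimum is
numerically zero. The standard error comes from the observed information
in $\rho$.

Numerical choices for degenerate inputs:

* **Empty cells.** The unrestricted MLE diverges when a cell is empty, so
  such tables receive a continuity correction of $+0.5$ on every cell
  (flagged `corrected`), and the estimate is clamped to
  $[-0.999, 0.999]$. A perfectly concordant table therefore reports
  $\hat\rho = 0.999$, not 1.
* **Degenerate margins.** A disease present in 0 or all patients
  identifies nothing; estimation refuses with an error telling the caller
  to drop the pair. The network builder treats such failures as skipped
  pairs, never as fatal.

### Significance and the edge rule

The test of $H_0: \rho = 0$ is the likelihood-ratio statistic
$2\{\ell(\hat\rho) - \ell(0)\}$ on $\chi^2_1$. A Wald test or the Pearson
chi-square on the same table would be asymptotically equivalent; the LRT
was chosen because it is internal to the ML machinery and needs no extra
approximation, and the Pearson variant is exposed
(`test_rho_zero(..., method = "pearson")`) for sensitivity analysis. Under
independent median-split pairs ($n = 1000$), the LRT rejects at the 0.01
level at an empirically calibrated rate of about 1% (measured at 0.99%
over 10,000 simulated tables in development; the acceptance suite
re-measures it on 2,000).

Edges require $p < \alpha$ with $\alpha = 0.01$, the conventional
stricter-than-0.05 guard against the multiplicity of
$\binom{D}{2}$ tests; a formal FWER procedure is deliberately not applied
(a Bonferroni-style correction can be had by passing a smaller `alpha`).
By default only **positive** significant correlations become edges:
comorbidity patterns are co-occurrence structures, and modularity on
signed graphs is a different method. `include_negative = TRUE` admits
negative edges carrying $|\hat\rho|$ as weight for users who want to see
exclusion structure; the Louvain module will then refuse only if a raw
negative weight reaches it.

Node inclusion uses **strict** prevalence > `min_prevalence` (default 1%):
11/1000 patients qualifies, 10/1000 does not. The filter is applied per
stratum — each stratum's own 1% — since each network is built from its own
population; a cohort-wide alternative would keep node sets identical
across strata at the cost of letting one large stratum dictate the others'
nodes.

## Community detection

Patterns are communities under weighted Newman-Girvan modularity at
resolution 1,

$$Q = \frac{1}{2m} \sum_{ij} \left(w_{ij} - \frac{s_i s_j}{2m}\right)
[c_i = c_j],$$

optimized by an in-package Louvain implementation: repeated single-node
moves to the neighboring community with the largest positive gain
(including the option of detaching into a fresh singleton), then
aggregation of communities into super-nodes, iterated until a full pass
improves $Q$ by less than $10^{-10}$. Ties keep the current community,
otherwise take the lowest community id; node visit order is shuffled under
the caller's seed; internally nodes are processed in name-canonical order,
so the result is equivariant under node relabelling. Aggregation is exact
under the package's weight-matrix convention (self-loops carry the full
internal weight), and the implementation asserts, at every level, both the
monotone improvement of $Q$ and the identity between the aggregated and
full-graph modularity.

Louvain is a greedy heuristic. On tiny graphs its failure mode is visible
and quantifiable: a brute-force oracle (`brute_force_best_partition()`,
exhaustive enumeration over all set partitions, practical to 10 nodes)
shows that single seeded runs reach the exact optimum on most but not all
random 4-8-node graphs, and on rare graphs the optimum is a fixed point
unreachable from the all-singletons start by any move sequence —
independent Louvain implementations cap at the same local optimum. For
this reason `louvain()` exposes `n_restarts`: best-of-20 restarts is the
package's recommendation for small graphs (milliseconds of work), and the
pipeline uses best-of-5 per stratum. Leiden-style refinement is out of
scope.

Isolated (edge-less) nodes are retained as singleton communities, so every
prevalent disease appears in exactly one reported pattern. Naming the
patterns clinically is intentionally left to humans; the package emits,
per community, the member diseases sorted by prevalence and the strongest
internal correlations as raw material for that judgment.

## The synthetic cohort generator

`generate_cohort()` exists because cohorts of linked EHR diagnoses are
generally not shareable. It draws, per stratum, $n$ i.i.d. latent vectors
$Z \Sigma^{1/2}$ (upper Cholesky factor, column-major normal fill — the
documented stream order of the seed contract) with
$\Sigma_{jk} = \rho_{\text{within}}$ for same-block pairs,
$\rho_{\text{between}}$ otherwise, and thresholds disease $j$ at
$\Phi^{-1}(1 - p_j)$. Strata use independent substreams derived
deterministically from the master seed and the stratum label, so cohorts
are reproducible under stratum subsetting. Specs whose implied $\Sigma$ is
not positive definite are rejected up front.

Default study conditions used by the analysis scripts and the acceptance
suite: 24 diseases in 3 equal blocks, prevalences spread over 5-25% (all
clear the 1% filter), $\rho_{\text{within}} = 0.5$,
$\rho_{\text{between}} = 0$, both sexes by five age bands, 5,000 patients
per stratum for recovery benchmarks (the `analysis/` scripts use a
1:10-scale cohort whose stratum sizes follow the published cohort's
sex-by-age distribution). The published study reports only one correlation
magnitude (a near-ceiling 0.99 between two respiratory conditions), so
0.5 is a package choice of a realistically strong latent association, not
an estimate from data.

The generator is deliberately the exact inverse of the tetrachoric
estimator — same latent model, same thresholds — which is what makes
end-to-end parameter recovery a meaningful test: estimated edge weights
converge to the planted $\rho_{\text{within}}$, and Louvain on the
resulting networks recovers the planted blocks (ARI 1.0 at $n = 5000$ per
stratum). What passing these tests does **not** show: robustness to
violations of latent normality, to diagnosis codes arriving with
care-seeking or coding biases, to within-patient correlation of
measurement error, or to longitudinal onset structure — none of which the
generator emulates. Results on real data inherit the usual caveats of
cross-sectional EHR analysis.

## Record grouping conventions

* The chronic-condition flag and clinical-category grouping are **user
  data**: the package ships only toy fixtures and a documented TSV schema
  (`code`, `chronic_flag`; `code`, `category_id`, `category_label`).
  Licensing and versioning of the standard ICD-9-CM tables live with their
  distributors. ICPC-1 codes pass through the same interface with a
  user-supplied table; no automatic conversion is attempted.
* Age bands are consumed pre-assigned; `assign_age_band()` bands raw ages
  with inclusive integer bounds [0,2], [3,10], [11,17], [18,65], (65,∞) —
  boundary inclusivity is a convention fixed and documented here.
* A patient whose rows disagree on sex or age band is a hard error, not a
  first-seen-wins silent choice; malformed rows and unmapped codes go to
  explicit reports.
* The index condition that defines the cohort should be excluded from the
  matrices (`exclude_categories`); a node present in ~100% of patients has
  degenerate margins and estimates nothing.

## Problem sizes

The test suite and acceptance script run at: 2,000 simulated tables of
$n = 1000$ for null calibration; 10 seeds x $n = 20{,}000$ median-split
pairs per true $\rho$ for consistency; 50 random ≤8-node graphs against
the brute-force oracle; and one 10-stratum cohort at $n = 5000$ per
stratum (50,000 patients, 24 diseases) for end-to-end recovery. These
sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite completes in about a minute.
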