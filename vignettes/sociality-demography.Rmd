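---
title: "From matrix population models to a sociality continuum: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From matrix population models to a sociality continuum: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demosoc)
```

`demosoc` links a five-level sociality continuum (solitary, gregarious,
communal, colonial, social) to the demography of animal species. The raw
material is one matrix population model (MPM) per species, `A = U + F`,
where `U` holds stage-specific survival and transitions and `F`
reproduction, with columns indexing the source stage and rows the
destination (`A[i, j]` is the per-capita contribution of stage `j` to
stage `i` over one projection interval `P`). From each model the package
derives life-history traits, stable-structure-weighted vital rates,
elasticities of the population growth rate, and transient metrics, and
then asks — with body mass and phylogeny controlled — whether these vary
along the sociality continuum.

## Preparing the models

Studies are filtered before any demography is computed: only
unmanipulated wild populations, matrices of dimension at least 4 (enough
stage resolution to see age patterns and avoid mortality/fertility
plateaus), an available `U`/`F` split, stage survival column sums at most
1, and extant species. When one species has several studies,
`select_study()` keeps the longest study, breaking ties by matrix
dimension; `grand_mean()` then averages the chosen study's matrices
element-wise. Models with `P != 1` are annualized by raising every
element to `1/P`, so all traits share yearly units. Element-wise powers
are a deliberate approximation: they do not commute with matrix
multiplication, and for columns whose survival is spread across many
destinations the rescaled column sum can exceed 1, in which case
validation fails loudly rather than producing inflated longevities.

Elasticities and the asymptotic/transient metrics require a single, real,
strictly dominant eigenvalue. `check_ergodicity()` therefore gates them
behind three conditions: irreducibility (the life-cycle graph is strongly
connected), primitivity (aperiodicity, tested with Wielandt's bound
`A^(n^2-2n+2) > 0`), and ergodicity (strictly positive left eigenvector).
Life-history traits are computed regardless, because they depend only on
`U` and `F`.

## Age from stage

All life-history traits rest on collapsing the stage description into age
schedules. A cohort with entry distribution `c` has survivorship
`lx(x) = 1'U^x c` and fertility `mx(x) = 1'F U^x c / lx(x)`, and the
fundamental matrix `N = (I - U)^{-1}` gives the expected time spent in
each stage before death. Ages count projection intervals with age 0 at
the first census, so a cohort certain to die before its second census has
life expectancy exactly 1. Two choices here are genuinely open and are
made explicitly:

* **Cohort entry stage.** The source data do not state where offspring
  enter the life cycle. `default_start_distribution()` places all mass on
  the row of `F` receiving the largest reproductive inflow (ties go to
  the first such stage) — the stage newborns are actually projected into.
* **Truncation.** Schedules run to `xmax = 1000` intervals with an early
  stop once `lx < 1e-7`; shape metrics are additionally truncated at the
  `L_max` age (first age with more than 99% of the cohort dead, strict
  inequality) so plateau tails cannot bias them.

The eleven traits are generation time `T`, net reproductive output `R0`
(dominant eigenvalue of `F N`), mean and variance of life expectancy from
the absorbing-chain moments, maximum longevity `L_max`, age at maturity
`L_alpha` and maturity probability `p_R` (from the chain in which
reproductive stages — columns of `F` with positive sum — are made
absorbing), the reproductive window `L_alpha_omega` (mean remaining life
expectancy at first maturity), the survivorship and reproduction shape
statistics `s_lx`, `s_mx`, and the degree of parity `S`.

Three of these deserve detail:

* **Generation time.** No formula is canonical; the default is
  `T = log(R0) / log(lambda)`, consistent with the `R0`/`lambda`
  machinery already required, with the mean age of mothers at the stable
  structure (`T = lambda v'w / v'Fw`) available via `method = "abar"`.
  When `lambda = 1` and `R0 = 1` simultaneously the ratio is 0/0 and the
  trait is flagged missing.
* **Shape statistics.** Both standardize age to `[0, 1]` and compare a
  curve with its constant-rate reference, so both live in
  `[-0.5, +0.5]`. For survivorship the curve is
  `g = log lx / log lx_last` and `s_lx = 0.5 - integral(g)`: exponential
  decline maps to exactly 0, senescence to positive values. For
  reproduction the cumulative curve is anchored at zero *before* the
  first age (grid `x = 0..n`, `M(x) = sum of mx below x`), which is what
  makes a constant schedule map to exactly 0 rather than to a `1/(2n)`
  grid artefact; `s_mx = integral(M/M_total) - 0.5`.
* **Degree of parity.** Shannon entropy (natural log, `0 log 0 = 0`) of
  the normalized age distribution of reproduction `lx mx`; strict
  semelparity gives exactly 0, uniform spread over `k` ages `log k`. The
  entropy is not discounted by population growth — discounting would
  break the exact semelparity anchor.

## Perturbation and transients

Vital rates are read off the columns of `U`: survival `sigma_j` is the
column sum, growth `gamma_j` the below-diagonal share of the column
conditional on survival, shrinkage `rho_j` the above-diagonal share, and
reproduction `phi_j` the column sum of `F`; stage order is taken from the
stage label sequence, and the diagonal (stasis) belongs to neither growth
nor shrinkage. Averages weight stages by the stable distribution `w`,
renormalized over stages with positive survival for the conditional
rates.

Element elasticities are `e_ij = a_ij v_i w_j / (lambda v'w)` and sum to
1. How elasticities to the four *vital rates* aggregate across stages is
not uniquely defined; the package differentiates through the column
parameterization: a survival perturbation scales a whole `U` column
(`E_sigma` is the sum of element elasticities over `U`), reproduction
scales `F` columns, and growth (shrinkage) perturbations scale the
below- (above-) diagonal conditional mass with compensation on the
diagonal so survival stays fixed. This choice is validated against
central finite differences of `lambda` under exactly the same
perturbations (relative step `1e-6`, agreement within `1e-4` across
thousands of random gated matrices).

Transients use the subdominant eigenvalue `lambda_2` (second-largest
modulus; of a conjugate pair, the member with positive imaginary part):
damping ratio `zeta = lambda/|lambda_2|`, period of oscillation
`2*pi/|arg lambda_2|` (infinite when `lambda_2` is real positive), and
the one-step amplification envelope of `A/lambda` — reactivity and
first-step attenuation as the maximum and minimum column sums. These are
invariant to uniform rescaling of `A` and bracket 1 by construction.

## Comparative statistics

The phylogenetic machinery is standard Brownian-motion (BM) theory on an
`ape` tree: `C[i, j]` is the shared root-to-MRCA path length, and Pagel's
lambda scales the off-diagonal of `C`. `fit_pagel_lambda()` maximizes the
profile GLS likelihood over `lambda` in `[0, 1]` (boundary values are
checked explicitly since the optimum is often at 0 or 1) and reports a
95% profile-likelihood interval (drop of 1.92 log-units, truncated at the
boundaries). Every trait is residualized over log body mass (grams,
natural log) by this PGLS before any group comparison, removing the
allometric confound.

The phylogenetic ANOVA is simulation-based: the observed one-way F is
compared with `nsim` F statistics from BM data simulated on the tree, at
the REML rate estimated from the residuals under a mean-only model, with
the add-one continuity correction `p = (1 + #{F* >= F}) / (nsim + 1)`.
Pairwise post hoc t statistics are referred to the same simulated null
(two-sided) and summarized as compact letters (insert-and-absorb).
Sociality enters as an unordered 5-level factor — the ordering of the
continuum is interpretive and the F test does not use it. On a star tree
the procedure converges to the classical F test. Bonferroni correction is
applied across the traits tested in one run.

For the multivariate view, time-based traits are screened in three steps
mirroring the univariate/multivariate split of the analysis: Spearman
pruning (one member of any pair with `|rho| > 0.70` is dropped — the one
with more missing data, ties resolved by the canonical trait order),
a strict `< 40%` missingness screen, log-transformation and PGLS
residualization, scaling to mean 0 / variance 1, and imputation. The
phylogenetic PCA then uses the GLS mean and the evolutionary covariance
`R = (X - 1a)' C^{-1} (X - 1a)/(n - 1)` with `C` at the jointly
ML-estimated lambda; axes with eigenvalue above 1 are retained (Kaiser,
meaningful because columns are standardized). Scores are uncorrelated in
the `C^{-1}` metric by construction.

Imputation follows the iterative-PCA description: initialize missing
cells with column means, reconstruct with `ncomp = 2` components
(matching the retained PCA axes) whose singular values are
ridge-shrunk by the noise variance estimated from the trailing spectrum,
replace only the missing cells, iterate to relative tolerance `1e-6`
(cap 1000, non-convergence flagged rather than thrown). Twenty
imputation sets are generated by perturbing imputed cells with
column-wise residual noise; downstream results use the converged point
estimate, and the between-set spread of PCA scores is reported in the run
manifest. During imputation the complete demographic-summary columns and
log body mass are appended as auxiliary variables (and discarded after),
so the trait reconstruction can borrow strength from the rest of the
dataset; `impute_with_auxiliary = FALSE` disables this. Univariate tests
never see imputed values — species with a missing trait are dropped and
the tree pruned per trait.

## The synthetic generator

`make_dataset()` emulates the statistical structure of the real
comparative data so every stage is testable without downloads: a
birth-death tree rescaled to unit depth; a latent-liability sociality
continuum with Pagel's lambda 0.9 (the strong signal regime reported for
the real continuum) thresholded at empirical quintiles; log-normal body
masses with phylogenetic signal; and four-stage Lefkovitch models per
species whose adult survival embeds
`log T = a + 0.25 log(mass) + group effect + BM noise` — quarter-power
allometric scaling as the default link — with fertility tuned so `R0`
fluctuates around 1. Missing data are masked completely at random at rate
0.15, mirroring the gaps of the real trait table; the generator does not
model informative missingness, multi-study species, non-annual projection
intervals, or the real tree's taxonomic imbalance, so passing tests
establish correctness of the machinery, not realism of any particular
biological conclusion. Ground-truth traits of the no-shrinkage archetype
(life expectancy, `R0`, maturity probability and age) are computed from
independent closed forms of the forward chain and attached to each model.

## Numerical choices and limitations

* Decomposition and survival-sum tolerance `1e-9` (published MPMs carry
  at most 6 significant digits); eigen-identities checked at `1e-8`.
* `L_max` uses the strict inequality `lx < 0.01` ("more than 99% dead").
* Degenerate inputs are flags, not crashes: sterile models yield `NA`
  reproductive traits, gate failures yield `NA` summaries with a
  `gate_reason`, and all `NA`s propagate as missing data downstream.
* Test problem sizes are chosen to give tight Monte-Carlo error at
  interactive runtimes: 200 000-individual cohorts for the lifespan
  oracle, 10 000 random matrices for the elasticity identity, 500
  replicates at `nsim = 500` for the ANOVA calibration, 200 replicates
  of 150-tip trees for signal recovery.
* Known limitations: no clonality sub-matrix, no stochastic-environment
  growth rates, no Kreiss bounds or all-horizon amplification envelopes,
  no chained-equations imputation, and polytomies are treated as hard.

## A worked run

```{r example, eval = FALSE}
study <- make_dataset(n_species = 120, seed = 1,
                      effect_profile = list(group_T = c(0, 0, 0.4, 0.8, 1.2)))
cfg <- pipeline_config(study, output_dir = "demo_run", seed = 1,
                       nsim = 1000)
res <- run_pipeline(cfg)
report_table1(res$table1)
res$ppca
```

The Table-1-style output groups traits into five blocks (life history,
vital rates, elasticities, asymptotics, transients) with `R2`, `F`,
conventional d.f. `(k - 1, n - k)`, simulation p-values before and after
Bonferroni, and the PGLS Pagel's lambda with its profile CI; the post hoc
letter files are the boxplot-annotation analogues, and the PCA files hold
loadings, scores and percent variance per axis.
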