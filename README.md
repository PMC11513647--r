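# demosoc

Comparative demography of social living. `demosoc` asks whether species
that are more social — along a five-level continuum from *solitary*
through *gregarious*, *communal* and *colonial* to *social* — differ
demographically from less social ones, once adult body mass and shared
ancestry are controlled. It is aimed at comparative ecologists working
with stage-structured matrix population models (MPMs) and a phylogeny.

The package implements the full analysis chain:

1. **MPM handling** — validation of the `A = U + F` decomposition
   (columns = source stage, survival column sums ≤ 1), study-selection
   filters (wild/unmanipulated, dimension ≥ 4, U/F split, survival ≤ 1,
   extant), annualization (`a_ij^(1/P)`), element-wise grand means, and
   the irreducibility/primitivity/ergodicity gate.
2. **Demographic traits** — eleven life-history traits via age-from-stage
   schedules and absorbing Markov chains: generation time
   `T = log R0 / log λ`, net reproductive output `R0` (dominant
   eigenvalue of `F(I−U)⁻¹`), mean/variance of life expectancy from the
   fundamental matrix `N = (I−U)⁻¹`, maximum longevity (first age with
   `lx < 0.01`), age at and probability of maturity, reproductive
   window, the survivorship/reproduction shape statistics (bounded in
   `[−0.5, 0.5]`, 0 = constant rates) and the degree of parity (Shannon
   entropy of the age distribution of reproduction; 0 = semelparity).
3. **Perturbation & transients** — stable-structure-weighted vital rates
   (σ, γ, ρ, φ), element elasticities `e_ij = a_ij v_i w_j/(λ v'w)` and
   their vital-rate aggregates (validated against finite differences),
   damping ratio `λ/|λ₂|`, period of oscillation `2π/|arg λ₂|`, and the
   one-step reactivity/attenuation envelope of `A/λ`.
4. **Phylogenetic statistics** — maximum-likelihood Pagel's λ with
   profile-likelihood CIs, PGLS residuals over log body mass,
   simulation-based phylogenetic ANOVA with post hoc letters, Spearman
   pruning (> 0.70), a < 40% missingness screen, regularized
   iterative-PCA imputation (20 sets), and a phylogenetic PCA with
   Kaiser retention.
5. **Synthetic data** — generators for trees, sociality continua, body
   masses and Lefkovitch MPMs with closed-form ground truth, so the whole
   pipeline is testable end-to-end without external databases.

## Worked example

```r
library(demosoc)

# a 120-species study in which more social species live longer
study <- make_dataset(n_species = 120, seed = 1,
                      effect_profile = list(group_T = c(0, 0, 0.4, 0.8, 1.2)))
cfg <- pipeline_config(study, output_dir = "demo_run", seed = 1, nsim = 1000)
res <- run_pipeline(cfg)
head(report_table1(res$table1), 5)
```

```
                 type     trait    R2       F   d.f.        p p_bonferroni pagel_lambda   lambda_ci
1 life history traits         T 0.837 128.480 4, 100 0.000999       0.0230        0.694  0.442-0.87
2 life history traits        R0 0.012   0.297  4, 94 0.965000       1.0000        0.000     0-0.193
3 life history traits     eta_e 0.254   7.730  4, 91 0.012000       0.2760        0.089      0-0.34
4 life history traits var_eta_e 0.604  34.356  4, 90 0.000999       0.0230        0.398 0.063-0.751
5 life history traits     L_max 0.785  87.822  4, 96 0.000999       0.0230        0.505 0.198-0.778
```

Each row is one demographic trait: `F` and `p` come from the
body-mass-corrected phylogenetic ANOVA of the trait's PGLS residuals on
the sociality factor (p simulated under Brownian motion on the tree,
then Bonferroni-corrected), and `pagel_lambda` is the phylogenetic
signal of the PGLS fit. Here the planted longevity effect surfaces in
generation time, life-expectancy variance, maximum longevity and the
reproductive window, while `R0` and maturity traits stay at the null —
as constructed. The post hoc letters show where along the continuum the
effect sits:

```r
subset(res$letters, trait == "eta_e")
```

```
  trait      level letters
  eta_e   solitary       a
  eta_e gregarious       a
  eta_e   communal      ab
  eta_e   colonial      ab
  eta_e     social       b
```

Groups sharing no letter differ at p < 0.05: social species have longer
mass-corrected life expectancy than solitary and gregarious ones.
Per-species traits, summaries, PCA loadings/scores and a JSON manifest
(seed, filter counts, gate failures, imputation diagnostics) are written
to the output directory.

Single models work the same way without the pipeline:

```r
gl <- validate_mpm(matU = matrix(c(0, 0.5, 0, 0), 2),
                   matF = matrix(c(1, 0, 2, 0), 2))
compute_all_traits(gl)
#>         T R0 eta_e var_eta_e L_max L_alpha L_alpha_omega p_R s_lx s_mx         S
#>   1.44042  2   1.5      0.25     2       0           1.5   1   NA   NA 0.6931472
demographic_summary(gl)[c("lam", "zeta", "Pi", "reactivity")]
#>        lam     zeta Pi reactivity
#>   1.618034 2.618034  2   1.236068
```

This is the golden-ratio Leslie matrix: λ = (1+√5)/2, two offspring per
lifetime (`R0 = 2`), damping ratio λ/|λ₂| ≈ 2.618, a period-2 transient
oscillation, and shape statistics flagged `NA` because only two ages
carry positive survivorship.

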