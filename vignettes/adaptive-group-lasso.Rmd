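---
title: "Adaptive group lasso for SNP main effects and epistatic interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive group lasso for SNP main effects and epistatic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control association studies genotype N individuals (N_d cases, N_u
controls) at L bi-allelic markers and ask which markers influence disease
risk.  Two kinds of signal matter: *main effects*, where a single SNP
shifts risk on its own, and *epistatic interactions*, where a pair of SNPs
carries signal jointly that neither carries marginally.  With L in the
thousands and all L(L-1)/2 pairs as candidates, the model space dwarfs the
sample size, so `aglsnp` casts detection as penalized variable selection in
a logistic regression.

A SNP has three genotypes (AA, Aa, aa), so it is treated as a three-level
factor coded with three indicator (dummy) variables — `[1 0 0]` for AA,
`[0 1 0]` for Aa, `[0 0 1]` for aa — rather than as a single additive dose.
A SNP pair is a nine-level factor with nine indicators.  This factor coding
is deliberately assumption-free: additive, dominant, recessive and
interference-type effects are all linear in the dummies, so no genetic
model has to be presumed.  The cost is that selection must act on whole
factors, which is exactly what the group lasso does.

## The model

Write $X_j$ for the $N \times p_j$ indicator block of group $j$ ($p_j = 3$
for a SNP, $p_j = 9$ for a pair) and $\beta_j$ for its coefficients.  The
fitted model minimizes

$$
-\ell(\beta_0, \beta) \;+\; \gamma \sum_j w_j \sqrt{p_j}\, \lVert \beta_j \rVert_2 ,
$$

where $\ell$ is the Bernoulli log-likelihood
$\sum_i [y_i \eta_i - \log(1 + e^{\eta_i})]$ with
$\eta_i = \beta_0 + \sum_j X_{ij} \beta_j$, the intercept is unpenalized,
$\gamma \ge 0$ trades likelihood against sparsity, and $w_j > 0$ are
per-group weights.  The $\sqrt{p_j}$ multiplier is the standard group-lasso
scaling; it also penalizes pair groups more heavily than main groups
($\sqrt 9 = 3$ vs $\sqrt 3$), which discourages an interaction from
entering when the same variation is explained by main effects.  The
*active set* is $\mathcal{A} = \{ j : \beta_j \ne 0 \}$.

The main-effect model uses only the L SNP groups; the interaction model
additionally includes all admitted pair groups (every unordered pair by
default; `pair_filter` supports external pre-screening).  Interaction is
defined as departure from the main-effects model: the evidence for a pair
is the likelihood gap between a model containing its nine-level block and
one containing only the two three-level blocks.  This definition drives
both the model structure and the tests below.

## Optimization

The solver (`fit_group_lasso`) is a proximal-Newton scheme: at each outer
iteration the log-likelihood is replaced by its IRLS quadratic
approximation with working weights $u_i = \hat p_i (1 - \hat p_i)$ (floored
at `1e-5`), and the quadratic subproblem is solved by block coordinate
descent over groups.

A structural fact makes the block update exact and cheap: each block is a
one-hot indicator matrix, so a sample contributes to exactly one column
and the weighted within-group Gram matrix $X_j^\top U X_j$ is *diagonal*.
The penalized block subproblem
$\min_b \tfrac12 b^\top M b - c^\top b + \lambda_j \lVert b \rVert_2$
with diagonal $M$ then has the solution $b_k = c_k / (m_k + \lambda_j /
t)$, where $t = \lVert b \rVert$ solves a monotone one-dimensional
equation (solved by bisection to machine precision), and $b = 0$ exactly
when $\lVert c \rVert_2 \le \lambda_j$ — the group soft-threshold.  No
within-group orthonormalization is needed, and the penalty is applied to
the original coefficients throughout, so the solver optimizes the stated
objective exactly.  Because the three dummies of a group sum to one, the
blocks are collinear with the intercept; the penalty resolves this
indeterminacy and the diagonal subproblem never requires a matrix inverse.

Three devices keep the interaction model (hundreds of thousands of groups)
tractable without changing the optimum:

* **Working set + KKT sweeps.** Only groups that are active or violate
  their subgradient bound $\lVert X_j^\top (y - \hat p) \rVert_2 \le
  \gamma w_j \sqrt{p_j}$ are cycled; convergence is certified by a full
  sweep over all groups, and violators are pulled in until none remain.
* **Line search.** The Newton direction is step-halved until the true
  penalized objective does not increase, making the objective
  non-increasing across outer iterations by construction.
* **Path truncation (`dfmax`, default 50 groups).** Along a descending
  penalty path, grid points whose model grows beyond `dfmax` groups are
  abandoned.  With N in the hundreds, fifty groups already mean
  150–450 coefficients — a saturated model that cross-validation never
  selects; abandoning that region costs nothing statistically and most of
  the running time.  Single fits requested directly are never truncated.

Tolerances: coefficient-change `1e-5` for the outer loop, a tenth of that
for coordinate passes, caps of 50 outer iterations and 100 passes; all
exposed in `agl_control()` and recorded per fit.

## Penalty selection and adaptive reweighting

`cv_select_gamma` builds a log-spaced grid of 25 values from
$\gamma_{\max}$ (the smallest penalty with an empty model, computed in
closed form) down to $0.05\,\gamma_{\max}$, fits warm-started paths on
stratified five-fold splits, and scores validation deviance
(misclassification is available as `cv_loss = "class"`; the choice of loss
is a genuinely open design point and deviance is the default because it
matches the fitted likelihood).  Among penalties within one standard error
of the minimum, the largest (sparsest) is chosen.

`adaptive_fit` runs the reweighting loop: iteration 0 fits with all
weights 1 and a cross-validated penalty; then each active group's weight
becomes $w_j = \lVert \hat\beta_j \rVert_2^{-1}$ (small estimate, heavy
penalty), inactive groups are removed for good, and the model is refit —
with the penalty re-selected by cross-validation each iteration, since the
weight scale changes.  The loop stops when the active set repeats between
consecutive iterations (cap 10).  Two points here were underdetermined and
are settled as package defaults: the weight update is the reciprocal norm
with a configurable exponent (`weight_power`), the canonical adaptive
choice consistent with "smaller estimate, larger penalty"; and
cross-validation is repeated every iteration (`recv_gamma = FALSE` reuses
iteration 0's penalty for speed).

## Significance assessment

Selection is not inference: noise groups survive reweighting occasionally,
so every selected group is tested.  Because dummy blocks are collinear,
the refits maximize $\ell(\beta) - \tfrac{\text{ridge}}{2}\lVert\beta\rVert^2$
with ridge $10^{-4}$ (intercept unpenalized), which is strictly concave and
safe on any block structure.  The effective model size of a ridge fit is

$$
\mathrm{df} = \operatorname{tr}\!\big[(\tilde X^\top U \tilde X + \Gamma)^{-1}
\tilde X^\top U \tilde X\big],
$$

with $\tilde X$ including the intercept column, $U = \mathrm{diag}(\hat
p_i(1 - \hat p_i))$ at convergence, and $\Gamma$ diagonal with 0 on the
intercept and the ridge on every other coefficient.  $\Gamma$ must have
one entry per *coefficient* (not per SNP) for the trace to type-check;
that is the convention implemented.  As the ridge vanishes the df tends to
the column rank (3 for one SNP's dummies plus intercept, i.e. 2 per
additional SNP), and as it grows the df tends to 1.

* `test_main_effects`: the full model holds all selected SNPs; for each
  SNP the reduced model drops its block.  The statistic
  $2(\ell_{full} - \ell_{\setminus j})$ is referred to
  $\chi^2_{\mathrm{df}_{full} - \mathrm{df}_{\setminus j}}$ (real-valued
  df, about 2 per SNP, via the continuous gamma-function form of the
  chi-square).
* `test_interactions`: for each selected pair the reduced model replaces
  its nine-dummy block with the two three-dummy main blocks of its SNPs
  (deduplicated if already selected), all other groups untouched.  Each
  main block lies in the pair block's column span, so the reduced model is
  nested and the statistic is non-negative up to round-off (about 4 df per
  pair).  This realizes the departure-from-main-effects definition of
  interaction.

P-values are Bonferroni-corrected by the size of the searched hypothesis
space: L for the main-effect model, $L + L(L-1)/2$ for the interaction
model.  The denominator is not dictated by the procedure itself; this
conservative choice makes the null-design arithmetic come out at
$10^6 \cdot t / L$ false positives per million SNPs at corrected threshold
$t$, and is overridable.  The default declaration threshold is 0.3 after
correction, matching common practice for this class of epistasis
detectors.  Note the p-values are post-selection: they are computed for
groups that survived the adaptive fit, and their calibration is checked
empirically by the null experiment rather than asserted theoretically.

## The simulators

`simulate_case_control` draws the two disease-locus genotypes jointly
under Hardy-Weinberg equilibrium (independent loci), assigns disease by a
Bernoulli draw from the 3x3 penetrance table, and accumulates by rejection
until the case and control quotas are met exactly (capped at $10^7$
attempts so degenerate tables fail fast).  Noise SNPs are independent of
phenotype with per-SNP MAFs uniform in [0.05, 0.5].  Genotypes are always
coded 0/1/2 as minor-allele counts.  `simulate_null` draws every SNP
independently and assigns a balanced phenotype independent of genotype.

Penetrance models: `build_table1_model` constructs the multiplicative
(M1-1) and interference (M1-2) families from a baseline penetrance
$\alpha$ and effect size $\theta$ (defaults document $\alpha = 0.05$;
$\theta$ is chosen per run, e.g. swept for power curves).
`table2_model` returns four fixed pure-epistasis tables (M1-3 … M1-6,
both MAFs 0.4) whose heritabilities
$h^2 = \sum_g P(g)(f(g) - K)^2 / K(1-K)$ computed from the tables are
0.30, 0.20, 0.10 and 0.05.  `prevalence` and `heritability` give these
summaries for any model.

What the generator deliberately does *not* emulate: linkage
disequilibrium (all loci are independent), missing genotypes (rejected,
not imputed), covariates, quantitative traits, and genetic heterogeneity.
Consequently the simulation results say nothing about LD-induced
redundancy (where a proxy SNP can absorb a causal signal) or
population-structure confounding; on real data those effects make the
procedure conservative at best and must be handled upstream.

## Experiment harnesses and problem sizes

`run_type1_experiment` and `run_power_experiment` reproduce the two
simulation studies at configurable scale.  The `"paper"` presets use the
full study conditions (100 null datasets of 10,000 SNPs x 1,000 samples;
100 case-control replicates of 1,000 SNPs with 200 cases and 200
controls).  The `"desk"` presets — 10 null datasets of 2,000 SNPs x 500
samples, and 20 replicates of 200 SNPs for power — are the sizes used by
the package's own checks; they preserve the per-dataset structure while
keeping a full run in the minutes range on one core.  At desk scale the
expected null event counts are below one, so the type-I check asserts a
generous bound (at most 60 per million at threshold 0.3, holding the
full design's Bonferroni factor of 10,000) rather than the
full-scale rates; the full-scale run is available behind
`--scale paper`.  Power is scored as the truth pair being *significant*
(not merely selected) at the corrected 0.3 threshold; for main-effect
power a config flag chooses between requiring both disease SNPs or at
least one.  Dataset d of a harness uses root seed + d, fits never see the
truth, and every report is reproducible from its config and seed.

## Known limitations

* The interaction model over all pairs is quadratic in L; beyond a few
  hundred thousand pairs a pre-filter (`pair_filter`) is required.
* Post-selection p-values are validated by simulation, not theory; with
  strong LD they are conservative in a way the null design cannot probe.
* The reciprocal-norm weight update is a one-parameter family
  (`weight_power`); no attempt is made to verify oracle-property theory
  empirically beyond parameter recovery.
* Missing genotypes abort the analysis by design; imputation is out of
  scope.
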