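---
title: "Phylogenetic mixed models for feather hydrogen isotopes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic mixed models for feather hydrogen isotopes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofeather)
```

## The scientific problem

Feather stable hydrogen isotope ratios (δ²H_f, per mil on the VSMOW-SLAP
scale) are the workhorse marker for assigning migratory songbirds to a
molt (usually breeding) origin: growing-season precipitation δ²H varies
predictably in space, and a transfer function maps the precipitation value
at a location to the δ²H_f expected of a feather grown there. Assignment
accuracy therefore hinges on how much δ²H_f varies *within one site* —
among individuals, among species, and between years — relative to the
spatial gradient. `isofeather` implements the statistical machinery for
quantifying those within-site sources of variation from a multi-species
sample of birds captured in one region: a Multivariate-Normal (MVN) mixed
model with phylogenetic covariance and species-specific variances, AICc
multimodel inference over a fixed candidate set, pre-model screening of
species whose feathers were not grown locally, and a year × species
ANOVA. Because the motivating study's individual-level data are not
deposited, the package also ships a synthetic-data generator that
reproduces the statistical structure of such a study, so every method can
be exercised, tested and calibrated end to end.

## The model

For individual $i$ of species $j$, the response $y_{ij}$ (δ²H_f, ‰) is

$$ y \sim \mathrm{MVN}(X\beta, \Sigma), \qquad
   \Sigma_{(ij),(lk)} =
   \begin{cases}
     \sigma_j^2 & \text{same individual} \\
     \sigma_j \sigma_k\, t_{jk}\, \lambda & \text{otherwise,}
   \end{cases} $$

where $t_{jk}$ is the shared evolutionary path length between species $j$
and $k$ (root-to-MRCA distance), here normalized to unit tree depth so
that $T = (t_{jk})$ is a correlation matrix with $t_{jj} = 1$, and
$\lambda \in [0,1]$ is Pagel's λ, a multiplier on the off-diagonal:
λ = 0 means trait values independent of phylogeny, λ = 1 the full
Brownian-motion expectation. Fixed effects enter only the mean; all
random structure lives in $\Sigma$. Equivalently, with $Z$ the
individual-to-species indicator matrix and $D_\sigma$ the diagonal matrix
of per-individual SDs,

$$ \Sigma = D_\sigma \left( \lambda\, Z T Z^\top + (1-\lambda) I \right) D_\sigma , $$

an identity the likelihood code exploits (see *Numerical choices*).

Two conventions and one candidate grid complete the model space:

* **Variance structure.** `hom` uses a single residual SD σ for every
  species; `het` gives each species its own σ_j. The heteroscedastic
  structure requires at least two individuals per species, which
  `fit_ml()` enforces.
* **Conspecific covariance.** The covariance formula applied literally at
  $j = k$ gives two distinct individuals of the same species covariance
  $\lambda \sigma_j^2$ — within-species correlation equal to λ. That is
  the default (`conspecific = "lambda"`); it is exactly the "phylogenetic
  random species effect observed with individual noise" reading of the
  model, since a species-level effect with variance $\lambda\sigma_j^2$
  plus individual noise of variance $(1-\lambda)\sigma_j^2$ produces the
  same Σ. An alternative `"independent"` switch zeroes the within-species
  off-diagonal for sensitivity analyses. One consequence of the default:
  with any species sampled twice, λ = 1 makes Σ singular (two individuals
  perfectly correlated), so λ̂ lives in [0, 1) whenever the data contain
  conspecifics.
* **Candidates.** Sixteen fixed-effect structures — intercept-only (0);
  species (1); species-level traits: ground/non-ground forage substrate
  (2), insectivore/omnivore diet (3), nesting substrate (4); station-level
  covariates: land cover at the station point (5), dominant cover within
  100 m (6), wetland area (7), latitude (8); individual covariates: mass
  (9), mass + mass² (10), sex (11); and the interactions forsub × diet
  (12), forsub × station cover (13), nest × diet (14),
  forsub × diet × nest (15) — each fit under both variance structures, 32
  candidates in total, with λ estimated in every one (the candidate table
  lists λ alongside σ for the null model too). Structure 13's "land
  cover" is taken at the station point (structure 5's covariate); the
  candidate list names both land-cover variables and does not pin down
  which one enters the interaction.

## Phylogenetic correlation from a tree sample

Real analyses use a sample of trees (pseudo-posterior draws) rather than a
single topology. `correlation_from_tree()` converts one ultrametric tree
(relative tip-depth spread ≤ 1e-6, configurable) to a correlation matrix
by dividing shared root-to-MRCA heights by tree depth and fixing the
diagonal at 1. `correlation_from_trees()` pools a sample. Two pooling
orders are defensible and differ slightly because normalization is
nonlinear: average the per-tree *correlation* matrices elementwise (the
default, which keeps every pooled entry a mean of correlations and the
unit diagonal exact), or average the *node heights* first and normalize
once (`method = "mean_height"`). Both re-fix the diagonal to 1 and both
preserve positive semidefiniteness (a convex combination of PSD matrices).
The constant of proportionality between shared path length and $t_{jk}$
is not determined by the model statement; unit-depth normalization is this
package's choice, and because σ_j multiplies $t_{jk}$ in Σ, a different
constant would simply rescale the σ_j — the fit and the ranking are
unaffected, only the nominal meaning of σ_j changes.

`apply_lambda()` implements the off-diagonal multiplier and satisfies
`apply_lambda(C, λ) = λC + (1 − λ)I` exactly for unit-diagonal C; the
test suite asserts that identity, the λ = 0 / λ = 1 endpoints, and
monotonicity of every off-diagonal element in λ.

## Maximum-likelihood machinery

**Evaluation.** The log-likelihood is evaluated through the factorization
$\Sigma = D_\sigma M D_\sigma$ with $M = \lambda Z T Z^\top + (1-\lambda)I$.
Writing $a = 1 - \lambda$, the Woodbury identity and the matrix
determinant lemma reduce everything to S × S solves:

$$ M^{-1} = \tfrac{1}{a}\left[ I - Z\, W (aI + NW)^{-1} Z^\top \right],
   \qquad
   \log|M| = (n - S)\log a + \log\det(aI + NW), $$

with $W = \lambda T$ and $N = \mathrm{diag}(n_j)$. Each evaluation costs
O(nS + S³) instead of O(n³), which is what makes the 32-candidate and
replication studies cheap. At the λ = 1 boundary (a = 0, reachable only
when every species is sampled once) a dense Cholesky path takes over, and
the same dense path serves the `"independent"` conspecific convention.
The suite cross-checks the structured path against a naive dense
determinant-and-solve oracle to 1e-8 on random instances.

**Optimization.** β is profiled out by generalized least squares at every
(σ, λ): the GLS normal equations use the same Woodbury pieces. The
remaining parameters are optimized on transformed scales — log σ and
logit λ — so bounds are automatic. For `hom` candidates σ² is additionally
profiled in closed form ($\hat\sigma^2 = q/n$), leaving a one-dimensional
problem in logit λ that is solved by bracketing the optimum on a 37-point
logit grid and refining with Brent's method; λ = 0 is checked explicitly
as a boundary candidate. `het` candidates use multi-start BFGS (default 5
starts: per-species OLS residual SDs, jittered ×exp(N(0, 0.2)) and
stratified λ starts {0.25, 0.5, 0.75, 0.1, 0.9}), relative convergence
tolerance 1e-8 on the objective; the start jitter is seeded, so fits are
deterministic given data and seed, and `converged` reports the optimizer's
own flag honestly. Aliased design columns (e.g. the saturated
forsub × diet × nest cells) are detected by QR pivoting, dropped before
fitting, and reported; the parameter count k counts the retained columns
plus 1 (hom) or S (het) variance parameters plus 1 when λ is estimated —
λ is counted once per model, in every candidate, including the null.

**Comparability.** All 32 candidates must be fit to the identical record
set for AICc to be meaningful, so `fit_candidates()` applies a
complete-case rule over the union of covariates used by any requested
candidate before fitting anything, and `rank_models()` refuses to rank
fits with unequal n.

**Data cloning.** As an independent check on the optimizer, `fit_dataclone()`
runs a componentwise random-walk Metropolis sampler on the posterior
proportional to $L(\theta)^K \pi(\theta)$ with proper diffuse priors
(N(0, 500²) on β in ‰, N(log 10, 3²) on log σ, N(0, 2.5²) on logit λ).
As the clone count K grows, the posterior mean converges to the MLE and
K × posterior variance to the asymptotic ML variance, so (i) point
estimates should match `fit_ml()` and (ii) K × variance should stabilize
in K — both are asserted in the acceptance suite (K = 4 vs 16 within 25%).
Proposal scales adapt toward ~35% acceptance during burn-in only; chains
are seed-deterministic, and acceptance rates outside [0.05, 0.8] set a
`mixing_ok = FALSE` flag rather than failing silently.

## When λ cannot be estimated: an identifiability boundary

A structural fact the package documents (and tests) rather than hides:
**whenever the fixed effects contain species indicators, the MLE of λ is
exactly 0.** With free species means, within-species contrasts carry
information only about $\sigma_j^2(1-\lambda)$, and the between-species
blocks of Σ affect only the distribution of the species sample means —
which the free means absorb. What remains of λ in the profile likelihood
is the log-determinant of the species-mean directions, and that term is
strictly increasing in λ; the likelihood therefore always peaks at the
λ = 0 boundary, and σ̂_j estimates $\sigma_j\sqrt{1-\lambda}$. The
practical corollaries: (i) fitted λ values from species-mean candidates
are boundary artifacts, not evidence about phylogeny — λ is interpretable
only from candidates whose mean structure does not saturate species
(intercept-only, trait or station structures); (ii) a parameter-recovery
experiment for λ must generate the species-level signal *through the
covariance* (intercept mean), not through fixed species means, which is
how the package's recovery experiment is built; and (iii) weak fitted λ
in species-mean candidates is expected behavior of this model family, not
a failure of the data.

## Screening, ANOVA and transfer functions

`screen_records()` applies, in order: the age filter (after-second-year
birds only, when an `age` column is present), an explicit species
exclusion list, and the minimum-sample rule (default 9 individuals per
species, the study's sampling criterion). It is idempotent and reports
every exclusion with its reason. On the packaged species table (21
species, 279 birds) with the six presumed non-local molters excluded, 192
records across 15 species remain — the screening arithmetic the suite
pins down. `flag_nonlocal_molt()` operationalizes the qualitative
judgement "these feathers were grown off the breeding grounds" as a
configurable upper bound on the species mean, default −110‰ — chosen
between the most positive local species mean (−127‰) and the least
positive non-local mean (−97‰) — with a *strict* inequality at the bound
(a mean exactly at −110 is retained).

`year_species_anova()` fits the two-way fixed-effects model with
interaction and reports Type-II sums of squares, appropriate for the
unbalanced species samples (the choice is ours; nothing in the candidate
table dictates it). Because a reported interaction F with numerator df
equal to cells − 1 is sometimes the *full-model* F of the cell-means fit
(for 4 species × 2 years: F with 7 numerator df), the function emits both
the interaction row and a full-model row and lets the reader choose.

`predict_feather_band()` evaluates configured transfer functions
(intercept + slope · δ²H_p ± residual SD) — the coefficients are study
inputs, not estimated here — and `classify_local_molt()` tests a species
or group mean against the closed band interval.

## The synthetic-data generator

`simulate_tree_set()` draws pure-birth (Yule) trees rescaled to unit
depth as a stand-in for a genetic pseudo-posterior: only the shared-path
structure matters downstream, and a Yule sample gives dispersed, valid
ultrametric topologies with one knob. `simulate_dataset()` draws records
exactly from MVN(Xβ, Σ) with Σ built by `expand_to_individuals()` — the
generator and the likelihood share one covariance definition, so
distributional tests (sample covariance → Σ in Frobenius norm) validate
both at once. Station, sex, mass and year labels are drawn independently
of y unless the generating structure puts them in the mean — matching the
null structure of covariates the selection exercise should reject.
`simulate_year_dataset()` shifts species means between two year labels by
configured offsets. Per-species means and SDs for fixture-based runs come
from a shipped table that is *synthetic* (the study's per-species values
are not published) but anchored to every printed constraint: local means
span −162 to −127‰ with SAVS and SWTH at the endpoints, SDs span 4
(MOWA) to 22‰ (SOSP), and the six non-local species span −97 to −51‰.

What the generator does *not* emulate: isotope measurement chemistry and
its ±2‰ analytical error (no measurement-error term — it is absorbed into
σ_j), spatial isoscape surfaces, real phylogenetic relationships among
the 21 species, spatial autocorrelation between stations, and any
dependence of the non-selected covariates on y. Passing tests therefore
demonstrate that the estimators and the selection machinery behave
correctly when the model's assumptions hold, and that the screening and
ANOVA stages reproduce printed arithmetic; they cannot show that the MVN
covariance is the right model for real feathers.

## Study-scale experiments and their design choices

Problem sizes were chosen so the full suite runs in minutes on one core:

* **Parameter recovery** — 15 species × 30 individuals, σ_j spanning
  4–22‰, λ = 0.6, intercept mean (see the identifiability section), 20
  replicates; the matching candidate recovers mean λ̂ within a few
  percent of truth and replicate-mean σ̂_j within 15%.
* **Selection recovery** — scaled down to 8 species × 10 individuals with
  species means drawn per replicate from N(−143, 12²) (the observed
  between-species spread) so that alignment between means and traits is
  accidental, σ_j spanning 4–22‰ (> 4-fold heterogeneity), λ = 0.6, 100
  replicates: Het1 ranks first in well over 70% and the heteroscedastic
  subset beats the homoscedastic one essentially always.
* **Study emulation** (analysis stages 2–3, acceptance script) — the full
  retained design: 15 species with the transcribed per-species n (192
  records), species-mean signal from the synthetic means table, σ_j from
  its SDs, and generating λ = 0.25, consistent with the weak phylogeny
  signal the species-mean candidates report; a large conspecific λ would
  shrink observable within-species SDs to σ_j√(1−λ), well below the
  anchored 4–22‰ range. On this design Het1 competes head-to-head with
  Het14/Het15 — the retained trait combinations almost saturate the
  species set (14 distinct forsub × diet × nest cells for 15 species), so
  which species-level heteroscedastic candidate lands on top varies with
  the simulation draw. That near-degeneracy is a property of the real
  study design, and echoes a second-place nest × diet candidate within a
  few AICc units of the species model.
* **Year × species power** — offsets (−6, +4, +9, +12)‰ at n = 15/cell,
  σ = 8‰: the closed-form noncentral-F power at α = 0.001 is 0.76, and
  the simulated detection rate matches it (the experiment clears 95%
  detection only at α = 0.05).

## Known limitations

* No REML: variance parameters are plain ML and biased low in small
  samples (the iid closed-form test pins the divide-by-n convention).
* λ and σ_j are confounded under species-mean fixed effects (see above);
  the package reports the boundary estimate rather than refusing to fit.
* AICc uses a parameter count that includes boundary-estimated λ; no
  mixture-of-χ² boundary correction is attempted.
* The data-cloning sampler is a plain componentwise random-walk — adequate
  for the low-dimensional cross-checks it serves, not tuned for large S.
* Heteroscedastic fits need ≥ 2 individuals per species and λ̂ is capped
  away from 1 by the logit parameterization when conspecifics are present
  (where the likelihood is −∞ anyway).
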