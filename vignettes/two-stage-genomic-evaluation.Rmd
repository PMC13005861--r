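---
title: "Two-stage and single-stage genomic evaluation of augmented multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage and single-stage genomic evaluation of augmented multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polystage)
```

# Scope and model

`polystage` analyses series of augmented row–column trials of a hexaploid
clonal crop — many unreplicated test clones, a few replicated checks and
parents — and compares the practical **two-stage** route (per-environment
analysis, then a weighted across-environment model on the adjusted
"entries") against the **single-stage** benchmark (one joint fit of all
plots). Everything rests on one dense REML engine, `reml()`, so the two
routes are algebraically comparable.

## The plot-level model

Within one environment the baseline model is

$$y = 1\mu + X_1 b + X_2 t + Z_1 g + Z_2 r + Z_3 c + Z_4 rc + \varepsilon,$$

with fixed pool ($b$) and check ($t$) effects, genetic effects $g$ over the
parents and test clones, random row-group ($r$), column-group ($c$) and
block ($rc$) effects, and a separable spatial residual
$\varepsilon \sim N\{0, \sigma^2_\varepsilon\,[\mathrm{AR1}(\rho_r)\otimes
\mathrm{AR1}(\rho_c)]\}$ evaluated at the observed plot coordinates
(missing plots are handled by conditioning, i.e. subsetting the full-grid
covariance — never by padding with pseudo-records).

Three stage-one variants differ only in $g$:

* **BLUE** — $g$ fixed. We use the treatment-means parameterisation
  `y ~ 0 + treatment`: with fixed genetic effects the model is otherwise
  rank-deficient (pool is a function of genotype), and treatment means keep
  the entries on one common, estimable scale across variants. Dropped
  (aliased) columns are reported on the fit.
* **BLUP** — $g \sim N(0, \sigma^2_g I)$.
* **ABLUP** — $g = a + na$ with $a \sim N(0, \sigma^2_a A)$ over the
  pedigree relationship matrix and $na \sim N(0, \sigma^2_{na} I)$.

Genetic variance components are tested with the boundary-corrected
likelihood-ratio test, $p = \sum_l 2^{-L}\binom{L}{l}P(\chi^2_l > LR)$, and
heritabilities are

$$h^2 = \frac{\Theta\sigma^2_a}{\Theta\sigma^2_a + \sigma^2_{na} +
\sigma^2_\varepsilon}, \qquad
H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon},$$

with the correcting factor $\Theta = \overline{D(A)} - \bar A$ (from $G$ in
the single-stage case) aligning the components to the reference population.

## Deregression and weights

BLUPs would be doubly shrunken if carried into a second mixed model, so the
entries are **deregressed**: the plot model is refitted with the genetic
effects *fixed* while all non-genetic variance components (and, for the
ABLUP variant, $\sigma^2_{na}$) are frozen at the REML estimates of the
supplying fit. The refit's fixed-effect covariance gives the entry
covariance $Q_m$; stacking environments gives
$Q = \oplus_m Q_m$. Freezing $\sigma^2_{na}$ in the dABLUP refit means the
fixed treatment effect targets the additive component; the resulting $Q$
consequently embeds the uncertainty attributable to the frozen non-additive
term — the convention this package adopts where the procedure leaves the
choice open.

Two weighting schemes go to stage two: **FW** carries $Q$ intact;
**DW** keeps only $1/D(Q^{-1})$ as a diagonal covariance. A near-singular
$Q$ receives a ridge of $10^{-8}\,\overline{D(Q)}$ before inversion.

## The second-stage and single-stage models

Stage two fits, on the entries of the genotyped individuals,

$$y^* = 1\mu + Xe + Zg + s + \varepsilon, \qquad s \sim N(0, Q),$$

with $g = a + na$: additive effects
$a \sim N(0, \Sigma_g \otimes G)$, $\Sigma_g = \Lambda\Lambda' + \Psi$ a
factor-analytic covariance of order $K$, and non-additive effects with
heterogeneous compound symmetry
$\sqrt{D}[I + \varrho(J - I)]\sqrt{D} \otimes I$. The i.i.d. residual
$\varepsilon$ is retained even though $Q$ is known, with a small lower
bound ($10^{-6}\,\mathrm{var}(y^*)$) so it cannot be confounded with $Q$;
a fit at that bound is visible in the parameter table. The single-stage
model uses the same genetic structures on the plot data directly, with the
ungenotyped treatments (checks and clones without marker data) moved to the
fixed part, per-environment AR1×AR1 residuals, and design effects with a
common variance across environments (one level set per environment), which
is how the benchmark model writes them; it also keeps the free-parameter
count of the joint fit tractable for dense algebra.

$K$ is chosen by the percent-variance-explained rule: the smallest $K$
explaining at least 90% of the additive variance overall with every
environment at 60% or more; AIC accompanies the choice. From $\Sigma_g$ we
report the between-environment genetic correlations
($\Delta\Sigma_g\Delta$) and the variance partition: main-effect variance
(mean of the covariances), interaction variance (mean variance minus
main-effect variance), split into heterogeneity of scale (variance of the
genetic standard deviations) and lack of correlation (the remainder —
additivity is exact by construction).

GEBV reporting: per-environment GEBVs are the additive factor-analytic
predictions; the single across-environment GEBV per candidate is their
plain environment average. A loading-weighted index would be an
alternative; the plain mean was chosen as the neutral summary and is the
only place this choice matters (selection concordance).

# The REML engine

`reml()` evaluates the restricted log-likelihood by dense algebra on
$V = \sum_t Z_t G_t Z_t' + R$ with the orthonormal error-contrast
convention
$\ell_R = -\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| -
\log|X'X| + y'Py]$, assembling each structure's contribution to $V$
directly as an $n \times n$ block through index matrices (one Cholesky per
evaluation). Optimisation is quasi-Newton (`nlminb`) on transformed
parameters: log variances, atanh correlations, unconstrained loadings with
a lower-triangular $\Lambda$ for identification (all consumers —
$\Sigma_g$, %EV, GEBVs — are rotation-invariant). Convergence uses a
relative objective tolerance of $10^{-8}$ with an iteration cap of 500.
Because factor-analytic likelihoods can be multimodal, models containing an
FA term default to 3 optimisation starts (jittered from the common
initialisation); other models use 1. Ties between starts are broken by best
likelihood, then smallest parameter norm. Variance parameters reaching the
zero boundary are flagged, not fatal. Aliased fixed-effect columns are
dropped deterministically and reported. With every parameter frozen the
function skips optimisation and returns Henderson's mixed-model solution
(BLUEs, BLUPs, PEV from the relevant inverse blocks) at the supplied
values — this is how deregression, the equivalence analyses and the fast
cross-validation path are implemented.

AIC is $-2\ell_R + 2q$ with $q$ the number of *free covariance* parameters
only (fixed effects are profiled out under REML), the convention used for
the factor-order table.

# The synthetic-data generator

`sim_config()` describes the study conditions the package is built around:
six environments of a 50×30 augmented row–column design (10×10 row and
column groups, so 15 blocks), 8 checks appearing once per block (hence 3
times per row group, 5 per column group, 15 replicates each), 39 parents in
two pools (19 + 20) crossed in a partial diallel of 254 families with 1 to
18 offspring (1,138 test clones), 3,120 simulated loci, 13 clones without
marker data, and roughly 24% of plots on replicated treatments (the parent
replication plan draws counts from 1–15 and adjusts them to the remaining
field capacity — 242 plots at full scale).

Mechanics worth knowing:

* Founder dosages are Binomial(6, $p_u$) with $p_u$ uniform on
  [0.1, 0.9] — a Hardy–Weinberg autohexaploid base.
* Meiosis passes 3 of the parent's 6 allele copies without replacement, so
  gamete dosages are exactly hypergeometric; **double reduction is not
  modelled**.
* Additive values are built *marker-wise* ($a_m = \sum_k \lambda_{mk}
  W\beta_k + W\gamma_m$, with effects scaled by $1/\sum 6p_u(1-p_u)$) so
  that dosages and true values are mutually consistent and
  $\mathrm{Cov}(a) \approx \Sigma_g \otimes G$; non-additive values are
  drawn from the heterogeneous-CS covariance directly.
* Checks carry no marker data and enter as fixed effects.
* Missingness (default 5% full-scale, "mortality") is uniform at random —
  real mortality may be spatially clustered; that structure is not
  emulated.
* Parent plots are placed by unrestricted randomization (only checks follow
  the blocking constraints), matching how such designs are laid out.
* One master seed drives documented sub-streams (founders, crossing plan,
  meiosis, genetic effects, check effects, one per environment for layout
  and phenotypes), so datasets are bit-reproducible.

Default variance magnitudes (trait scale: storage-root yield, t/ha) were
chosen once to give single-environment broad-sense heritabilities around
0.25–0.45 and between-environment additive correlations spanning weak to
strong — the regime where the FW/DW and CV1/CV2 contrasts are scientifically
interesting. `demo_config()` is the same structure at desk scale (3
environments, 12×10 fields, ~100 clones, 300 loci).

What passing tests on these simulations do **not** show: robustness to
spatially structured mortality, non-Gaussian trait noise, genotyping error,
or pedigree errors — none of which the generator emulates.

# Relationship matrices

`G_matrix()` implements the hexaploid dosage scaling
$G = WW'/\sum_u 6p_u(1-p_u)$ with mean-imputation of missing dosages by
$6p_u$ before centring ($p_u$ always re-estimated from the analysed subset,
which is why pool-specific runs recompute $G$). Marker QC removes loci with
>10% missing data, no variation, or MAF < 0.05. `A_matrix()` uses the
polysomic kinship recursion with double reduction fixed at 0
($A_{ij} = \tfrac12(A_{sj}+A_{dj})$, $F_i = (F_s+F_d)/5 + A_{sd}/10$,
$A_{ii} = 1+5F_i$, founders at diagonal 1); a gene-dropping Monte-Carlo
oracle in the test suite is the ground truth for these recursions. `blend()`
applies $(1-w)M + wI$ (default $w = 0.02$ on $G$) for invertibility and
records the weight.

# Cross-validation

CV1 masks whole genotypes (all environments); CV2 masks
genotype-by-environment cells, stratified so each fold holds ~20% of every
environment's cells. Both use 5 folds and, at study scale, 30 repetitions.
Two deliberate design choices:

* **Stage one is not re-run per fold.** Masking operates on the entries:
  the object under evaluation is the second-stage (or single-stage) model.
* **`reuse_vc`**: by default the variance components are estimated once on
  the full entry set and reused across folds, and each fold is then a pure
  mixed-model solve. This is a fitting-cost choice (it makes 30×5 folds a
  matter of seconds) with a small, shared information leak through the
  variance components; `reuse_vc = FALSE` re-estimates per fold, and
  supplying `fixed` parameters eliminates any full-data fit (the leakage
  test in the suite runs in that mode).

Predictive ability is the Pearson correlation between held-out entries and
predicted GEBVs computed *within environment* and averaged (a pooled
correlation would conflate environment means). MSPE compares held-out
entries (or, single-stage, corrected phenotypes $y - Xf$ averaged per
cell) with GEBVs directly. Theoretical accuracy for single-stage
predictions is $\sqrt{1 - PEV_v/(\sigma^2_a(1+5F_v))}$ with $1+5F_v$ from
the $G$ diagonal; a negative radicand (an individual whose PEV exceeds its
genetic variance) is clipped to zero with a warning.

# Numerical choices and degenerate inputs

* Entries' $Q$: ridge $10^{-8}\overline{D(Q)}$ only when inversion fails.
* Stage-two residual lower bound $10^{-6}\mathrm{var}(y^*)$ (see above).
* Selection concordance breaks GEBV ties by candidate id, so the top-10%
  set is deterministic.
* `lr_test()` treats $\chi^2_0$ as a point mass: $LR = 0$ gives $p = 1$; a
  negative $LR$ beyond tolerance is an error (mis-nested models).
* Fold assignment errors out if a pool or unit set is smaller than the fold
  count.
* Layout generation validates divisibility of field dimensions by group
  sizes and exact plot-count feasibility before randomising.

# Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run at sizes chosen to make each
property measurable with comfortable Monte-Carlo margins: design-count
checks at the full 50×30 scale (layout generation is cheap); REML-oracle
equality on fixtures of ≤ 160 records; the two-stage/single-stage
equivalence on 40 genotypes × 3 environments; parameter-recovery on 50
replicates of a 12×10 trial (spatial/additive components) and of a
150-entry factor-analytic fit ($\Sigma_g$); and the directional
cross-validation comparisons pooled over 5 simulated trial series × 12
repetitions (60 repetitions per contrast). These are the package's own
choices of experiment size; all of them are re-generated in code at run
time.

# Known limitations

* Dense algebra: practical up to a few thousand records / a few hundred
  genotyped individuals per fit; no sparse or average-information updates.
* No combined pedigree–genomic (single-step H) matrix: ungenotyped
  individuals are handled as fixed effects in the single-stage model.
* Double reduction is assumed absent in both the generator and the pedigree
  recursion.
* Single-trait only; no spatially structured missingness; no forward
  (year-ahead) validation scheme.
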