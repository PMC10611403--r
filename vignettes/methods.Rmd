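---
title: "Methods: multilevel joint and individual variation for two-domain feature panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilevel joint and individual variation for two-domain feature panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmjive)
```

## The data model

`mmjive` analyses two blocks of daily features measured repeatedly on the
same subjects: a P-dimensional physical-activity (PA) block `x_ij` from a
wrist accelerometer and a Q-dimensional gait block `y_ij` from a lumbar
accelerometer, for subject `i = 1..n` on day `j = 1..n_i` (N = sum n_i
subject-days in total). Rows are keyed by `(subject, day)`; the block
membership of every feature is known and disjoint. Days with less than
10 hours of wrist wear time are conventionally excluded
(`filter_valid_days()`; the rule is `>=`). Features arrive in wildly
different units, so all models work on z-scored columns. Two scaling
scopes exist because two analysis grains exist:

- one-level models act on per-subject day averages `x_i., y_i.`; scaling
  with `scope = "subject_means"` standardizes over those means, so the
  one-level inputs are exactly mean-0/sd-1 (average-then-scale);
- multilevel models act on daily rows; `scope = "daily_rows"` standardizes
  over the N rows.

Rows with any missing feature value are dropped (with a logged count)
rather than imputed; nothing in the framework below handles missingness.

## One-level models

**Pairwise correlation.** Pearson correlations between all feature pairs
on subject means, with two-sided p-values from
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` df. The display mask defaults to
`alpha = 0.1` for the correlation report and `0.05` for regression
coefficient reports — the two conventions are deliberate and separately
configurable. No multiplicity correction is applied anywhere by default;
the masks are descriptive, not confirmatory.

**Lasso on the opposite domain.** Each feature of one domain is regressed
on all features of the other under the objective
`(1/2n) ||y - b0 - X b||^2 + lambda ||b||_1`, over a 100-point log-spaced
grid from `lambda_max = max |X'y| / n` down to `1e-3 lambda_max`. Model
selection is five-fold cross-validation with the one-standard-error rule:
the reported model is at the largest lambda whose mean CV error is within
one standard error of the minimum (the sparsest model not meaningfully
worse than the best). Folds are assigned at the row level of the
subject-means matrix — the subject is the sampling unit — under an
explicit seed, because the fold split is the only stochastic element of
the whole one-level analysis. Rather than iterative coordinate descent,
the solver is an exact feature-sign (active-set) search: with at most a
few dozen predictors, each candidate active set is solved in closed form
and sign changes are handled by a line search to the first zero crossing,
giving machine-precision solutions whose KKT residuals are ~1e-15. The
test suite checks the KKT conditions along the entire path and agreement
with the normal equations as `lambda -> 0`.

**Principal component regression.** PCA (by SVD) of the PA block;
`k = "auto"` keeps the smallest k whose cumulative explained variance
reaches 90%. The scree-elbow alternative (maximum second difference of
the explained-variance sequence) is computed and reported alongside but
does not drive the default, because a variance target is reproducible
while elbows on shallow scree curves are not. Each gait feature is then
regressed by OLS on the k PC scores, with t-based p-values masked at
`alpha = 0.05`.

## Domain-on-domain models

**Two-block PLS.** Per component, the leading singular-vector pair
`(mu, nu)` of the running cross-product `X'Y` maximizes the cross-block
covariance `mu' X'Y nu`; scores are the block projections, and both
blocks are deflated on the x-score regression (regression mode — the PA
block plays the predictor role). Two components are fitted by default;
they are the ones reported and compared downstream.
`covariance_explained` is the squared leading singular value over the
squared Frobenius norm of the initial `X'Y`. The correlation-circle
output is the correlation of every original feature with each x-score.

**JIVE.** The stacked blocks `Z = [X; Y]` (features in rows, samples in
columns) decompose as `X = J1 + A1 + E1`, `Y = J2 + A2 + E2` with
`J = [J1; J2]` of rank `r` shared across blocks and block-specific `A_l`
of rank `r_l`, subject to row-space orthogonality `J A_l' = 0` — the
constraint that makes "joint" and "individual" identifiable. Estimation
alternates (i) `J <- ` best rank-`r` SVD approximation of `Z - A` and
(ii) `A_l <- ` best rank-`r_l` approximation of `X_l - J_l` projected
off the row space of `J`, until the summed squared Frobenius change of
`(J, A1, A2)` falls below `tol = 1e-9` (cap 1000 iterations;
non-convergence is an error carrying the last change — it is not
silently accepted). Each block is pre-scaled to its Frobenius norm
(recorded and undone in the outputs) so that the wider or noisier domain
cannot dominate the joint fit; a flag disables this. Variance fractions
are normalized by the summed squared norms of the three parts, which
equals the block norm up to the O(tol) cross-terms left at convergence
and guarantees the reported fractions sum to exactly 1.

**Rank selection.** Permutation-based: the joint rank compares the
singular values of `Z` against nulls obtained by independently permuting
each block's columns (destroying cross-block association, keeping
within-block structure); each block's individual rank compares the
singular values of the block's joint-residual against nulls obtained by
permuting each feature row independently. Ranks grow sequentially while
the permutation p-value `(1 + #{null >= observed}) / (n_perm + 1)` stays
below `alpha = 0.05` (default `n_perm = 100`). Singular values below
`1e-8` of the data norm are treated as numerically zero and never
significant, which keeps noiseless fixtures from turning floating-point
dust into spurious ranks. A calibration caveat: the procedure runs three
tests at `alpha` each, so on pure noise all three ranks are zero with
probability about `0.95^3 ~ 0.86`, not `0.95`; this is a property of the
stated procedure, not of the implementation.

## Multilevel models

**ANOVA decomposition.** Every row splits exactly as
`z_ij = mu + (z_i. - mu) + (z_ij - z_i.)`. The between matrix has one row
per subject (day counts enter the sums of squares as weights, matching
the identity `SS_total = SS_between + SS_within` per column); the within
matrix rows sum to zero within each subject by construction. These are
identities, not estimates, and the tests assert them at 1e-10.

**Multilevel PCA.** Two estimators of the level covariances are exposed:

- `method = "moment"` (default): the between covariance from cross-day
  products within subject, `E[(z_ij - mu)(z_ik - mu)'], j != k`, averaged
  over ordered pairs; the within covariance as total minus between. This
  package adds a finite-day correction: under the exact ANOVA convention
  (within effects summing to zero per subject) the raw cross-day moment
  has expectation `S_b - gamma S_w` with `gamma = N / sum n_i (n_i - 1)`,
  so the debiased covariances `S_b = (R + gamma T) / (1 + gamma)`,
  `S_w = (T - R) / (1 + gamma)` are used. Without the correction the
  between share is systematically understated by roughly
  `within/(mean days - 1)` — about 0.04-0.06 at 9 days — which is larger
  than the recovery tolerances this package tests at.
- `method = "empirical"`: eigendecomposition directly of the
  (day-count-weighted) between and within ANOVA matrices; exactly
  consistent with the ANOVA sums of squares by construction.

Both covariances are symmetrized and projected to the nearest positive
semidefinite matrix (negative eigenvalues clipped to zero). Per level,
the smallest component count reaching `retained_fraction = 0.9` of the
level trace is kept — counted per level, not jointly, so each level's
representation is equally faithful; the threshold echoes the 90% PCA
convention of the one-level analysis and is logged in every manifest.
Level variance fractions are the traces of the level covariances over
their sum.

**Multilevel PLS** fits the one-level PLS separately on the between and
within matrices (split into their PA/gait column blocks). If all
subjects have a single day the within matrix is identically zero; the
within fit is skipped with a warning rather than failing the run.

**Multilevel JIVE** is two-step: MPCA first, then JIVE on each level's
retained low-dimensional reconstruction (scores times loadings, split
back into blocks). Level summaries report, per level, the MPCA level
share and the joint/individual fractions *of that level's total
variation in the ANOVA sums-of-squares convention* (between-level rows
day-count-weighted). The residual column therefore absorbs both the JIVE
residual and the MPCA truncation — fractions are comparable across
retention settings, and columns sum to at most 1.

**Cross-model comparison** correlates the first two component score
vectors of all fitted models at the subject grain: subject-level scores
as-is, observation-level (within, one-level-N) scores averaged per
subject. Per-subject averaging is this package's documented
interpretation of cross-grain comparison, not an established convention;
both signed and absolute correlations are reported because component
signs are arbitrary (a deterministic sign convention — flip so the
largest-absolute loading entry is positive — is applied to every
loading/weight vector precisely so reports reproduce across linear
algebra backends).

## The synthetic world

`simulate_multilevel()` is the forward model of the multilevel JIVE
decomposition: `z_ij = mu + u_i + w_ij` with
`u_i = joint_b + individual_b + noise_b` and
`w_ij = joint_w + individual_w + noise_w`. Defaults emulate the
free-living study shape this package targets: 65 subjects, day counts
`round(Normal(8.78, 1.86))` clipped to >= 1, 13 PA + 11 gait features
(with the field's standard abbreviations), rank-1 joint and rank-2
per-block individual structures at both levels, between-level share 0.46,
joint shares 0.53 (between) and 0.45 (within).

Accounting conventions, chosen once:

- With `v = noise_sd^2`, total variance is `1 + v` and the residual
  fraction of every level is `v / (1 + v)`; `noise_sd = 0.5` by default,
  a simulation convenience (the target study does not report a noise
  magnitude), giving a 20% residual share.
- `var_between` is the fraction of *total* variance (signal plus noise)
  at the between level; `var_joint_*` are fractions of the level total;
  the individual structure absorbs `1 - var_joint - v/(1+v)`, split
  equally over blocks with positive individual rank. If both individual
  ranks are zero, that remainder goes to the residual.
- Residual noise is drawn *per level* — subject-level i.i.d. for the
  between part, subject-centred observation-level for the within part —
  in proportion to the level shares. A purely observation-level residual
  would be invisible to the cross-day moment estimator and would
  systematically depress every within-level fraction, making the planted
  partition unrecoverable by any estimator of this family; allocating it
  to the levels keeps "planted fraction" and "estimable fraction" the
  same object.
- Loadings are orthonormal (joint loadings span both blocks, individual
  loadings are zero outside their block); all magnitude lives in the
  scores. Scores are centred in their level's convention, individual
  scores are projected off the joint scores — at the between level in
  both the day-count-weighted inner product (exact sums-of-squares
  planting) and the plain one (JIVE's row-orthogonality
  identifiability; under unequal day counts these differ) — and every
  component, including the noise matrices, is rescaled to hit its target
  sum of squares exactly. The realized variance partition therefore
  *equals* the requested one, and `empirical_variance_report()` confirms
  it from the stored truth.

What the generator does **not** emulate: non-Gaussian marginals, feature
units and scales (everything is z-scale), missing-data mechanisms,
circadian/weekday structure, cohort (age) effects, or serial correlation
across days. A green recovery test therefore establishes that the
estimators recover planted low-rank Gaussian structure at the stated
sizes — it does not validate the framework against the idiosyncrasies of
real accelerometry panels, and the published study's headline numbers are
not reproducible here because that data is available only on request.

## Numerical choices

- Convergence: JIVE `tol = 1e-9`, 1000 iterations, both configurable;
  exactness tests run at `1e-13`-`1e-14` since recovery error tracks
  `sqrt(tol)`.
- PSD clipping of moment covariances; eigenvalue ties and component sign
  ambiguity resolved by the max-abs-positive sign convention.
- The Lasso grid lower end (`1e-3 lambda_max`), fold count, and fold
  seed are explicit arguments; the CV split is the only randomness.
- Writers emit 12-significant-digit CSVs with fixed column order;
  "not selected / not significant" cells are blank, never NaN. Manifests
  carry the seed and the full config echo but no timestamps, so bundles
  are byte-identical under a fixed seed.
- Config files use a flat `key = value` TOML subset (strings, numbers,
  booleans, numeric arrays) or JSON; unknown keys are errors.

## Known limitations

- Pure-noise rank selection returns (0, 0, 0) in ~86% of runs at
  `alpha = 0.05` (three tests at alpha each), below a naive 95%
  expectation; lower alpha if strict null behaviour matters.
- On real data (where within effects need not sum to zero per subject),
  the ANOVA-convention MPCA correction makes the moment estimator match
  the ANOVA accounting, at the cost of attributing within-subject mean
  leakage (order `within/n_i`) to the between level — the two conventions
  genuinely differ at few-day designs.
- JIVE's alternating SVD converges to a stationary point; with adversarial
  initial structure a non-global optimum is conceivable. The tests cover
  planted-structure regimes, where it recovers the truth.
- Exactly two blocks; more blocks, longitudinal trends, and mixed-effects
  extensions are out of scope.
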