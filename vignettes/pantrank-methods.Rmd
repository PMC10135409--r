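---
title: "Models and methods behind pantrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pantrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pantrank infers male dominance-rank trajectories from dated dyadic
submissive interactions (pant-grunts) and relates them to questionnaire
personality traits and to genetic siring success. This vignette is the
package's account of the models it fits, the conventions it adopts where
the methodology is genuinely open, and what its synthetic-data tests do
and do not establish about real data.

## 1. Maximum-likelihood Elo ratings

A pant-grunt is given only by the subordinate of a dyad, so each record
is an outcome: the receiver "wins". Scores start at each male's
*hierarchy-entry score* and are updated after every interaction:

$$p_{ij} = \frac{1}{1 + 10^{-(s_i - s_j)/\sigma}}, \qquad
  s_w \leftarrow s_w + k\,(1 - p_w), \quad
  s_l \leftarrow s_l - k\,(1 - p_w),$$

with $\sigma$ the logistic scale and $k$ the update constant. Unlike
classical Elo, both $k$ and every entry score are free parameters
estimated by minimizing the negative log-likelihood
$-\sum_t \ln p(\text{winner}_t)$ of the observed sequence
(`fit_ml_elo()`). Free entry scores matter for young males: with a
common start value, a young male's early rank would be an artifact of
the initialization rather than data.

Conventions, chosen once and fixed:

* **Link and scale.** Classical base-10 logistic with $\sigma = 400$.
  The likelihood depends only on $(s_i - s_j)/\sigma$ and $k/\sigma$, so
  any fixed scale gives the same cardinal and ordinal output; tolerances
  on cross-implementation comparisons must allow for other conventions.
* **Anchor.** The likelihood is flat along translations of all entry
  scores, so the mean entry score is fixed at 1000. Cardinal and
  ordinal outputs are anchor-invariant (tested).
* **Optimization.** $k$ on the log scale (positivity), entry scores as
  anchored deviations; BFGS from the documented start ($k = 16$, all
  entries at the anchor), relative tolerance $10^{-10}$. The sequential
  likelihood is evaluated in C++ because the optimizer calls it
  thousands of times; a step-by-step R ledger pins its correctness.
* **Within-day order.** Interactions are processed in date order with
  the input-file order preserved within a day; that order is part of
  the data contract.
* **Hierarchy entry.** The entry date is the later of the male's
  age-12.0 date (ages are days/365.25) and his first appearance in the
  adult-filtered record. Both interaction participants must be at least
  12.0 years old, boundary inclusive.

Daily series (`daily_scores()`) hold, per male-day from entry to death
or last observation: the raw score (constant between interaction days),
the *cardinal* score
$c_i = \frac{1}{n-1}\sum_{j \ne i} p_{ij}$ — the mean probability of
beating each other male present — and the *ordinal* rank (1 = alpha,
ties share the smallest rank). The $(n-1)$ divisor keeps $c_i \in
[0, 1]$ and makes each day's values sum to $n/2$ exactly, a machine-
precision test invariant. Days with a single male present have no
defined cardinal or ordinal value and are excluded downstream.

## 2. Rank-trajectory components and validation regressions

`extract_components()` reduces each male's series to six summaries:
cardinal score at entry, rise slope (cardinal change per year from
entry to the first day at the lifetime-best ordinal rank), peak
cardinal, best ordinal, days between first and last day at the best
ordinal, and the decline slope over the two years after the last day at
the best ordinal. Eligibility mirrors the study design: entry/rise
require entry at age 12 (entry age in [12, 13)); peak and best ordinal
require rank data to at least age 26; tenure additionally requires a
best ordinal of 3 or better and entry before 16; decline requires two
further years of data. A male who never improves on his entry-day
ordinal rank has no defined rise slope (this is how the injured male's
trajectory is handled in the study design; exclusions are a roster
flag, never a silent row deletion). Slopes are per year of 365.25 days;
the magnitudes printed in the source analyses are only consistent with
a yearly unit.

`validate_component()` regresses a component on a z-scored trait by
ordinary least squares with a normal-theory 95% CI. The trait is
standardized over the full rated sample by default (configurable via
`z_sample`) because one trait score per male is reused across analyses
with different inclusion sets.

## 3. Personality scores and reliability

Ratings arrive in long form (rater x male x item, 1-7). Negatively
keyed items are reversed ($x \to 8 - x$); each rater's trait score is
the mean of their keyed items; the male's score is the mean over raters.
The item-to-trait key is a configuration input: the instrument's
published key lives outside the source analyses, so the shipped default
(`default_scoring_key()`, also as `inst/extdata/default_key.yaml`) is a
synthetic unit-weighted key built from the standard adjective
descriptions of the six traits — 19 keyed items of 24, with
reverse-keyed items where an adjective opposes its trait. Analyses of
real ratings should substitute the instrument's own key.

Interrater reliability is the Shrout–Fleiss ICC(3,k) for the
consistency of the mean of $k$ raters: $(BMS - EMS)/BMS$ from the
targets x raters ANOVA, with the rater factor entered first so the
target mean square is adjusted for raters, and $k$ the harmonic mean of
raters per target in unbalanced designs. The unbalanced correction is
not specified in the source framework; the harmonic mean is the
standard choice.

## 4. The rank GAMM suite

Six nested Gaussian models of the z-scored daily cardinal score, fit by
REML in mgcv: (1) age only; (2)–(4) adding Dominance and/or
Conscientiousness with age-by-trait interactions; (5) all six traits;
(6) model 5 plus a random date effect, kept only as a regression
check. Fixed effects are tensor-product interaction (`ti`) smooths so
main effects and interaction surfaces are separately penalized, on
shrinkage cubic regression spline bases (`bs = "cs"`) whose penalty can
remove a term entirely. Marginal basis dimension defaults to 5
(reference df 4 for main effects, 16 for interactions). Random effects
are ridge-penalized (`bs = "re"`) per-male intercepts and slopes for
age and each trait.

Interpretation caveats, verified directly during development:

* A `cs` smooth on an exactly linear signal reports edf near 2.5, not
  1: its single penalty shrinks the linear span and the wiggle
  together, so edf measures penalization, not curvature. A linear
  effect is recognized by its fitted partial effect (a straight line
  within its standard-error band), which is what the tests assert.
* Model comparison uses $\chi^2$ tests of twice the REML-score
  difference with df equal to the difference in total effective df —
  approximate, as are the Wald-type smooth p-values.
* AIC-style weighting is not used for these models; fit is summarized
  by deviance explained, adjusted $R^2$, and cross-validation.

Two cross-validation schemes (`cross_validate()`): *stratified 10-fold*
(each male's rows split across folds, seeded) and *forward chaining*
(rows cut into 10 sequential date blocks; train on blocks $1..m$,
predict block $m+1$), whose fold indices are audited in tests to prove
no prediction ever uses future data. Fold MSE is reported in squared
cardinal units. Two prediction guards: covariates are clamped to the
training support, and forecasts are bounded to the training outcome
range ± 0.5 — cubic splines extrapolate linearly at best, and tensor
surfaces can diverge in unoccupied corners of the covariate box, which
otherwise lets a single unseen male dominate a fold's MSE by orders of
magnitude. Males absent from a training window are predicted at the
population level (random-effect terms excluded). Basis dimensions are
reduced automatically when a training fold has too few distinct
covariate values to support them.

For large tables `fit_gamm(..., engine = "bam")` uses `mgcv::bam` with
fREML and discretized covariates; the default `gam` engine is exact
REML.

## 5. Siring success

Each offspring with known paternity defines a risk set
(`assemble_risk_sets()`): the estimated siring date is birth minus the
population mean gestation of 228 days; candidates are males at least
11.0 years old that day (the youngest documented sire was 11.4) with a
cardinal score, trait scores, and a relatedness value to the mother —
dyads with missing relatedness are excluded, and a recorded sire
failing these filters raises an integrity error rather than a silent
drop. Age and cardinal score are z-scored across retained rows; trait
z-scores across the male sample.

`fit_siring_glmm()` fits a logit-link binomial GLMM with a male random
intercept by Laplace-approximated ML (lme4), reporting odds ratios with
Wald 95% CIs; `random_intercept = FALSE` gives the degenerate plain-GLM
case used as a test oracle. `aicc_compare()` fits the 14-model family
(base = age + cardinal + relatedness; additions of Dominance,
Conscientiousness, their squares, and age/rank interactions; one
all-six-traits model) and tabulates
$AICc = -2\ell + 2p + 2p(p+1)/(n-p-1)$ with $n$ the number of candidate
rows and $p$ from the fitted likelihood (fixed effects plus the
random-intercept variance); $\Delta_i = AICc_i - AICc_{best} \ge 0$
(the source table prints the sign the other way) and Akaike weights
$w_i \propto e^{-\Delta_i/2}$.

## 6. The synthetic-data generator

`simulate_study()` produces a full study bundle with known truth. One
latent quality scalar per male links every stage: entry scores load on
it (0.6), traits load on it (Dominance +0.8, Conscientiousness −0.8,
smaller loadings elsewhere), and siring odds depend on rank, age,
relatedness and Dominance (linear +0.95, quadratic −0.33 on the
log-odds scale, matching the effect sizes the pipeline is meant to
detect). Interactions are generated sequentially: each day a random
co-present dyad meets and the winner is drawn from the current true
scores, which are then updated with the true $k = 20$ — so the
generating process is exactly the model the estimator assumes.

Calibration choices: entry scores have SD 300 around the anchor so that
entry-day cardinal scores span roughly 0.05–0.95, the steep-hierarchy
regime implied by published entry cardinal ranges; the default
community is 30 males over 37 years at 15 interactions per male-year
(~6,000 interactions, ~150,000 male-days). Rater noise has three
components: a per-rater *halo* on the male's latent quality (SD 2.2
quality units) that propagates to every trait through its loading, a
trait-level rater bias (SD 1.1), and per-item noise (SD 1.0). The halo
is essential: with independent noise alone, trait reliabilities of
~0.4–0.5 would attenuate a true trait correlation of −0.6 below
detectability; correlated rating errors reproduce the observed
combination of moderate ICCs (~0.35–0.55 at three raters) and a strong
observed Dominance–Conscientiousness correlation (~−0.6). Relatedness
is a mixture (most dyads near 0, ~10% at 0.25, ~5% at 0.5) with a 10%
missing-dyad rate to exercise the exclusion path. All randomness flows
from one master seed through named sub-streams (roster, interactions,
ratings, siring), so stages can be re-randomized independently and the
same seed yields byte-identical bundles.

What passing synthetic tests shows — and does not. The generator
matches the statistical *structure* each stage assumes (sequential Elo
outcomes, rater noise, multinomial siring), so recovery tests establish
the estimators are correct under their own assumptions at realistic
sizes. Real data differ in ways the generator does not emulate:
observation effort varies over time, interactions are not independent
of relationships (coalitions), trait ratings may drift with rater
tenure, and true competitive ability changes with age rather than by
the Elo random walk alone. Parameter recovery on synthetic data is
therefore necessary, not sufficient, evidence for field inference.

## 7. Problem sizes and runtimes

The test suite runs the full pipeline at reduced scale: the recovery
benchmark uses 10 fully co-resident males and ~2,000 interactions per
replicate (20 replicates; median $k$ error and entry-score Spearman are
the tested statistics, as medians are stable at this size); GAMM tests
use 8–12 males with daily series thinned to every fourth day (~5,000
rows); coverage tests use 25 null-coefficient replicates of ~25 siring
events. `scripts/acceptance.R` runs the same stages at study scale
(30 males, 37 years) in a few minutes and writes every headline
quantity as JSON.

## 8. Known limitations

* The ML Elo $k$ is weakly identified when hierarchies are static:
  free entry scores can explain a stable dominance order with $k \to
  0$. Recovery is reliable at steep-hierarchy, multi-year scales; on
  small flat instances the profile in $k$ is shallow and the estimate
  noisy.
* Forward-chaining forecasts for males without training history are
  population-level and bounded; they are honest but coarse, and
  forward MSE is dominated by hierarchy drift the model cannot see.
* ICC(3,k) from sequential ANOVA is exact for balanced designs; for
  unbalanced designs it is the standard approximation, not a REML
  variance-component estimate.
* The shipped scoring key is synthetic; substantive analyses of real
  ratings require the instrument's published key.
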