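---
title: "Gene-pair prognostic signatures: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgpair)
```

## The model

`irgpair` builds survival signatures from *relative expression orderings*.
For genes $a, b$ and sample $s$ with expression $x_{as}$, the feature is the
binary indicator

$$ I_{ab}(s) = \mathbf{1}\{x_{as} > x_{bs}\}, $$

with strict inequality: ties, like the reversed order, score 0. This is the
only reading under which the score is binary; because ties have measure zero
in continuous expression data, the asymmetry is immaterial in practice but
must be fixed for reproducibility. Only one orientation per unordered pair
is enumerated (in input gene order): the reversed pair is the complement off
ties and adds no information.

The prognostic model is a sparse linear predictor over these indicators
under a Cox proportional-hazards model,

$$ h(t \mid s) = h_0(t) \exp\Big(\sum_{k} \beta_k\, I_{a_k b_k}(s)\Big), $$

and the *risk score* of a sample is $\sum_k \beta_k I_{a_k b_k}(s)$. Since
each $I_{ab}$ depends only on the within-sample ranking, the score is
invariant under any strictly increasing per-sample transform of the
expression column. That is the point of the construction: a signature
frozen on one platform scores another platform's samples without any
normalization. The test suite asserts this invariance bitwise across random
cohorts and random monotone warps.

## Pipeline stages and their parameters

**Constancy filter** (`filter_constant_pairs`, threshold 0.80). Pairs whose
indicator takes one value in *more than* 80% of samples are removed —
strictly more than: a pair constant in exactly 80% survives. Such pairs
split the cohort into a tiny group versus the rest and carry almost no
contrast. The filter is applied chunk-wise (`build_filtered_indicators`),
so the full pair space (3.1M pairs for a 2498-gene immune universe) never
has to be materialized; peak memory is `chunk_size` × samples.

**Log-rank screen** (`screen_pairs`, `alpha = 1e-4`, `min_group_size = 2`).
Each pair defines a two-group split; the standard unweighted log-rank
statistic $(\sum(O_1 - E_1))^2 / \sum V$ with per-distinct-time
hypergeometric moments is computed for all pairs at once by matrix
operations, and pairs with $p < \alpha$ (strict) are kept. No
multiple-testing correction is applied — the screen deliberately operates on
raw p-values at a stringent threshold, reproducing the field's practice for
this family of signatures; `alpha` is exposed for users who want FDR-style
control instead. `min_group_size` (default 2) is a numerical guard: the
statistic is formally defined for singleton groups but its chi-square
approximation is useless there. At the default constancy threshold the
filter already forbids groups smaller than 20% of the cohort, so the guard
only matters when the filter is relaxed. Tests cross-check the statistic
against `survival::survdiff` and against a brute-force loop, verify null
calibration (selection rate within binomial error of `alpha` over 10,000
null pairs) and power (hazard-ratio-3 pairs at n = 300 are selected in
≥95% of replicates).

**Stability-selected lasso Cox** (`stability_select`). The screened
indicator matrix enters an L1-penalized Cox regression (glmnet; Efron ties;
path of 100 lambdas). Cross-validated partial-likelihood deviance picks a
lambda per the `lambda_rule` (`"min"` default, `"1se"` optional — which of
the two such signatures should use is genuinely open, so both are exposed).
Because the chosen support varies with the random fold assignment, the fit
is repeated `repeats` times (default 1000) with reshuffled folds, all fold
seeds derived deterministically from the master seed, and the *modal*
non-zero support — the most frequent set — is the signature. Frequency ties
break toward the sparser support. Reported coefficients are the penalized
(shrunken) estimates at the largest path lambda whose support equals the
modal set, not an unpenalized refit; when no path lambda matches the modal
set exactly (it is a cross-repeat consensus), the path is refit on the
modal features and the largest lambda at which all of them are active is
used. Two deliberate choices: binary indicators are **not** standardized
(standardizing 0/1 columns rescales the penalty toward balanced pairs), and
the mechanism is fully seed-controlled so a fixed seed reproduces the
signature bit for bit.

**Risk stratification** (`timedep_roc`, `optimal_cutoff`, `assign_groups`).
Discrimination at a clinical horizon (1 year by default, which is why times
are converted to years at read time) is measured by a
cumulative-case/dynamic-control time-dependent ROC: cases have an observed
event by the horizon, controls are still under observation beyond it, and
subjects censored earlier contribute through inverse-probability-of-
censoring weights ($1/\hat G(T^-)$ for cases, $1/\hat G(t^\*)$ for
controls, $\hat G$ the Kaplan-Meier estimate of the censoring
distribution). This estimator was chosen because it is well defined under
censoring and collapses to the empirical ROC when censoring is absent; the
unweighted variant is available (`ipcw = FALSE`) for sensitivity analysis.
The AUC is the trapezoidal integral over all distinct score thresholds,
identical to the weighted Mann-Whitney statistic with half-credit for tied
scores — the tests verify this equivalence against an exhaustive pairwise
oracle. The cutoff maximizes Youden's index (sensitivity + specificity − 1);
ties break toward the lower threshold, i.e. the larger high-risk group, and
a degenerate all-equal score returns that single value. Group assignment is
strict: score > cutoff is high-risk, equality is low-risk.

**Evaluation** (`compare_survival`, `cox_fit`, `summarize_cohort`,
`compare_feature_by_group`). Risk groups are compared by per-group
Kaplan-Meier curves and the log-rank test; the signature's independence
from clinical covariates is assessed by univariate and multivariate Cox
models (Efron ties, Wald 95% CIs with the 1.96 normal quantile). Covariates
enter as age in years, gender 0/1, and grade/stage as ordinal integers 1-4
— one hazard ratio per variable, matching the usual forest-plot reporting;
dummy coding was considered and rejected as the default because the
reference reporting style implies a single HR per variable. Cohort tables
report per-category counts and percentages rounded *half-up* to one decimal
(R's own `round` is round-half-even, which cannot reproduce standard
clinical tables). Externally supplied per-sample features (e.g. immune-cell
fractions from a deconvolution tool — running such a tool is out of scope)
are compared between risk groups by two-sided Wilcoxon rank-sum tests with
the conventional star thresholds.

## The synthetic cohort generator

`simulate_cohort` emulates the data a cross-platform signature study needs:

- i.i.d. log-normal background expression per gene (means N(2, 1), log-sd
  U(0.3, 1)) — arbitrary but realistic positive skew;
- planted pairs whose within-sample ordering equals a latent
  Bernoulli($\pi$) state ($\pi = 0.5$ by default, safely inside the
  constancy filter), imposed *by construction*: when the drawn values
  disagree with the latent state the two genes' values are swapped within
  that sample, so indicator control is exact. The two genes of a planted
  pair share their marginal parameters: otherwise the swap leaks the latent
  state into each gene's absolute level, and pairs of a planted gene versus
  background genes become strong proxy features that can displace the true
  pair in the lasso — the signal is supposed to live in the ordering, not
  in levels;
- survival from an exponential (or Weibull) baseline scaled by
  $\exp(\sum_k \beta_k z_{ks} + \text{covariate terms})$; the default
  baseline rate gives a median survival of 1.5 years at linear predictor 0,
  typical of advanced pancreatic cancer;
- censoring as an administrative follow-up cap (10 years) plus independent
  exponential drop-out whose rate is calibrated by bisection to a target
  censoring fraction (default 0.475, the training-cohort alive fraction in
  the motivating setting); infeasible targets (below what the cap alone
  inflicts) raise an error rather than silently miss;
- clinical covariates with marginals typical of a pancreatic-cancer cohort
  (~30% under 60, ~55% male, grade mostly 2-3, stage dominated by II).

`distort_platform` applies an independent strictly increasing warp
$b + a\,\log(1+x)^{g}$ ($a, g > 0$) per sample to emulate a platform
change; non-positive scale or power parameters are rejected.

What the generator does **not** emulate: gene-gene correlation structure,
batch effects within a platform, informative censoring, or anything about
immune-cell composition. Passing tests therefore demonstrate that the
estimators and the pipeline logic are correct under the model's own
assumptions — not that a signature built on real pancreatic-cancer data
will validate prospectively.

## Experiment sizes and the strong-signal regime

The end-to-end recovery experiment in the test suite uses cohorts of 300
training / 100 validation samples, 200 genes, five planted pairs with
log-hazard effects ±1.5, ~40% censoring, stability selection with 100
repetitions of 5-fold cross-validation, over 20 seeded replicates. Two of
these numbers deserve comment.

*Effect size.* The marginal log-rank screen tests each pair ignoring the
others, so the remaining planted signals act as a frailty: with five pairs
of |β| = β₀ at prevalence 0.5, the omitted-signal variance (~β₀²) attenuates
each pair's marginal log-hazard ratio by roughly 30%. At β₀ = 1 the
attenuated effect (~0.7) sits near the detection boundary of a p < 10⁻⁴
screen with ~180 events — per-pair power only ~80-90%, so some planted pair
usually fails the screen. Recovery experiments are therefore run at
β₀ = 1.5, where the attenuated marginal effect clears the screen with high
margin; that is the regime a "strong-signal" recovery check is meant to
probe. Weaker signals degrade gracefully (the screen, not the lasso, is the
first bottleneck) — users planning real studies should read the screen's
α and their expected effect sizes against this attenuation.

*Folds and repeats.* Stability selection costs repeats × folds penalized
path fits; 100 repetitions of 5-fold CV keep the 20-replicate experiment
at roughly ten minutes on one core while still averaging over fold noise.
The package defaults (1000 repetitions, 10 folds) are what a single
real-data build should use.

## Numerical choices and degenerate inputs

- Ties in event times: hypergeometric moments are summed per distinct event
  time in the log-rank statistic; Cox fits use Efron's correction.
- A log-rank call with zero events in both groups returns χ² = 0, p = 1
  (not an error); an empty group is an error.
- Constant features are dropped from lasso input with a warning; an
  all-censored cohort is an error everywhere a Cox likelihood is needed.
- An empty modal support (typically under `lambda_rule = "1se"` on pure
  noise) is an error advising a weaker rule, never a silent empty signature.
- Missing values are rejected at read time with the offending row/column
  named; nothing is imputed. Gene identifiers match case-sensitively by
  exact string — no alias resolution, so identifier harmonization is the
  user's responsibility.
- Whether input expression is raw or log scale is irrelevant by
  construction (log is strictly increasing); the orientation of the input
  file and the time unit of the clinical table are declared, not guessed.
- `screen_pairs` accepts `alpha = 1` as an explicit "screen off" setting;
  selection stays strictly `p < alpha`.
- Signature files store coefficients with 17 significant digits so the
  TSV round-trip is bit-exact.

## Known limitations

- The screen's raw-p policy at α = 10⁻⁴ controls nothing family-wise; it
  mirrors the practice this pipeline reproduces and is configurable.
- The modal-support rule can have low modal frequency when the screened set
  is large and correlated (the provenance records the frequency; treat
  values below ~0.3 with suspicion).
- The IPCW ROC assumes censoring independent of both score and outcome.
- Proportional hazards is assumed, not tested; no diagnostics are provided.
- Synthetic validation exercises transferability only with respect to
  monotone per-sample distortions, which is exactly the invariance the
  method guarantees — real cross-cohort differences (case mix, assay
  failure modes) are outside it.
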