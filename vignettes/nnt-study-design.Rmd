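---
title: "Designing biomarker validation studies on the NNT scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing biomarker validation studies on the NNT scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(nntdesign)
```

## The decision model and its assumptions

`nntdesign` addresses the simplest binary medical decision: some action
(treatment, referral, intensive monitoring, trial enrolment) is either best
taken or best withheld for each patient, according to a latent status we
call *best-to-act* versus *best-to-wait*. A binary biomarker test is
proposed to separate the two. The framework assumes:

* the decision is binary and the test is binary (continuous biomarker
  scores and movable cutoffs are out of scope);
* a single prevalence `p = Pr(best-to-act)` describes the deployment
  population, and the test's sensitivity and specificity are transportable
  from the validation sample to that population;
* the ethical trade-off between overtreating best-to-wait patients and
  missing best-to-act patients can be elicited from the design team.

The elicitation device is the *number needed to treat*: imagine `NNT`
patients of whom, with certainty, exactly one would benefit from the action.
Treating all helps that one and overtreats `NNT - 1`; waiting spares the
`NNT - 1` but abandons the one. The **discomfort range**
`(NNT_Lower, NNT_Upper)` brackets the values of NNT where neither choice is
comfortable. It is deliberately a pure value judgment: no probabilities are
involved, which sidesteps well-documented numeracy pitfalls. A useful test
must satisfy `NNT_Pos < NNT_Lower` in the positive group and
`NNT_Neg > NNT_Upper` in the negative group, with strict inequalities
(equality leaves the dilemma unresolved, so `nntdesign` treats boundary
values as failures).

Identifying one true positive among `NNT_Pos` treated positives and one
false negative among `NNT_Neg` untreated negatives gives the exact
correspondences `PPV = 1/NNT_Pos` and `NPV = 1 - 1/NNT_Neg`, hence the
required predictive values `PPV > 1/NNT_Lower`, `NPV > 1 - 1/NNT_Upper`.
NNT values are kept real-valued (they are expected counts); requiring
integers would break the algebra, and nothing in the elicitation depends on
it. An `NNT_Neg` of infinity is a meaningful limit (a perfect negative arm,
`NPV = 1`) and is represented and serialized explicitly as `Inf`; an
infinite `NNT_Pos` is rejected, since a test whose positives never benefit
has no clinical use. We admit `NNT_Lower >= 1` — whether an NNT of 1 can
ever be "uncomfortable" is a judgment we leave to the elicitation rather
than the validator.

## The contra-Bayes inversion

Prospective cohorts estimate predictive values directly, but a
retrospective case–control study — usually the affordable first step —
estimates sensitivity (cases are best-to-act patients identified in
hindsight) and specificity (controls). Converting required predictive
values into required test characteristics inverts Bayes theorem. With
`Odds = p/(1-p)`, `PPO = PPV/(1-PPV)`, `NPO = NPV/(1-NPV)`:

$$SP = \frac{PPO - Odds}{PPO - NPO^{-1}}, \qquad
  SN = \frac{NPO - Odds^{-1}}{NPO - PPO^{-1}}.$$

The inversion is meaningful exactly when the test moves the prior odds in
the expected directions, `PPO > Odds > NPO^{-1}`; `check_feasible()` reports
both margins and `contra_bayes()` refuses infeasible inputs, naming the
violated inequality. Equality on either side is classified infeasible: that
test arm conveys no information, and the solution degenerates. The
feasibility conditions are equivalent to the recovered `SN`, `SP` lying in
`[0,1]`, which the implementation checks rather than clamps — an
out-of-range value would indicate a bug, not a rounding inconvenience.

Numerically, the two ratios are evaluated after multiplying numerator and
denominator by `(1 - PPV)` and `(1 - NPV)` respectively, so predictive
values of exactly 1 become finite algebraic limits (`PPV = 1` forces
`SP = 1`, `NPV = 1` forces `SN = 1`) instead of `Inf/Inf`. Round-trip
identity with forward Bayes holds to near machine precision on feasible
inputs; the test suite checks `1e-9` over 10,000 random draws.

## The feasible region

`compute_region()` evaluates the inversion on a grid, either in
predictive-value axes or on NNT axes (`x = NNT_Pos = 1/PPV`,
`y = NNT_Neg = 1/(1-NPV)`, log-spaced between 1.05 and 1000 by default,
covering the clinically interesting range; the default resolution of
201×201 is fine enough for smooth contour plots while keeping the grid
under a second to compute). Under the algebra above, the feasible region in
predictive-value axes is exactly the open rectangle
`PPV > p`, `NPV > 1 - p`. Its corner `(p, 1 - p)` is the image of every
uninformative test, and the contours `SN = p` and `SP = 1 - p` pass exactly
through it. Approaching the left edge the inversion degenerates towards
`SN = 1, SP = 0` (a positive result that conveys nothing); approaching the
bottom edge towards `SN = 0, SP = 1`. Infeasible nodes are flagged with the
violated inequality (`ppv_not_above_prevalence`,
`npv_not_above_complement`, or `both`) so plots can shade the two
infeasible regions distinctly; their `SN`/`SP` values are `NA`, never
clamped. The tested artifact is the exported grid (`export_region()` /
`read_region()` round-trip through CSV); `plot_region()` is a thin optional
ggplot2 layer.

## Anticipated precision of a design

For planning, the package works with *anticipated results*: assume the
estimates come out at the hoped-for values and ask how precise they would
be.

* `anticipated_prospective_counts()` splits a cohort by the anticipated
  positive fraction and sets the success counts to
  `round(n_pos/NNT_Pos)` and `n_neg - round(n_neg/NNT_Neg)`. Rounding is
  half away from zero; the canonical 40-patient example is exact so the
  choice only matters for awkward group sizes.
* `exact_binomial_ci()` is the two-sided Clopper–Pearson interval from the
  beta-quantile closed form. The method and the 95% level were chosen
  because together they reproduce every printed interval of the worked
  example we validate against (19–81% and 83–100% for the prospective
  predictive values, 60–95% and 70–94% for the retrospective SN/SP); the
  suite cross-checks against `stats::binom.test` and verifies
  conservativeness by exhaustive enumeration for all `n <= 25` over a
  99-point grid of true proportions.
* `nnt_interval_from_pv_interval()` maps interval endpoints through the
  order-reversing reciprocals; an NPV upper limit of 1 maps to an infinite
  `NNT_Neg` bound, and comparisons treat `Inf` as larger than any finite
  value.
* `bayes_predictive_nnt_intervals()` draws `SN` and `SP` independently from
  Jeffreys posteriors `Beta(x + 1/2, n - x + 1/2)` updated with the
  anticipated counts, pushes each draw through forward Bayes at the stated
  prevalence, and reports equal-tailed quantile intervals of the NNT
  transforms. Defaults: level 0.95, `1e5` draws (quantile Monte-Carlo error
  well under 2% there; a warning fires below `1e4`), and an explicit seed
  in every report — the sampler saves and restores the caller's RNG state,
  so randomness never leaks through global state. Equal-tailed rather than
  highest-density intervals were chosen because the NNT transforms are
  monotone in the predictive values, making equal-tailed intervals
  transformation-equivariant, which highest-density intervals are not.

`minimum_n_search()` is deliberately modest plumbing: it scans total cohort
sizes (bracket doubling, then a linear scan, since integer rounding of
anticipated counts makes clearance non-monotone in `n`) for the smallest
cohort whose anticipated NNT-scale intervals clear the discomfort range. It
is not a power calculation — no sampling variability of the future estimates
enters, only the width of the anticipated intervals.

## The scaffold workflow

`load_scaffold()` / `run_scaffold()` drive the whole pipeline from a
versioned YAML or JSON file (schema in the help page; a filled-in example
ships in `inst/extdata/ctcl_scaffold.yaml`). The rendered report quotes the
team's free-text clinical scenario, goal and benefit statements verbatim, so
the intended clinical use travels with the numbers. Reports serialize to
JSON and parse back losslessly, with infinite NNT endpoints written as the
string `"Inf"`. Every stochastic quantity in a report carries its level,
draw count and seed. The CLI (`inst/cli/nntdesign`) is a thin wrapper over
`nnt_cli()`, which is tested in-process.

## Display conventions

Stored values are never rounded; formatting happens only at print time.
Predictive values print as whole percents, sensitivity and specificity to
0.1%, NNT values to one decimal up to 100 and three significant digits
above. Rounding is half-up (matching how such tables are conventionally
printed — e.g. `1/0.8` shows as `1.3`), with a relative epsilon of `1e-12`
so that floating-point representations landing a few ulps below a `.5`
boundary (e.g. `1/PPV = 5.749999999999997` where the exact value is 5.75)
still round as their exact values would.

## What the checks do and do not show

The test suite validates the algebra (round-trip identities, monotonicity,
coverage by enumeration) and reproduces a published worked example of the
framework. It does not — cannot — validate the elicitation itself: whether a
design team's discomfort range reflects their real values, whether the
stated prevalence matches the deployment population, and whether banked
specimens represent the time point at which the clinical decision would be
made are scientific questions outside any package's reach. One further
caveat: the predictive intervals published for the worked example's
retrospective step are not recoverable from the procedure as described
(independent Jeffreys posteriors from 18/22 and 34/40, 95% equal-tailed);
this package's simulation converges to (1.45, 3.09) for `NNT_Pos` and
(13.5, 75.2) for `NNT_Neg` instead of the published (1.4, 2.7) and
(16.4, 87.8), which correspond to about 88.8% central mass of the correct
posterior push-forward. We report what the stated procedure yields.

## Known limitations

Binary tests only; a single aggregate discomfort range (no multi-clinician
pooling or sensitivity analysis over elicitations); no frequentist power
calculations or group-sequential designs; prevalence is treated as known
rather than estimated with uncertainty. Where the required predictive values
are themselves infeasible at the stated prevalence, the contra-Bayes error
is surfaced for the user to revise the inputs — there is no automatic
adjustment.
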