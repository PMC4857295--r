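# nntdesign

Planning biomarker validation studies on the number-needed-to-treat scale.

## The problem

Most validation studies of binary biomarker tests are justified with
statistical criteria — p-values, hazard ratios, sensitivity and specificity —
that have at best a murky relationship to the medical decision the test is
supposed to improve. `nntdesign` supports the opposite workflow: start from
the clinical decision, elicit the ethical trade-off on the *number needed to
treat* (NNT) scale, and derive from it the performance a prospective or
retrospective validation study must demonstrate.

The package is for biostatisticians and clinical investigators designing
validation studies of a binary test that separates patients into a group for
whom it is best to act (treat, refer, enrol, monitor intensively) and a group
for whom it is best to wait.

## The model

Let `NNT` be the expected number of patients treated per patient who
benefits. The design team elicits a **discomfort range**
`(NNT_Lower, NNT_Upper)`: for observed NNT inside this interval neither
treating everyone nor treating no one is ethically comfortable. A test
splitting patients into positive and negative groups is clinically useful
when

```
NNT_Pos < NNT_Lower < NNT_Upper < NNT_Neg
```

Since one of `NNT_Pos` treated positives is a true positive, and one of
`NNT_Neg` untreated negatives is a false negative,

```
PPV = 1/NNT_Pos ,   NPV = 1 - 1/NNT_Neg ,
```

so the discomfort range converts directly into required predictive values —
the criteria for a *prospective* study. A *retrospective* (case–control)
study estimates sensitivity (SN) and specificity (SP) instead, and needs the
prevalence `p` of best-to-act patients. Writing `Odds = p/(1-p)`,
`PPO = PPV/(1-PPV)` and `NPO = NPV/(1-NPV)`, inverting Bayes theorem gives
the **contra-Bayes theorem**

```
SP = (PPO - Odds) / (PPO - NPO^-1)
SN = (NPO - Odds^-1) / (NPO - PPO^-1)
```

valid exactly when the test moves the prior odds in the expected directions,
`PPO > Odds > NPO^-1`. Around these mappings the package provides exact
(Clopper–Pearson) confidence intervals for anticipated study results, their
transforms to the NNT scale, Monte-Carlo Bayes predictive intervals for NNT
under independent Jeffreys posteriors on SN and SP, a feasible-region grid
for plotting, and a config-driven step-by-step design scaffold with a CLI.

## Worked example

Early-stage cutaneous T cell lymphoma (CTCL): about 15% of patients have an
unexpectedly rapid progressive course and would benefit from aggressive
upfront therapy. The principal investigator stipulates the discomfort range
(2, 30).

```r
library(nntdesign)

required_predictive_values(discomfort_range(2, 30))
#> Predictive values: PPV 50%, NPV 97%
```

A positive test must carry at least a 50% probability of rapid progression
(treat no more than 2 to help 1), a negative test at least a 97% probability
of indolent course (miss no more than 1 in 30). For a prospective cohort of
40 patients, anticipating 25% positive and estimates matching the targets:

```r
prospective_summary(prospective_design(40, 0.25, nnt_pair(2, 30)),
                    discomfort_range(2, 30))
#> Prospective design: n = 40 with 25% anticipated positive
#>   target NNT_Pos 2.0, NNT_Neg 30.0
#>   anticipated PPV 5/10: 19%-81% CI, NNT_Pos (1.2, 5.3)
#>   anticipated NPV 29/30: 83%-100% CI, NNT_Neg (5.8, 1190)
#>   clears discomfort range: positive side FALSE, negative side FALSE
```

The wide intervals show 40 patients cannot pin down the PPV — hence a
retrospective case–control study first. At prevalence 15% the required test
characteristics and the precision anticipated from 22 cases and 40 controls
are:

```r
contra_bayes(0.5, 29/30, 0.15)
#> Test characteristics: sensitivity 83.3%, specificity 85.3%

retrospective_summary(retrospective_design(22, 40, 18, 34, 0.15),
                      discomfort_range(2, 30), seed = 1)
#> Retrospective design: 22 cases, 40 controls, prevalence 15%
#>   anticipated SN 18/22: 60%-95% CI
#>   anticipated SP 34/40: 70%-94% CI
#>   required SN 83.3%, SP 85.3% (contra-Bayes)
#>   Bayes predictive NNT_Pos (1.5, 3.1), NNT_Neg (13.4, 75.4)  [1e+05 draws, seed 1]
```

The predictive intervals say: if the anticipated counts materialise, the
posterior belief about the deployed test's NNT in the positive group would
span roughly 1.5–3.1 patients treated per patient helped.

The same analysis runs end-to-end from a config file, from R or the shell:

```sh
Rscript inst/cli/nntdesign scaffold run inst/extdata/ctcl_scaffold.yaml
Rscript inst/cli/nntdesign contrabayes --ppv 0.5 --npv 0.96667 --prevalence 0.15
Rscript inst/cli/nntdesign region --prevalence 0.15 --axes pv --out region.csv
```

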