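# discountr

Delay discounting — the devaluation of an outcome with the delay until it is
received — is a workhorse behavioral construct in addiction research: heavier
drinkers tend to discount delayed monetary rewards more steeply, but the
association is small and potentially confounded by socioeconomic status and
age. `discountr` implements the full analysis pipeline for an
intertemporal-choice study of delayed reward discounting (DRD) and delayed
loss discounting (DLD) in frequent drinkers: task design generation, choice
modeling and maximum-likelihood fitting, questionnaire scoring and
preregistered exclusions, a synthetic-cohort generator, and the confirmatory
(H1–H5) plus exploratory statistical suites.

## The model

Choices are between a smaller-sooner amount `r1` and a larger-later amount
`r2` at delay `D` days. Delayed outcomes are valued with the modified
hyperboloid model

    V(a2) = r2 / (1 + kappa * D^s)        V(a1) = r1

where `kappa` (bounded to `[0, 1000]`) is the individual discount rate, and
`s` (`[0, 1]`) an individual temporal scaling exponent. In the loss
condition both values carry negative sign. Values map to immediate-choice
probabilities through a sigmoid

    p(a1) = 1 / (1 + exp(beta * (V(a2) - V(a1))))

with inverse temperature `beta` (`[0.01, 2]`): large `beta` means
near-deterministic value-based choice. Per participant and condition,
`(kappa, s, beta)` are estimated by bounded multi-start maximum likelihood,
and `kappa` is analyzed as `log(kappa + 0.0001)` so that the bounds map to
−9.21 and 6.91. Model-free indices (relative frequency of discounted
choices; discount factor at a one-year delay) complement the fitted rate,
and participants with a discounting frequency below 5% are classed as
nondiscounters.

The 96-trial-per-condition design is solved a priori: for a grid of
hypothetical discounting parameters, delays `{7, 30, 90, 180, 365, 1095}`
days and delayed amounts `{5, 10, 20, 50}` GBP, the immediate amount is
chosen so a hypothetical agent would pick it with a target probability
(default 0.5), then rounded to 10 p and randomized into alternating
reward/loss blocks.

## Worked example

Simulate one participant on the default design and fit the model:

```r
library(discountr)
design <- generate_design()
plan   <- randomize_blocks(design, seed = 1)
agent  <- tibble::tibble(participant_id = "P0001",
  kappa_R = 0.05, s_R = 0.8, beta_R = 1.5,
  kappa_L = 0.005, s_L = 0.4, beta_L = 1.0)
trials <- simulate_participant_choices(agent, plan, seed = 2)
fit_discounting(trials[trials$condition == "reward", ])
#> <discounting_fit> reward: kappa = 0.07377 (log kappa = -2.605), s = 0.768, beta = 1.531
#>   NLL = 18.2556 over 96 trials (27 starts, converged)
```

The fitted discount rate (log kappa −2.61, true value −3.00) comes with its
negative log-likelihood over the 96 usable trials; `s` and `beta` recover to
0.77 and 1.53 against true values 0.8 and 1.5.

Generate a full synthetic cohort matched to the published covariate
structure and run the preregistered analyses:

```r
cfg   <- cohort_config(n = 341, seed = 7)
cov   <- sample_covariates(cfg)
truth <- derive_true_params(cov$latents, cfg)
tab   <- cohort_truth_table(list(participants = cov$participants,
                                 ground_truth = truth, config = cfg))
run_confirmatory_suite(tab)
#> <confirmatory_report> preregistered hypotheses
#> # A tibble: 5 x 6
#>   hypothesis statistic   value          p     n significant
#> 1 H1         F          6.58   0.0107       341 TRUE
#> 2 H2         r         -0.0732 0.178        341 FALSE
#> 3 H3         F         14.0    0.00000143   333 TRUE
#> 4 H4         F          2.85   0.0594       333 FALSE
#> 5 H5         F_block    5.06   0.0251       333 TRUE
#>   (H2 regression not computed: correlation gate not passed)
```

H1 is the simple regression of AUDIT on the reward discounting parameter;
H2 gates its regression on a significant loss-side correlation (here absent,
so none is run); H3/H4 regress discounting and AUDIT on education and
income; H5 adds the discounting parameter to the SES model and tests the
R-squared increment — in this run ΔR² = 0.015 with Alf–Graf 95% CI
[−0.011, 0.041], a significant block F whose interval still covers zero,
the characteristic signature of a small unique effect. Per-analysis `n`
varies because missing questionnaire entries are excluded per analysis, not
listwise.

`run_pipeline(run_config(...))` chains all stages — design, cohort
simulation, per-participant fitting, quality control (completion < 80%,
single-key responding, mean RT < 500 ms), table construction, and both
suites — deterministically from one master seed, writing CSVs, a JSON
report, and the serialized configuration.

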