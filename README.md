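# vforage

Tools for analysing sequential decision-making in a five-day "virtual
foraging" task, for researchers in computational cognitive science who
want a tested, reproducible version of the full analysis chain: the
task's Markov decision process and its exact solution, the heuristic
decision variables that compete with it, a task simulator and
synthetic-participant generator with known ground truth, logistic
choice models with BIC evidence, group-level Bayesian model selection,
and hierarchical reaction-time regression.

## The model

An agent must keep an energy state s in {1..5} above zero over a
horizon of n = 5 days. Each day, one of two weather types (p, g) is
drawn with probability 0.5; foraging gains g points with probability p
and loses 2 otherwise, waiting surely loses 1; energy is capped at 5
and state 0 is absorbing starvation. The normative policy minimizes
the starvation probability p_starve(n, s, t) and is obtained by
backward induction over the 12-state (6 energy x 2 weather) process:

    Q(s, w, t, a) = survival probability of taking action a now
                    and acting optimally afterwards,
    dq(s, w, t)   = Q_forage - Q_wait.

The continuous value difference dq is the decision variable used in
the choice, RT and benchmark analyses. Choices are modelled as
p(forage) = 1 / (1 + exp(-DV)) with DV linear in candidate predictors;
per-participant evidence is summarised by BIC and aggregated either as
fixed-effects log group Bayes factors or by random-effects Bayesian
model selection (variational Dirichlet posterior, exceedance
probabilities, Bayesian omnibus risk, protected exceedance
probabilities PEP = EP(1 - BOR) + BOR/K). Log RTs are regressed on p,
dq, their choice uncertainties and the heuristic-optimal discrepancy
with participant-level random slopes.

## Worked example

```r
library(vforage)

f <- forest(weather(0.6, 1), weather(0.1, 1), start_energy = 2)
tab <- optimal_values(f, horizon = 5)
print(tab)
#> optimal value table, horizon 5
#> forest: bad (p = 0.10, g = 1), good (p = 0.60, g = 1), start energy 2
#> dq (forage - wait) at the first day:
#>      weather
#> state     bad   good
#>     1  0.0265 0.1592
#>     2 -0.1092 0.1762
#>     3 -0.0459 0.2204
#>     4 -0.2319 0.1354
#>     5 -0.0851 0.1296
```

Positive entries mean foraging improves five-day survival: here the
optimal agent forages in good weather, waits in bad weather except at
energy 1, where waiting is sure death (dq = 0.0265 > 0). Generate
synthetic participants and ask which single variable explains their
choices:

```r
ds <- generate_dataset(generative_params(n_participants = 6,
                                         n_sessions = 3), seed = 1)
#> synthetic dataset: 6 participants, 108.2 +/- 3.3 valid trials
#>   (of 120 days each; 56 starvation days overall)

ev <- fit_choice_models(ds$trials, choice_model_space("single"))
bms(ev, n_samples = 1e5, seed = 2)
#> random-effects BMS: 11 models, 6 participants (BOR 0.020)
#>               dq_h5 p_success  gain    ev ...
#> expected freq 0.059     0.379 0.059 0.090
#> EP            0.009     0.902 0.008 0.022
#> PEP           0.010     0.886 0.009 0.024
```

The probability of foraging success emerges as the best single
predictor (PEP 0.89 even in this six-participant demo), matching the
structure the generator builds in. `fit_rt()`, `opposing_trials()`,
`horizon_contrast()` and `starvation_benchmark()` continue the chain;
`run_pipeline(pipeline_config(...))` executes all stages and writes
CSV/JSON artifacts with a manifest.

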