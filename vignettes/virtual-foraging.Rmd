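---
title: "Modelling sequential decisions in a virtual foraging task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sequential decisions in a virtual foraging task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vforage)
```

## The task and its Markov decision process

`vforage` analyses behaviour in a sequential "virtual foraging" task.
An agent lives for up to five days in a *forest* defined by two
*weather types*, each drawn independently with probability 0.5 on every
day. A weather type is a pair (p, g): with probability p a foraging
attempt gains g energy points (g in 0..4), otherwise it loses 2.
Waiting loses exactly 1 point. Energy is capped at 5; energy 0 is
absorbing starvation, and the agent is rewarded only for being alive
(at any positive energy) after day five. Per forest the process has 12
states — 6 energy levels times 2 weather types.

The normative solution minimizes the starvation probability
p_starve(n, s, t) over a finite horizon of n = 5 days. `optimal_values()`
computes, by backward induction from the final day, the survival
probabilities Q(s, w, t, a) of foraging and waiting at every energy
state s, weather w and days-to-go t, together with their difference

dq(s, w, t) = Q_forage − Q_wait,

the continuous decision variable used throughout (policies that
binarize it discard the information about how strongly an action is
preferred). Induction is carried out on starvation probabilities
rather than survival probabilities so that states from which
starvation is unreachable (s > 2t, since the largest daily loss is 2)
have dq equal to *exactly* zero in floating point — exact indifference
is part of the model, not a tolerance question.

Agents may enter a forest with a non-normative horizon n ≠ 5; the
horizon then shrinks by one per day and is floored at one
(`value_difference_series()`), which is how myopic (h-1) and deep
(h-5) policies are compared on the same trials.

### Numerical verification

Because the horizon is short, the solver can be checked against an
independent oracle: `brute_force_survival()` enumerates every weather
sequence and outcome branch of an episode explicitly and evaluates any
policy exactly. The test suite verifies the backward-induction Q-values
against this enumeration to 1e-12 for the full 9 x 5 stimulus grid and
all horizons up to five, and verifies on reduced instances (horizon <=
3, where the reachable decision points allow enumerating every
deterministic policy) that no policy beats the backward-induction
policy.

## Heuristic decision variables

`compute_heuristics()` appends, per trial, the ten momentary/history
variables considered as alternatives to the optimal policy: p, g, the
myopic expected value pg − 2(1 − p) (waiting's EV is always −1), the
continuous and binarized energy state, the weather label, the day in
the forest, the change in energy relative to the previous trial
(computed across forest boundaries, missing on a participant's first
trial), win-stay-lose-shift (forage after a gain), and the h-1 value
difference. The EV range implied by the grids is −1.8 to 3.4; the
range is derived from the grid definition rather than hard-coded.
Models using the history variables drop each participant's first trial
(complete-case); per-model trial counts are carried in the fits.

The *good/bad* weather labels are defined only relative to each other.
We order them by the starvation probability each weather would imply
on its own (horizon-5 optimal play in a single-weather world starting
from energy 3), breaking ties by higher p, then higher g.

## Simulator and synthetic participants

`simulate_episode()`/`simulate_participant()` reproduce the generative
structure of the experiment: fair weather draws, stochastic foraging
outcomes, absorbing starvation (post-starvation days are emitted as
marker rows without choices, so the session bookkeeping of 400
possible days per participant is preserved), and sessions of 24
forests totalling exactly 40 days. The stated session structure (an
exponential length distribution with mean 2.5 *and* binding totals of
40 days in 24 forests) is internally inconsistent for an untruncated
exponential, so episode lengths are drawn from the exact conditional
distribution of 24 i.i.d. truncated-exponential lengths given their
sum — honouring both the distributional shape and the binding totals.
This makes one-day visits the most common, with roughly 1.7 days per
forest on average.

`generate_dataset()` builds complete synthetic samples with known
ground truth. Choices are generated closed-loop from a logistic policy
on the centred probability of foraging success and the h-5 value
difference,

DV = b0 + b1 (p − 0.5) + b2 dq,   p(forage) = 1 / (1 + exp(−DV)),

with independent normal participant-level deviations around the group
means. Defaults (b = 0.3, 6, 2.5 with SDs 0.3, 1.5, 0.8) were chosen
once so that the qualitative structure reported for human data —
p strongest, dq a reliable secondary influence, choice stochasticity
realistic — emerges; they live in `generative_params()` and are never
assumed inside the fitting code. Log RTs are linear in the five RT
predictors (p, dq, both choice uncertainties, discrepancy) with
participant random effects (independent normals; the data give no
basis for a richer covariance) and residual SD 0.25 on the log-seconds
scale, placing typical RTs near 0.75 s under the task's 2 s deadline.
A 1.6% non-response rate plus naturally occurring starvation days
leave roughly 370 valid trials of 400, matching the study's
accounting.

Because the uncertainty and discrepancy predictors must come from an
*independent* sample, the generator (when not handed reference
policies) first simulates a 21-participant "behavioral sample" and
uses its mean single-variable fits as the reference logistic
functions — the same independence logic as in the study design. The
exact composition of the experiment's 240 forest types is not
recoverable, so forest sets are sampled from the full grid
(distinct weather pairs plus a start energy in {2, 3, 4}) under a
seed; this is the one structural feature of the real data the
generator does not reproduce, and trial-level quantities that depend
on the forest mix (e.g. which heuristic shares the most variance with
dq) can differ from the published values for that reason.

## Choice models and model comparison

`fit_choice()` maximizes the logistic likelihood per participant
(via `glm`), recording the log-likelihood and BIC = k ln n − 2 ln L.
Complete separation is caught and refit with a tiny ridge penalty
(1e-6), flagged rather than fatal. Predictors are z-scored within
participant by default for cross-predictor comparability (dq lives in
[−1, 1], energy in 1..5); the raw-scale path used by the recovery
studies is a flag away. `choice_model_space()` enumerates the model
battery: 11 single-variable models, the 10 "second predictor given p"
models, all 55 pairs, triples containing the best pair, and five
interaction forms built from certainty- and discrepancy-weighted
predictors.

`lgbf()` aggregates fixed-effects evidence as log group Bayes factors
(log evidence approximated by −BIC/2, summed over participants;
best-vs-second gaps above 3 are flagged decisive). `bms()` implements
random-effects Bayesian model selection: a variational Dirichlet
posterior over model frequencies, exceedance probabilities by
Monte-Carlo Dirichlet sampling (1e6 draws by default, chunked to bound
memory; EPs are stable to ~0.005 at that size), the Bayesian omnibus
risk from the variational free energies of the frequency model versus
the equal-frequency null, and protected exceedance probabilities
PEP = EP (1 − BOR) + BOR/K. The prior is uniform (alpha0 = 1) and the
alpha iteration converges to 1e-8.

## Uncertainties, discrepancy, and reaction times

Given reference policies, `choice_uncertainty()` is the logistic
derivative sigma(1 − sigma) normalized to a maximum of one — the
slope-constant is omitted because every downstream use is rank-based
and the normalized form keeps the index in (0, 1]. The discrepancy is
|sigma(DV_p) − sigma(DV_dq)|. `opposing_trials()` binarizes both
policies' predictions at 0.5 (exact midpoints excluded) and selects
disagreement trials; `horizon_contrast()` does the analogous selection
between h-5 and h-k value-difference signs and tests each
participant's h-5-consistency against the 0.5 midpoint.

`fit_rt()` fits log RT on the five predictors with participant random
intercepts and slopes by maximum likelihood, falling back from an
unstructured random-effects covariance to independent slopes to an
intercept-only model when a fit fails, fails to converge, or is
singular (the structure used is recorded in the result). Fixed-effect
significance comes from likelihood-ratio tests against models dropping
one fixed effect at a time. `rt_opposing_contrast()` compares mean RTs
between heuristic-followed and optimal-followed choices on opposing
trials. Note a subtlety the synthetic studies expose: even with no
latency difference built in, this contrast is slightly positive,
because which policy a choice follows is correlated with the RT
predictors on the selected trials; injection-recovery analyses should
therefore difference against a zero-penalty baseline rather than
against zero.

## Policy benchmarking

`starvation_benchmark()` asks which single variable one should live
by: each candidate becomes a logistic policy (reference fit, scaled by
a softmax temperature; temperature 0 thresholds it) and is played
through full five-day episodes across a forest set with start energies
uniform on {2, 3, 4}, with Monte-Carlo starvation rates and standard
errors reported. The published protocol for this simulation is not
described in enough detail to reproduce its exact rates, so the
package treats the claim qualitatively; in our configuration the
p-based policy achieves the lowest starvation rate of all
single-variable policies at every temperature in the sweep
(0.5, 1, 2), and the exact h-5 policy beats them all, as optimality
requires. Probabilistic policies were preferred over thresholded ones
as the default because the choice models themselves are logistic;
both are available.

## Problem sizes and reproducibility

Everything stochastic flows through explicit seeds
(`with_seed`-style local RNG handling; no global state leaks). The
test suite exercises the full 9 x 5 grid exactly, and uses synthetic
cohorts at the study's scale (28 participants x 400 days) for the
model- and parameter-recovery studies: 10 replicate seeds for the
55-pair model recovery, 20 for coefficient recovery, 300 episodes per
forest across 45 forests per policy for the starvation benchmark.
These sizes were chosen to keep Monte-Carlo error comfortably below
the effects being tested.

## Limitations

The synthetic generator reproduces the study's structure, not its
data: passing tests demonstrate that the pipeline recovers known
ground truth under realistic noise, not that human participants behave
like the generator. Features deliberately not emulated include the
visual presentation (subfield layouts beyond (p, g)), sequential
effects other than the previous-trial energy change, any covariance
between random effects, and RT floors/deadline censoring. The exact
240-forest composition and the supplementary starvation-simulation
protocol of the original experiment are unavailable; both are
config-driven here and the corresponding published numbers (e.g. the
0.15 starvation rate, the 0.37 shared variance) are treated as
qualitative anchors, not targets.
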