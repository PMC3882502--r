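---
title: "Planning multi-arm screening trials within a drug-development program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning multi-arm screening trials within a drug-development program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamscreen)
```

## The planning problem

A sponsor with a long pipeline of candidate treatments runs small
*screening* (phase II) trials to decide which candidates deserve a large
*confirmatory* (phase III) trial, and repeats the process — new candidates,
new screening trial — until some treatment finally succeeds at phase III.
`mamscreen` answers the design question this loop poses: **how many arms
`K` should a screening trial carry, with how many patients `n1` per arm,
and how promising (`c1`) must an arm look before phase III is launched, if
the goal is to minimize the expected number of patients recruited until the
first confirmed treatment?**

The model:

* Each screening trial allocates `n1` patients to each of `K` experimental
  arms and to a shared control.  Responses are normal with unit standard
  deviation (all effects are standardized), and each arm is summarized by
  `Z[i] = (mean(X_i) - mean(X_0)) * sqrt(n1/2)`.
* True standardized effects are exchangeable draws from `N(m0, v0^2)`;
  the control effect is 0.  Successive screening trials test *new*
  candidates, so cycles are independent and identically distributed.
* The confirmatory trial is sized before the program starts: one-sided
  level `alpha` (family-wise if multi-arm), power `1 - beta` at the
  clinically relevant standardized difference `delta`.  Its design never
  depends on the screening results — a clinically relevant difference is a
  property of the disease, not of the previous trial.

Two progression rules are supported, each with single-stage or
group-sequential confirmatory trials, giving four design families:

| family | screening rule | confirmatory trial |
|---|---|---|
| top-treatment, single-stage | best arm proceeds iff `max Z > c1` | two-arm, fixed size |
| all-interesting, single-stage | every arm with `Z > c1` proceeds | multi-arm, Dunnett-type FWER control |
| top-treatment, group-sequential | as above | `J`-stage triangular boundaries |
| all-interesting, MAMS | as above | multi-arm, multi-stage (simulation) |

## The optimality criterion

Because cycles are i.i.d. and the program stops at the first confirmatory
success, the expected total sample size follows the renewal identity

$$ESS = \frac{E[\text{patients per cycle}]}{P(\text{cycle ends in phase III success})},$$

which holds regardless of the correlation between a cycle's cost and its
outcome.  For the top-treatment single-stage family this specializes to
`ESS = ((K+1) n1 + 2 n2 E(P1)) / E(P2)`, with `E(P1)` and `E(P2)` the
per-cycle probabilities of conducting, and of winning, a confirmatory
trial.  Both are prior-predictive quantities: averages over the effect
prior as well as the trial noise.

The key computational device, used throughout, is conditioning on shared
quantities to factorize the `K` arms.  Given a treatment's own sample
mean, the events "beats the other `K-1` arms" and "clears `c1` once the
control mean is integrated out" are independent products of normal CDFs,
so `E(P1)` is a one-dimensional integral and `E(P2)` (which additionally
weights by the confirmatory power function at the treatment's true effect)
a two-dimensional one.  For the all-interesting family, conditioning on
the two control means (screening and confirmatory) makes the arms
conditionally i.i.d., collapsing the `2^K` subsets of passing treatments
to `K + 1` counts with binomial multiplicities.  All integrals are
Gauss–Hermite sums (96 nodes by default), accurate far beyond the 3–4
significant figures the published design tables are quoted to; the test
suite verifies them against closed forms where available and brute-force
Monte-Carlo oracles elsewhere.

## Worked example

The reference scenario used throughout the package is `m0 = 0`,
`v0 = 0.1`, `delta = 0.25`, `alpha = 0.025`, power 0.9:

```{r}
prior <- prior_spec(0, 0.1)
conf <- confirmatory_spec(delta = 0.25, alpha = 0.025, beta = 0.1)
ess_top_single(screening_design(K = 9, n1 = 22, c1 = -0.429), prior, conf)
```

Nine-arm screening trials with 22 patients per arm minimize the ESS for
this scenario (about 3805 patients); the optimal threshold is *negative* —
it is efficient to launch a confirmatory trial even when the best arm
looks slightly worse than control, because with nine draws from the prior
the best arm is usually genuinely good.  The family-wise screening error
(0.965) looks alarming but is the correct reading of a deliberately
permissive gate, and pinning `c1 = 0` costs under 0.2% of ESS:

```{r, eval = FALSE}
scan_K(1:15, prior, conf)            # argmin at K = 9
sensitivity_at(9, prior, conf, c1 = 0)
```

## Design decisions

**Standardization.** All computations fix the within-arm standard
deviation at 1; `m0`, `v0`, `delta` and `c1` are in effect-size units.
The published tables this package reproduces are stated in the same units.

**Continuous sample sizes.** Confirmatory sizes `n2` are continuous by
default (`integer = TRUE` rounds up); optimization treats `n1` as
continuous and then re-optimizes `c1` at the two neighbouring integers.
The ESS difference from rounding is below 0.3%.

**Multi-arm power convention.** `n2(i)` makes the *marginal* power of a
specific treatment — its own statistic crossing the Dunnett critical value
`c2(i)` when its effect is `delta` and the others' are 0 — equal to
`1 - beta`.  The marginal event ignores the other arms, so the continuous
solution is closed-form; at `i = 1` it coincides with the two-arm formula.

**Triangular boundary calibration.** Group-sequential confirmatory trials
use triangular stopping boundaries at equal information increments:
`u_j = C (1 + t_j) / sqrt(t_j)`, `l_j = -C (1 - 3 t_j) / sqrt(t_j)` with
`t_j = j / J`, meeting at the final analysis.  Both the scale constant `C`
and the per-stage size are calibrated on *efficacy-crossing* probabilities
with the futility bounds treated as non-binding — the standard regulatory
convention in which type-I error control must survive a sponsor overrunning
a futility bound.  The futility bounds are then applied operationally when
stopping probabilities, expected sample sizes and success probabilities
are computed, so the attained (futility-binding) error rates are slightly
conservative: for `J = 2` the design attains type-I error 0.0235 and power
0.879 against nominal 0.025 / 0.9.  Calibrating instead with binding
futility (attaining the nominal rates exactly under the stopping rule)
lowers the resulting program ESS by about 1.5%; the non-binding convention
is the package default because it is the one under which the published
two-stage design tables reproduce to within 1%, and because it is the more
defensible convention in practice.  No discreteness ("Christmas-tree")
corrections are applied: the discrete-look design is calibrated exactly by
numerical integration instead.

**Stage-probability recursion.** Stopping probabilities for any `J` use
the classical density recursion on the score scale over the continuation
regions (Gauss–Legendre panels, 160 nodes per stage).  For `J = 2` the
recursion is verified against exact bivariate-normal probabilities, and
for all `J` against trial simulation.

**MAMS trials.** For the all-interesting family with an interim analysis,
an `i`-arm trial uses the same triangular shape with its constant
re-calibrated so that the probability *any* arm ever crosses an efficacy
bound under the global null is `alpha` (non-binding, conditioning on the
shared control path), and per-stage size from the marginal power rule.
Arms are dropped individually at futility bounds; the trial stops at the
first efficacy crossing.  Two stages are supported for multi-arm trials —
the configuration of practical interest — while the two-arm machinery
handles any `J`.

**Optimization.** Nelder–Mead on `(log(n1 - 1), c1)` — the transform
enforces `n1 > 1` without penalties — from start `(20, 0.5)` plus two
perturbed restarts, followed by the integer refinement of `n1`.  The
objective is deterministic for the three analytic families; the
simulation-backed family evaluates every candidate on one shared dataset
bank (common random numbers), which keeps the simulated ESS surface smooth.

**Degenerate inputs.** `v0 = 0` collapses the prior to a point mass and is
handled by a single quadrature node (used by tests: with `m0 = 0` the
success probability is exactly `alpha` times the recommendation
probability).  `c1 = -Inf`/`Inf` give the limiting designs.  A design
whose success probability vanishes reports an infinite ESS rather than an
error.

## What the simulation engine emulates — and what it does not

The dataset bank (`build_bank()`) draws true effects from the prior and
standard-normal noise per arm and stage; sample means for any candidate
`(n1, n2)` are formed by scaling.  This is *exact* for the normal model —
the simulation and analytic paths estimate the same estimand, which is why
the test suite can demand 3-standard-error agreement between them.  What
neither path models: non-normal or heteroscedastic responses, correlated
treatment effects (dose–response pipelines), drift between screening and
confirmatory populations, different endpoints across phases, or a finite
candidate pipeline.  Passing tests therefore certify the computation of
this model, not the realism of the model for any particular program.

Default replicate counts are 100,000 for optimization-time estimates and
of the order of 200,000 programs for sample-size quantiles (the published
quantile values used up to 5,000,000); bootstrap standard errors are
reported so users can judge the residual noise.  The test suite and the
reproduction script use problem sizes (up to 10^7 oracle replicates,
200,000 simulated programs) chosen to keep every published-value check
well inside its tolerance at interactive runtimes.

## Known limitations

* One control arm per trial and equal allocation everywhere, as in the
  patient-count identities `(K+1) n1` and `(i+1) n2(i)`.
* Normal endpoints with known (standardized) variance; binary or
  time-to-event endpoints would need their own z-approximations.
* The all-interesting analytic path covers single-stage confirmatory
  trials; multi-stage multi-arm programs go through the simulation engine.
* The optimizer guarantees local optimality (verified on a neighbour grid
  in the tests), not global; the published optima are reproduced from the
  default starts.
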