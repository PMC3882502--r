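# mamscreen

Optimal design of multi-arm screening trials embedded in a
drug-development program.

## The problem

A funder with a deep pipeline of candidate treatments screens them in
small multi-arm phase II trials — `K` experimental arms plus a shared
control, `n1` patients per arm — and sends promising arms (screening
z-statistic above a threshold `c1`) to large confirmatory phase III
trials, repeating with fresh candidates until a treatment is finally
confirmed. `mamscreen` computes the **expected number of patients
recruited until the first phase III success (ESS)** for such programs and
optimizes the screening design `(K, n1, c1)` to minimize it.

Treatment effects are standardized and exchangeable, `mu_i ~ N(m0, v0^2)`
with the control at 0. Since program cycles are independent and
identically distributed, the renewal identity gives

    ESS = E[patients per cycle] / P(cycle ends in phase III success)

where both quantities are prior-predictive: for the top-treatment rule
with a fixed-size phase III,

    ESS = ((K + 1) n1 + 2 n2 E(P1)) / E(P2)

with `E(P1)` the per-cycle probability a confirmatory trial is conducted,
`E(P2)` the probability it is conducted *and* succeeds, and
`n2 = 2 (z_{1-alpha} + z_{1-beta})^2 / delta^2`. Both reduce to one- and
two-dimensional integrals evaluated by Gauss–Hermite quadrature.

Four design families are covered:

* **top-treatment / single-stage** — only the best arm may proceed (analytic);
* **all-interesting / single-stage** — every arm above `c1` proceeds to one
  multi-arm confirmatory trial with Dunnett-type family-wise error control
  (analytic);
* **top-treatment / group-sequential** — `J`-stage confirmatory trials with
  triangular stopping boundaries (analytic);
* **all-interesting / multi-arm multi-stage** — simulation engine with a
  reusable common-random-numbers dataset bank.

## Worked example

```r
library(mamscreen)

prior <- prior_spec(m0 = 0, v0 = 0.1)
conf  <- confirmatory_spec(delta = 0.25, alpha = 0.025, beta = 0.1)

ess_top_single(screening_design(K = 9, n1 = 22, c1 = -0.429), prior, conf)
#> Program operating characteristics
#>   ESS until phase III success : 3805.4 patients
#>   P(confirmatory trial/cycle) : 0.9715
#>   P(phase III success/cycle)  : 0.2295
#>   Screening family-wise error : 0.9653
#>   Screening power             : 0.4119
```

Reading: each cycle screens 9 candidates (10 × 22 = 220 patients); with
probability 0.97 the best arm clears `c1 = -0.429` and a 2 × 336-patient
confirmatory trial runs, which succeeds 23.6% of the time it is
conducted — so on average about 3805 patients are recruited before the
program confirms its first treatment. The screening "family-wise error"
0.965 is the probability a confirmatory trial is triggered when all nine
effects are truly null; the deliberately permissive gate is what makes the
program efficient, since a phase III failure is cheap relative to waiting
for a perfect phase II signal.

Optimizing instead of evaluating:

```r
scan_K(1:15, prior, conf)
#> ...
#> Overall optimum: K = 9 (ESS = 3805.4)

sensitivity_at(9, prior, conf, c1 = 0)$pct_increase   # cost of a sane threshold
#> [1] 0.175
```

A command-line interface wraps the same functions
(`inst/cli/mamscreen`): `evaluate`, `optimize`, `quantile`, and
`table <table1|table2|table3|table4-crest>` presets that write the design
tables as CSV with a JSON run-metadata sidecar, e.g.

```sh
Rscript inst/cli/mamscreen evaluate --K 9 --n1 22 --c1 -0.429
Rscript inst/cli/mamscreen table table1 --out table1.csv
```

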