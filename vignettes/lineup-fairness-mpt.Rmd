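---
title: "Measuring lineup fairness with the 2-HT eyewitness identification model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lineup fairness with the 2-HT eyewitness identification model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineupmpt)
```

## The measurement problem

A police lineup is *fair* when the known-innocent fillers are plausible
alternatives to the suspect, so that nobody can pick the suspect out
without an actual memory of the culprit. The traditional way to measure
fairness is the mock-witness task: people who never saw the crime are
asked to guess who the suspect is, and measures such as Tredoux's *E*
(effective lineup size) and the proportion of suspect selections are
computed from their choices. But mock witnesses are forced to choose and
are told that someone may stand out — two features absent from a real
eyewitness task — so mock-witness fairness need not transfer.

The alternative implemented here measures biased suspect selection
*directly from eyewitness identification decisions*, using a
two-high-threshold (2-HT) multinomial processing tree (MPT) model over
the six observable response categories: suspect identifications, filler
identifications and rejections, in culprit-present and culprit-absent
lineups.

## The model

Four latent-process probabilities generate the data, with lineup size
$k$ a design constant (here $k = 6$, entered exactly as $1/k$, never as
a rounded decimal — rounding would break tree normalization):

* $d_P$ — detection of the culprit's presence (culprit-present tree);
* $b$ — *biased suspect selection*: choosing the suspect without
  memory because the photograph stands out. This is the unfairness
  parameter;
* $g$ — guessing-based selection among the $k$ members, splitting
  $1/k$ : $(k-1)/k$ between suspect and fillers;
* $d_A$ — detection of the culprit's absence (culprit-absent tree).

Culprit-present category probabilities:

$$P(\text{suspect}) = d_P + (1-d_P)\,b + (1-d_P)(1-b)\,g/k$$
$$P(\text{filler}) = (1-d_P)(1-b)\,g\,(1-1/k)$$
$$P(\text{reject}) = (1-d_P)(1-b)(1-g)$$

and culprit-absent:

$$P(\text{suspect}) = (1-d_A)\,b + (1-d_A)(1-b)\,g/k$$
$$P(\text{filler}) = (1-d_A)(1-b)\,g\,(1-1/k)$$
$$P(\text{reject}) = d_A + (1-d_A)(1-b)(1-g).$$

Each tree's three probabilities sum to one identically; the test suite
asserts this to $10^{-12}$ and checks the closed forms against a path
enumeration through the `.eqn` export (`serialize_eqn()`, `parse_eqn()`,
`eval_eqn()`).

## Estimation

`fit_mpt()` maximises the product-multinomial log-likelihood jointly
over conditions. Equality restrictions (`restriction_set()`,
`base_restrictions()`, `restrict_equal()`) map (condition, parameter)
slots to shared free groups; this is how the *base model* of a
four-condition experiment is formed ($d_A$ shared everywhere, $d_P$ and
$g$ shared within lineup format, $b$ free: 9 free groups, 16
independent category proportions, hence a $G^2(7)$ fit statistic).

Numerical choices:

* each free group is optimised on the logit scale (no box
  constraints), with BFGS, relative tolerance $10^{-12}$;
* 10 starts by default — one at 0.5 for every parameter plus seeded
  random starts — guarding against local optima in the $b$/$g$
  trade-off; the seed is a required, recorded input. Simulation loops
  use 2 starts; on the bundled data 2-start and 10-start fits agree to
  all printed digits;
* $G^2 = 2\sum n \ln(n/\hat e)$ over cells with $n > 0$; observed zero
  cells contribute zero; a zero *expected* cell with positive observed
  count yields an infinite, flagged statistic;
* tiny negative $G^2$ or $\Delta G^2$ (independent optimisations,
  within $10^{-6}$) is clamped to zero;
* standard errors come from the numerically differentiated observed
  information on the logit scale, delta-method back-transformed;
  boundary estimates are flagged and their SE reported as `NA`, never
  fabricated.

`compare_mpt()` computes $\Delta G^2$ for strictly nested restriction
sets (partition refinement is verified structurally; comparing a model
with itself is an error), with Cohen's $w = \sqrt{\Delta G^2 / N}$,
where $N$ counts all identification decisions entering the joint fit —
each participant contributes four. `sensitivity_w()` inverts the
noncentral-chi-square power function to give the minimum detectable
$w$; with $\alpha = .05$, power $.95$, $df = 1$ this reproduces the
published sensitivity figures ($w \approx 0.06$ at $N = 3132$).
The $df = 1$ choice matches the single-restriction tests actually
reported; the source analyses do not state their df, so this is an
inference, documented here.

## Fairness measures

`tredoux_e()` is $1/\sum_i p_i^2$ over the member choice proportions —
the point-value formulation, without the sampling-variance correction of
the original derivation, because only point values are needed for the
reproduced analyses. `proportion_suspect()`, `two_proportion_z()`
(pooled variant), `resultant_suspect_proportion()` (innocent-suspect ÷
all culprit-absent identifications) and `identification_rate()` follow
the standard definitions. Averages over the four lineups of a condition
use per-lineup *E* then the arithmetic mean, and count-weighted pooling
for proportions (`average_fairness()`); with equal counts per lineup the
weighting is immaterial.

The mock-witness study's per-member choice distributions are not bundled
(they live in an external repository), so its *z* test is recomputed
from counts reconstructed from the printed proportions: 47.5% of
$385 \times 4 = 1540$ choices is 731.5; both adjacent integers
reproduce $z = 12.8$ to one decimal, and the tests assert both.

## The synthetic-data generator

`simulate_eyewitness()` draws category counts from multinomials with
the model's own probabilities: per condition, participants × 2 trials
per tree (the four-lineups-per-participant, two-per-tree design).
Decisions are independent within participants — exactly the assumption
of the product-multinomial likelihood — so a green recovery test
establishes that the estimator inverts its own generative model at
realistic sample sizes; it does *not* establish robustness to
participant-level dependence, which real data may contain and the model
(like the reproduced analyses) ignores. `simulate_mock_witness()` draws
a witness's choice with suspect probability $(1+s)/(k+s)$ for bias knob
$s \ge 0$: $s = 0$ is the perfectly fair lineup, $s \to \infty$ the
maximally unfair one.

Defaults mirror the reproduced study: $k = 6$, four decisions per
participant, per-condition participant counts near 200, generating
values near the fitted ones ($d_P \approx 0.27/0.17$, $g \approx
0.59/0.80$, $d_A = 0.04$, $b$ in 0.05–0.30). The type-I-error
calibration uses this world with the tested $b$ equality imposed; the
spec of the null world is otherwise open, and fixing it at the fitted
values is the most informative choice.

## Known limitations

* **Wald coverage near the boundary.** The ±2 SE recovery check is
  marginal for $d_A = 0.04$ at these sample sizes: the delta-method SE
  shrinks with the estimate, so intervals from near-zero estimates
  miss the truth. Long-run coverage of the shared $d_A$ group is
  ≈ 0.904 (1000 replications) — barely above the 0.90 criterion — and a
  200-replication run can land either side of it (the bundled run
  lands below). The other eight parameter groups sit at ≈ 0.95. A
  transformation-respecting (logit-scale) interval would behave
  better; the package reports probability-scale SEs for comparability
  with the established MPT tools, and the check honestly measures that
  interval.
* Asymptotic inference only: no bootstrap or Bayesian intervals.
* No confidence ratings, response times, showups, or fillers-only
  culprit-absent trees; no participant-level heterogeneity.
* The `.eqn` export writes the $1/k$ split as a pseudo-parameter
  `u_<condition>` that consumers must fix at $1/k$, because the plain
  dialect has no numeric literals.
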