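---
title: "Detecting hot hands with subordinated self-exciting point processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hot hands with subordinated self-exciting point processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hothands)
```

## The question and the representation

The hot-hand question asks whether success breeds success: does a strong
performance raise the probability that the next performances are also
strong?  `hothands` answers it for ordered, non-negative performance
sequences — the motivating case is cricket batting careers, where player
$j$ scores $S_j(t)$ in their $t$-th game, $t = 1, \dots, \tau_j$.

The package's central device is a change of clock.  The *performance time*

$$H_j(t) = \sum_{i \le t} \frac{1}{S_j(t_i)}$$

maps the career onto a one-dimensional point process: each game is an event
on the $H$ axis, and a run of high scores becomes a tight cluster of
events, because good games contribute small increments.  Temporal
structure in the scores is thereby turned into *clustering of points*,
which is exactly what self-exciting point-process machinery is built to
detect.  On this axis we model the conditional intensity as a Hawkes
process,

$$\lambda(t) = \mu + \sum_{t_i < t} \varphi(t - t_i),$$

where $\mu$ is the background rate — the player's intrinsic performance
level — and the kernel $\varphi \ge 0$ encodes how much a past event
boosts the present.  The *branching ratio*
$n = \int_0^\infty \varphi(t)\,dt$ is the mean number of events directly
triggered per event; $n$ near 0 means no carry-over, $n$ near 1 means
strong self-excitation, i.e. a strong hot hand.

Two assumptions matter.  First, the background rate is constant within a
career: seasonal or ageing trends are absorbed into apparent excitation if
present (a known limitation, see the end).  Second, excitation is linear
and additive in past events, which keeps estimation tractable and is the
standard first-order model of endogenous clustering.

## Handling zero scores

$1/S$ is undefined for a duck ($S = 0$), and ducks are common.  The
package floors scores at `s_min` before inversion:
$\tilde S = \max(S, s_{\min})$, with default $s_{\min} = 0.5$.  The
default makes a duck's increment (2.0) strictly larger than the increment
of any positive integer score ($\le 1.0$), preserving the
worse-score-longer-gap ordering while keeping $H$ finite.  This is the
single most consequential free choice in the transformation, so it is an
explicit argument of `to_performance_time()` and is carried in the
returned object; the round trip `from_performance_time()` returns
`s_min` in the slots that were floored, and the tests pin this behaviour
down.

## Nonparametric EM estimation

`hawkes_em()` estimates $\mu$ and a piecewise-constant kernel (8 linear
bins by default) by expectation–maximisation over the latent branching
structure: in the E-step each event is apportioned between the background
($\propto \mu$) and each earlier event within the kernel support
($\propto \varphi$ at that lag); in the M-step $\mu$ becomes the summed
background responsibility over the horizon, and each bin height the summed
responsibility in that lag bin divided by the bin's *exposure* — the total
length of that lag interval actually observable before the horizon, summed
over events.  The fractional exposure makes each M-step the exact
maximiser of the complete-data likelihood, which is what guarantees the
monotone log-likelihood trace the tests assert (an integer count of
"events whose window fits" is the limiting approximation and can break
monotonicity near the horizon), and it removes the downward bias of
kernel tails near the end of the observation window.

Numerical choices, all exposed as arguments:

* **Kernel support**: twice the 95th percentile of inter-event gaps.  The
  gap scale differs by orders of magnitude between players (it is set by
  score level), so a fixed support would be meaningless; a gap-quantile
  rule adapts it per career.
* **Initialisation**: $\mu_0 = 0.5\,N/T$ and a uniform kernel with
  $n_0 = 0.5$, a symmetric start that lets the data decide the split
  between background and excitation.
* **Convergence**: relative log-likelihood change below $10^{-6}$, at most
  500 iterations; non-convergence is reported in the fit object, not
  raised.
* **Subcriticality** is not imposed during EM; fits with $n \ge 1$ are
  flagged `supercritical` so that shuffle-null comparisons retain them.

The log-likelihood of any window uses the exact piecewise-linear
integrated kernel, verified in the tests against breakpoint-aware
quadrature at $10^{-8}$ and against the Poisson closed form at
$10^{-12}$.  Goodness of fit uses the time-rescaling theorem
(`residual_gof()`): compensator-transformed gaps are Exp(1) under the true
model, tested by KS; the test suite checks that this rejection rate is
nominal on simulated data and that badly wrong models are rejected.

## The evaluation experiment

`evaluate_career()` runs the per-career experiment.  The first 80% of
games (floor rule) train the model; the last 20% are scored by
out-of-sample log-likelihood with the intensity conditioned on the
training history, so excitation crossing the split boundary — the
phenomenon under test — contributes.  One hundred controls shuffle the
*training scores only* and re-fit; the validation window is bit-identical
across controls because the training increments are permutation-invariant
in total.  The relative difference
$\delta = (L^{\text{model}} - L^{\text{control}})/L^{\text{control}}$
uses the median control.  Separately, the branching ratio of the full
career is compared with branching ratios re-estimated on whole-career
shuffles.

**Why two p-values per comparison.**  The classical construction — a
one-sample Wilcoxon signed-rank on the hundred differences
$L^{\text{model}} - L^{\text{control}}_i$ — is reported
(`wilcoxon_p_*`) but is *anticonservative*: all hundred differences share
the single real value, so they are strongly positively correlated and the
null rejection rate at $\alpha = 0.05$ is near 0.4, not 0.05 (easily
verified by simulation, and worth keeping in mind when reading descriptive
hot-hand literature built on this construction).  The headline p-values
(`p_loglik`, `p_branching`) are therefore exact *placement* probabilities,
$(1 + \#\{\text{controls} \ge \text{real}\})/(M+1)$: under the shuffle
null the real career is exchangeable with its controls, so these are
calibrated by construction.  The acceptance tests verify calibration
(type-I in $[0.02, 0.10]$ on 200 i.i.d. careers) and power (over half of
200 careers with true branching 0.6 detected) for the headline test.

At cohort level, `cohort_summary()` counts significant careers and
attaches the exact binomial meta-probability of that count under a global
null with per-test error $\alpha$ — the same arithmetic used at the
reference cohort sizes (98 and 73 tested streaks) in the acceptance
script.  Team series from `team_performance_series()` (per-game sums of
individual scores) run through the identical machinery.

## Winning streaks

`streak_significance()` handles outcome sequences.  A streak is a maximal
run of wins; draws, ties and no-results break streaks — a streak is
continuous *wins*, so anything that is not a win ends it.  The null
ensemble permutes the outcome sequence itself (1000 shuffles by default),
preserving the win count.  For an observed (length $n$, frequency $f$)
pair, $p(n)$ is the fraction of null trajectories whose longest streak
reaches $n$, and $p(n_f)$ the fraction containing at least $f$ streaks of
length at least $n$ — the conditional read as a proper joint tail
probability, which also yields the logical guarantee
$p(n_f) \le p(n)$.  Monte-Carlo p-values use the add-one correction
$(k+1)/(M+1)$ so none is exactly zero.  All five standard corrections
(Bonferroni, Holm, Hochberg, Benjamini–Hochberg, Benjamini–Yekutieli) are
applied to the $p(n)$ and $p(n_f)$ families across the streaks handed in
together (per team, in the pipeline); the headline `extreme` label uses
Holm — valid under arbitrary dependence without the FDR reinterpretation —
and a streak is `extreme` when either adjusted p-value falls below
$\alpha$.

## What the synthetic generator does and does not emulate

`synthesize_career()` provides the ground-truth test surface.
`null_iid` mode draws zero-inflated geometric scores (mean 25, 8% extra
mass at 0) — the heavy right tail and frequent ducks of batting scores
with no temporal structure.  `hot_hawkes` mode inverts the subordination:
it simulates a Hawkes process on the $H$ axis ($\mu$ defaulting to
$25(1-n)$ so the event rate matches the score level, exponential-shaped
kernel with memory of about 2.5 mean gaps) and converts gaps to scores by
$S = \mathrm{round}(1/\Delta H)$ clamped to $[1, 500]$.

The generator emulates the marginal score distribution and controllable
self-excitation; it does not emulate real careers in at least three ways.
First, the clamp piles the strongest performances onto ties at
$S_{\max} = 500$, so *rank-based* statistics (the top-three co-location
analysis of `delta_distributions()`) lose their signal in hot synthetic
cohorts — ties are resolved by career order, not by gap structure.  The
sensitivity of that detector is therefore tested with planted
co-location, and passing those tests says nothing about clamp-induced tie
behaviour on real data, where exact top-score ties are rare.  Second,
scores are stationary: no ageing, form cycles or opposition strength.
Third, win/loss sequences from `synthesize_outcomes()` use a one-step
Markov persistence, the simplest streaky alternative.  Calibration and
power results on these cohorts transfer to real data only to the extent
that these simplifications are benign.

## Problem sizes and reproducibility

The simulation studies are sized for a desk machine: parameter recovery
uses 20 simulated processes with horizon 2000 (roughly 4000 events each);
calibration and power use cohorts of 200 careers of length 100–150 with
100 shuffle controls per career; the streak null calibration uses 50
teams with 1000-shuffle ensembles.  Every randomised routine accepts a
seed, and cohort-level functions derive one substream per (entity, role)
pair from the master seed, so results are reproducible and independent of
evaluation order or parallel scheduling; configuration and seed are
echoed into every pipeline artifact.

## Known limitations

* A constant background rate within each career; slow trends masquerade
  as excitation.
* The zero-score floor is a modelling choice, not an estimate; results
  for players with many ducks are sensitive to `s_min`, which is why it
  is logged everywhere.
* The histogram kernel's support rule assumes the gap distribution is not
  too heavy-tailed; extremely short careers (below the 30-game filter)
  give unstable fits, which is the reason for the filter.
* The placement p-value's resolution is $1/(M+1)$; with 100 controls the
  smallest attainable p is about 0.01, so per-career evidence is capped
  and cohort-level aggregation does the heavy lifting.
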