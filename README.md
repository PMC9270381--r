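# hothands

Detection and quantification of the **hot-hand effect** — positive serial
dependence in performance — in ordered score sequences, built for sports
analytics and for anyone studying persistence in careers of repeated
attempts (the motivating case is international cricket batting).

## The method

A career is a score sequence $S(t) \ge 0$, $t = 1,\dots,\tau$, indexed by
game order. The package subordinates it to a **performance time**

$$H(t) = \sum_{i \le t} \frac{1}{\max(S(i),\, s_{\min})},$$

so each game becomes an event on the $H$ axis and runs of high scores
become tight clusters of events. The event process is modelled as a
**Hawkes self-exciting point process** with intensity

$$\lambda(t) = \mu + \sum_{t_i < t} \varphi(t - t_i),$$

where $\mu$ is the intrinsic (background) performance rate and the
nonparametric histogram kernel $\varphi$ — estimated by an
expectation–maximisation algorithm over the latent branching structure —
carries the memory of past performances. The **branching ratio**
$n = \int_0^\infty \varphi$ is the headline statistic: the mean number of
events directly triggered per event, with $n$ near 1 meaning strong
self-excitation (a strong hot hand).

Evidence is always measured against **shuffle nulls** — permutations of
the same scores that destroy order while preserving the score multiset:

* out-of-sample log-likelihood of a chronological 80/20 split versus 100
  shuffled-training controls, with the relative difference
  $\delta = (L^{\mathrm{model}} - L^{\mathrm{control}})/L^{\mathrm{control}}$;
* the full-career branching ratio versus whole-career shuffles;
* calibrated placement p-values per career, plus exact binomial
  meta-probabilities at cohort level;
* winning-streak significance ($p(n)$ and $p(n_f)$ from 1000-shuffle null
  ensembles, five multiple-testing corrections);
* co-location of a career's three best performances versus shuffled
  nulls, with a permutation 2D Kolmogorov–Smirnov test.

A synthetic-data module generates careers and win/loss sequences with
known self-excitation and persistence, so every stage has a ground-truth
calibration and power surface.

## Worked example

```r
library(hothands)

# a synthetic career with genuine self-excitation (true branching 0.6)
hot    <- synthesize_career(150, "hot_hawkes", branching = 0.6, seed = 42)
career <- hot$scores[[1]]
head(career, 10)
#>  [1]  50  54  44  79  24  21  25 476 105  58

fit <- hawkes_em(to_performance_time(career))
fit
#> <hawkes_fit> 150 events on (0, 5.541]
#>   mu = 14.17, branching ratio n = 0.4873
#>   loglik = 349.6 after 65 iterations (converged)

res <- evaluate_career(career, player_id = "demo", n_controls = 100, seed = 1)
dplyr::select(res, delta, p_loglik, n_real, n_null_med, p_branching)
#> # A tibble: 1 × 5
#>     delta p_loglik n_real n_null_med p_branching
#>     <dbl>    <dbl>  <dbl>      <dbl>       <dbl>
#> 1 0.00837    0.337  0.487      0.329       0.0495
```

The fitted branching ratio (0.49) sits close to the simulated truth
(0.6 would be the career-ensemble value; a single 150-game career is
noisy). Against 100 whole-career shuffles the real branching ratio is
significantly high (`p_branching` just under 0.05) — the branching route
detects the planted hot hand — while this particular career's
out-of-sample predictive advantage (`delta` > 0 but `p_loglik` = 0.34) is
positive yet not individually significant: single careers carry limited
evidence, which is why conclusions are drawn at cohort level with
`evaluate_cohort()` + `cohort_summary()`.

Winning streaks work the same way:

```r
oc  <- synthesize_outcomes(120, p_win = 0.55, persistence = 0.25, seed = 7)
sig <- streak_significance(oc, n_shuffles = 1000, seed = 8)
dplyr::select(sig, length, freq, p_n, p_nf, label)
#> # A tibble: 5 × 5
#>   length  freq   p_n  p_nf label
#>    <int> <int> <dbl> <dbl> <chr>
#> 1      1     9 1     1     probable
#> 2      2     7 1     1     probable
#> 3      3     3 1     0.999 probable
#> 4      4     3 0.995 0.750 probable
#> 5      5     3 0.892 0.192 probable
```

Mild persistence (0.25) over 120 games is not enough to beat the shuffle
null after Holm correction — every streak is labelled `probable`.

`run_hothand_pipeline()` chains filtering (≥ 30 games), evaluation,
cohort summaries and team streak analysis, writing CSV/JSON artifacts
with the full configuration and seed embedded.

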