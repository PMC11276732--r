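---
title: "Methods: task model, error taxonomy, synthetic participants, and Bayesian inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task model, error taxonomy, synthetic participants, and Bayesian inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iwcst)
```

## The task model

The package simulates an internet-administered card-sorting task of the
Wisconsin family. A target card lives in a three-dimensional feature space
(COLOR, SHAPE, NUMBER), each dimension taking one of four features, encoded
as indices 1–4. Four fixed keycards sit under the response keys Y/C/B/M;
keycard $k$ carries index $k$ on every dimension, so a response is
classified by pure index equality: the chosen keycard matches the target on
dimension $d$ iff the target's index on $d$ equals the keycard position.
Only the 24 *unambiguous* cards — pairwise-distinct indices, hence a
different matching keycard per dimension — are used as targets; the fourth
keycard shares no feature and its selection is an *odd error*.

A covert rule cycles COLOR → SHAPE → NUMBER → COLOR…, advancing after six
consecutive correct sorts (a *category*). We start the cycle at COLOR, the
head of the published order; the starting rule is configurable and nothing
downstream depends on it. Feedback ("correct"/"incorrect") is the only
signal; rule switches are never announced. A session ends at 240 trials, or
earlier once the participant has encountered 20 potential non-repetitive
*and* 20 potential repetitive perseveration errors (see below). Termination
is checked after each completed trial. The 1200 ms feedback and 800 ms
inter-trial timings are recorded in the configuration but do not affect
simulation semantics.

### Target sequencing

Targets are drawn pseudo-randomly under two constraints: no exact repeat on
consecutive trials, and a 50/50 balance of repetitive versus non-repetitive
perseveration opportunities. On a trial following an *informative error* —
incorrect feedback on a response that matched some dimension $d$ — a fair
coin chooses whether the new target repeats the previous target's feature on
$d$ (repetitive stratum, 5 eligible cards) or changes it (non-repetitive
stratum, 18 cards), with a uniform draw inside the stratum. An explicit coin
is the only mechanism that guarantees the stated 50% marginal regardless of
the participant's behavior; how the original task engineered the balance is
not documented, so we adopted this construction. On all other trials the
draw is uniform over the 23 legal cards. We balance on the dimension
disconfirmed on the immediately preceding trial (the *critical* dimension);
correct feedback and odd responses clear it.

## Error taxonomy and measures

Each trial receives exactly one label; errors are labelled by precedence
OE > PE > IE > SLE > switch-signal > unclassified:

* **Perseveration error (PE)** — repeating the dimension disconfirmed on the
  immediately preceding trial. The *occasion* is repetitive or
  non-repetitive according to whether the critical feature repeats between
  the two trials; this is a property of the occasion, independent of the
  committed response. The *error suppression effect* for a participant is
  `ese = npe_pct - rpe_pct`, with per-occasion percentages; `ese_sum`
  normalizes by the sum and is defined only when at least one PE was
  committed.
* **Integration error (IE)** — after informative errors on two *distinct*
  dimensions on the two preceding trials, re-choosing the first-excluded
  dimension instead of the remaining third. Same-dimension error runs do not
  create IE occasions.
* **Set-loss error (SLE)** — an error following confirmed-correct feedback
  with the rule unchanged. The first trial after a covert switch is
  excluded: the old-rule response there is an unavoidable *switch-signal
  error*, not a set loss. Without this exclusion the SLE-occasion count
  would exceed its empirically observed share of trials.
* **Odd error (OE)** — the keycard sharing no feature. Odd feedback
  disconfirms no dimension and never creates or extends PE/IE chains.

Occasion denominators with zero counts yield *undefined* percentages,
represented as `NA` and propagated into cohort statistics by pairwise
deletion — never coerced to 0. Cohort exclusion follows three rules:
categories more than 3 SD below the cohort mean, odd errors more than 3 SD
above, or fewer than 8 occasions of either perseveration type.

Open points we resolved: an odd response committed on a PE occasion counts
the occasion but no committed PE; `categories_pct` is per-participant
`100 * n_categories / n_total_trials`; the final partial category is not
counted.

## Synthetic participants

The agent is a descriptive probabilistic policy — controllable error rates,
not a cognitive-process model. It tracks a candidate dimension and responds
by it; each scoring pathway has a generating probability:

| parameter | meaning | default |
|---|---|---|
| `p_pers_nonrep` | repeat the disconfirmed dimension, feature changed | 0.092 |
| `p_pers_rep` | repeat the disconfirmed dimension, feature repeated | 0.039 |
| `p_sle` | abandon a just-confirmed set | 0.051 |
| `p_ie` | faulty integration on an IE occasion | 0.149 |
| `p_oe` | odd response, any trial | 0.0045 |

Defaults are the cohort-level per-occasion rates reported for neurotypical
adults (the odd-error rate is the mean odd-error count divided by the mean
trial count). These defaults *are* the stated world of the generator and are
not tuned further. `p_pers_rep < p_pers_nonrep` yields a positive mean ESE
(the goal-directed-instrumental-control regime); the reverse ordering the
negative-ESE regime.

After a single informative error the agent switches set: to the remaining
third dimension when two consecutive distinct dimensions were disconfirmed
(choosing the first-excluded one instead with probability `p_ie`), to the
still-valid confirmed set when the error was its own lapse, and uniformly
between the two alternatives otherwise. The lapse-recovery rule is a
deliberate design choice: a uniform re-choice would make half of all
set-loss recoveries a second informative error on a distinct dimension,
inflating the integration-occasion count per session to ≈ 15 where ≈ 11 is
observed; reinstating the rewarded set matches behavior and keeps all
occasion-count means within ±20% of the observed values.

Randomness: one master seed per session; the sequencer and the agent consume
independent sub-streams (private Mersenne-Twister states) derived from it,
so adding draws to one never perturbs the other and cohorts are
reproducible agent by agent.

What a green simulation test does *not* establish: the generator emulates
per-occasion error rates and their occasion structure, not response times,
learning or fatigue trends within a session, individual differences beyond
Monte-Carlo variation in identical parameters, or any cognitive mechanism.

## Bayesian inference layer

For $n$ paired differences summarized by $t = (\bar d / s_d)\sqrt n$, the
likelihood of $t$ given the standardized effect $\delta$ is noncentral-$t$
with $\nu = n - 1$ and noncentrality $\delta\sqrt n$. The alternative places
a Cauchy prior $\delta \sim \mathrm{Cauchy}(0, r)$ with $r = 1/\sqrt 2$ by
default (wide 1, ultrawide $\sqrt 2$); the null fixes $\delta = 0$. All
Bayes factors are natural logs.

Numerical choices:

* The noncentral-$t$ **log density** is computed by quadrature over the
  scale variable $s = \sqrt{\chi^2_\nu/\nu}$, whose integrand has an
  analytic mode (root of a quadratic), in log space. `stats::dt(ncp=)`
  returns hard zeros with precision warnings in exactly the deep-tail
  regime needed for tail masses of order $10^{-40}$; the custom density
  agrees with `stats::dt` to ~$10^{-12}$ in the bulk and stays accurate far
  beyond. In tests, `stats::dt` powers the *independent* dense-grid oracle,
  where misreported far-tail zeros are negligible at the checked tolerance.
* The **posterior grid** is centered on $\hat\delta = t/\sqrt n$, widened
  until the end-point density falls below $10^{-12}$ of the peak, always
  covers 0, and uses ≥ 4001 nodes. The CDF uses midpoint accumulation (a
  left-Riemann CDF biases quantiles by half a grid step). Normalization is
  checked to $10^{-4}$ and holds to $10^{-6}$ in tests.
* **Order-constrained evaluation** of $\delta > 0$ versus $\delta < 0$ uses
  the encompassing-prior tail-mass ratio with equal prior model
  probabilities; tail masses are accumulated in log space, so extreme
  evidence reports a bound (e.g. pmp > 1 − 10⁻⁴⁰) rather than NaN.
  Order-constrained Bayes factors obtained with fractional-prior
  approximations are a different estimand and are deliberately not
  reproduced here.
* **Correlation Bayes factors** integrate the exact sampling density of
  Pearson's $r$ (Gauss hypergeometric via series, fast for the relevant
  arguments) against a symmetric stretched-beta prior, $\kappa = 1$
  (uniform) by default, matching the defaults of the statistics application
  used for the published analysis.

Printed summary statistics carry one-decimal rounding; propagated through
$t$, this induces roughly ±1–2% relative uncertainty on posterior
summaries and a few percent on log Bayes factors. Package results at the
rounded inputs (e.g. log BF ≈ 73.8 where 73.34 is printed from unrounded
data) agree with an independent implementation to $10^{-5}$, so the residual
gap is input rounding, not numerics.

## Worked example

```{r example, eval = FALSE}
# simulate a cohort under the default (positive-ESE) regime and score it
sessions <- simulate_cohort(agent_params(), 100, master_seed = 1)
measures <- score_cohort(sessions)
colMeans(measures[, c("npe_pct", "rpe_pct", "ese")], na.rm = TRUE)

# confirmatory inference from the scored ESE values
diffs <- measures$ese[is.finite(measures$ese)]
inference_report(diffs = diffs)

# or directly from published summary statistics
inference_report(5.3, 8.7, 489)
```

## Known limitations

* The agent's parameters are context-free constants; real participants
  drift, learn and fatigue.
* Cohort heterogeneity is not modelled (all agents share parameters), so
  between-participant variance of the measures is narrower than observed;
  rate *means* are matched, spreads are not.
* The original task's exact pseudo-random schedule is unpublished; only its
  stated constraints are reproduced.
* Session-log CSVs do not serialize the session configuration; readers
  attach one explicitly.
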