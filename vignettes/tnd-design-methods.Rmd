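---
title: "Designing test-negative vaccine-effectiveness studies: tests, sample sizes, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing test-negative vaccine-effectiveness studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnddesign)
```

## The design problem

A test-negative design (TND) study enrols patients who are tested for a
target pathogen as part of routine care: test-positives become cases,
test-negatives become controls, and vaccine effectiveness (VE) is
estimated as one minus the odds ratio of testing positive comparing
vaccinated with unvaccinated patients. Structurally the data look like a
case-control study, with one important difference: in a case-control study
the investigator fixes the case:control ratio; in a TND only the *total*
number of tests is under any control, and the split between positives and
negatives — the percent positivity — is a random outcome of the two
competing illness processes.

Two features make design calculations for such studies delicate:

* **Sparsity.** Effective vaccines empty the vaccinated-case cell. When VE
  is 95% and coverage 10%, the expected vaccinated fraction among cases is
  about 0.55%, and a correctly sized study of a couple of hundred tests
  sees *zero* vaccinated cases in roughly two thirds of realizations. Any
  procedure that needs all four cells filled breaks down exactly where
  vaccines succeed.
* **A random case:control split.** Even at a fixed total, the binomially
  varying number of positives adds variance that case-control formulas do
  not see, eroding power at high VE.

`tnddesign` provides the three standard one-sided tests of a VE margin on
the 2×2 table, their matched sample sizes, a TND-specific sample size
that integrates power over the random positivity, and a hazard-based
simulator for checking any of it by Monte Carlo.

## Parameters and derived quantities

All planning starts from `design_inputs()`:

| parameter  | meaning                                             | default |
|------------|-----------------------------------------------------|---------|
| `ve`       | assumed vaccine effectiveness, $1-\text{OR}$        | —       |
| `p_n`      | vaccinated fraction among test-negatives (coverage proxy) | — |
| `lambda_i` | hazard/day of test-positive illness (unprotected)   | 0.001   |
| `lambda_n` | hazard/day of test-negative illness (everyone)      | 0.002   |
| `tau`      | study duration, days                                | 100     |
| `alpha`    | one-sided significance level                        | 0.025   |
| `power`    | target power $1-\gamma$                             | 0.8     |
| `theta`    | null margin of $H_0\!: \mathrm{VE} \le \theta$      | 0       |

The default hazards describe a pathogen infecting 1–10% of the
health-care-seeking population over a ~100-day season while symptomatic
look-alike illnesses accrue at about twice that rate — a realistic
influenza-like setting. Two derived quantities drive everything:

* the vaccinated fraction among cases,
  $p_I = p_N(1-\mathrm{VE})\,/\,(1 - p_N\,\mathrm{VE})$
  (`case_vax_fraction()`), the exact inversion of the odds-ratio
  definition of VE; and
* the expected percent positivity
  $\pi = A/(A + \Lambda_N)$ with
  $A = (1-p_N\,\mathrm{VE})\,(1-e^{-\Lambda_I})$
  (`expected_positivity()`), where $\Lambda_I=\lambda_I\tau$ and
  $\Lambda_N=\lambda_N\tau$ are the cumulative hazards. $\pi$ plays the
  role of the case fraction $1/(k+1)$ of a case-control study with
  control:case ratio $k$. If surveillance data suggest a different
  positivity, every sample-size function accepts a user-supplied `pi`
  directly; no estimator from historical data is provided.

Both derivations are consistent with the per-person expected cell counts
(`unit_cell_counts()`), and `population_size()` converts a target test
count into the source-population size whose expected test count over
$\tau$ reaches it.

```{r}
d <- design_inputs(ve = 0.95, p_n = 0.1)
case_vax_fraction(0.1, 0.95)
expected_positivity(d)
population_size(228, d)
```

## The three tests

All are one-sided tests of $H_0\!:\mathrm{VE}\le\theta$ against
$H_1\!:\mathrm{VE}>\theta$; effectiveness above the margin pushes the log
odds ratio *below* $\ln(1-\theta)$, so rejection is in the lower tail,
statistic $< z_\alpha$.

* **Wald** (`wald_test()`):
  $T_W = [\ln(ad/bc) - \ln(1-\theta)]\,/\,\sqrt{1/a+1/b+1/c+1/d}$.
  Undefined with any zero cell.
* **Continuity-corrected Wald** (`cc_wald_test()`): the same after adding
  $\delta$ (default 0.5, Yates) to every cell. Always defined for
  $\delta>0$, but the correction shrinks the log odds ratio towards zero
  — a bias that grows with $\delta$ and is substantial exactly in the
  sparse settings that motivate the correction (see `cc_sweep()`).
* **Score** (`score_test()`): from the logistic regression of test result
  on vaccination, with variance pooled under the null. At $\theta=0$,
  $T_S = (ad-bc)\sqrt{n}\,/\,\sqrt{(a{+}c)(b{+}d)(a{+}b)(c{+}d)}$, whose
  square is the Pearson chi-square; it tolerates a single zero cell as
  long as all margins are positive.

`hybrid_wald_test()` encodes the common practice of falling back to the
corrected statistic only when the plain Wald is intractable; the
Monte-Carlo harness can alternatively count intractable replicates as
non-rejections (`policy = "nonrejection"`) for sensitivity analyses.

For $\theta > 0$ the score statistic has no closed form here; it is
computed by profiling the logistic intercept under the constraint
slope $= \ln(1-\theta)$ (a one-dimensional root solve of the intercept
score) and standardizing the slope score by the profiled expected
information. This is the standard constrained-score construction; at
$\theta = 0$ it reduces to the closed form, which is what all shipped
design calculations use.

## Sample sizes

With $(p_I, p_N, \pi)$ fixed, the package provides four totals:

* `wald_sample_size()` — the classical Fleiss-type two-proportion formula
  re-parameterized for the TND;
* `cc_wald_sample_size()` — its Yates-corrected inflation
  $n_C = (n_W/4)\{1+\sqrt{1+2/[\pi(1-\pi)n_W|p_I-p_N|]}\}^2$, computed
  from the *unrounded* $n_W$ to avoid double-rounding (the difference is
  at most one test either way);
* `score_sample_size()` —
  $n_S = (z_{1-\gamma}\sigma_1 + z_{1-\alpha}\sigma_0)^2/(p_I-p_N)^2$
  with the pooled null variance
  $\sigma_0^2 = [\pi p_I + (1-\pi)p_N][\pi(1-p_I)+(1-\pi)(1-p_N)]/[\pi(1-\pi)]$
  and the harmonic alternative variance
  $\sigma_1^2 = \frac{p_I(1-p_I)\,p_N(1-p_N)}
  {\pi p_I(1-p_I) + (1-\pi)p_N(1-p_N)}\cdot\frac{1}{\pi(1-\pi)}$;
* `tnd_score_sample_size()` — the TND-specific size described next.

All sizes round up. Every formula is invariant to relabelling the two
groups ($p_I \leftrightarrow p_N$ with $\pi \leftrightarrow 1-\pi$), and
on the planning grid VE ∈ {30,…,95%} × coverage ∈ {10,…,90%} the score
size never exceeds the Wald size.

### Accounting for the random positivity

In a TND the realized positivity $\hat\pi=(a+c)/n$ is binomial, not
fixed. `tnd_power()` computes the attainable power at total size $n$ as
the mixture

$$\sum_{k=0}^{n}
  \Phi\!\left(\frac{z_\alpha\,\sigma_0-(p_I-p_N)\sqrt{n}}
  {\tilde\sigma_1(k/n)}\right)\binom{n}{k}\pi^k(1-\pi)^{n-k},$$

holding $\sigma_0$ at its fixed-$\pi$ value (it is nearly constant in
$\hat\pi$) and using the multinomial-derived alternative SD
$\tilde\sigma_1^2(x) = p_I(1-p_I)/x + p_N(1-p_N)/(1-x) + 2p_Ip_N$. The
boundary terms $k\in\{0,n\}$ — tables with an empty column, where no test
exists — contribute zero rejection probability; their binomial weight is
below $10^{-9}$ in any practical design, so the convention is numerically
irrelevant. `tnd_score_sample_size()` grid-searches $n$ upward from the
case-control score size until this mixture reaches the target, with a
hard cap at 100× the starting size (an explicit error, never a silent
truncation). Because $\tilde\sigma_1 \ge$ the fixed-$\pi$ SD by convexity,
the proposed size is never below the score size, and the search is over a
monotone stretch of the power curve.

```{r}
sample_size(d, "score")$n      # case-control score size
sample_size(d, "tnd_score")$n  # TND-adjusted size
tnd_power(179, case_vax_fraction(0.1, 0.95), 0.1, expected_positivity(d))
```

## The simulator

`simulate_population()` generates the testing history of a source
population of `N = population_size(n, inputs)` health-care-seeking
individuals over an event horizon of `horizon_multiple * tau` (default
5×, so count-based stopping virtually never exhausts the horizon;
shortfalls set a `truncated` flag rather than failing silently):

* a fixed `round(N * p_n)` subset is vaccinated;
* protection is **all-or-none**: each vaccinee is fully protected
  independently with probability VE, the rest share the unvaccinated
  hazard. The independent-Bernoulli reading is the standard all-or-none
  model and is what makes the vaccinated-case count marginally binomial —
  the zero-cell frequency of a correctly sized high-VE study then matches
  the closed form $(1-p_I)^{m}$, which a fixed protected count (a
  hypergeometric mechanism) would visibly miss;
* unprotected individuals experience at most one test-positive illness
  (exponential time at rate $\lambda_I$; immunity afterwards), and
  everyone accrues test-negative illnesses as a Poisson process at rate
  $\lambda_N$, capped at 3 per person (under the defaults about 1.8% of
  individuals would otherwise record a second negative test by day
  $\tau$, so the cap is rarely binding). Individuals are not removed
  after a positive test;
* event times are continuous, so ties have probability zero; ordering is
  nevertheless made fully deterministic by sorting on (time, individual,
  positive-before-negative).

`sample_tnd()` takes the first $n$ tests in calendar order — both margins
random. `sample_cct()` fixes the split: the first `round(n * pi)`
positives in calendar order are the cases (ties at `.5` round half up;
extreme-coverage designs are sensitive to this rounding, which is why the
quota is exposed in the protocol object), and controls are a simple
random sample *of events* (a person contributing two negative tests can
enter twice, each event at most once) from all negatives on the horizon.
Diagnostic sensitivity and specificity are 100%.

The harness (`estimate_power()`, `zero_cell_rate()`, `cc_sweep()`,
`score_spread_by_positives()`) runs replicates from a single stream
seeded once per call, each replicate consuming the next block of draws,
so any (protocol, reps, seed) triple is exactly reproducible.

## What the simulator does and does not emulate

The generator reproduces the mechanism the design formulas assume:
constant hazards and coverage, vaccination completed before the study,
all-or-none protection, perfect tests, no confounding, and passive
enrolment of everyone who tests. Real TND data differ in known ways —
health-care-seeking behaviour correlated with vaccination, waning or
leaky protection, covariate adjustment, seasonally varying hazards,
imperfect assays. Passing the shipped checks therefore validates the
design arithmetic under its own assumptions, not robustness to those
violations.

## Numerical and scale choices

* Monte-Carlo work in the shipped tests and the acceptance script uses
  20,000 replicates per scenario (binomial SE ≈ 0.002 on a power of 0.9;
  the unit tests use 3,000–5,000 for structural checks), with fixed
  seeds. Power and frequency comparisons carry tolerances matched to
  that precision.
* The discrete tests are slightly conservative at realistic design sizes:
  the exact one-sided size at the nominal 0.025 is about 0.019–0.022.
  Type-I checks therefore verify *control* (not exceeding the nominal
  level, and not collapsing far below it) rather than exact attainment.
* The continuity-correction sweep's default illustration pairs the
  corrected test with its own sample size ($n_C = 92$ at VE 95%,
  coverage 30%), where Yates' $\delta = 0.5$ biases the log odds ratio by
  ≈ +0.5; at the score size (63) the same correction biases by ≈ +0.73 —
  the bias grows as studies shrink, which is the argument against
  rescuing the Wald test with corrections rather than switching to the
  score test.
* `tnd_score_sample_size()` evaluates `tnd_power()` exactly (full
  binomial sum); no normal approximation to the mixture weight is used.

## Known limitations

* The $\theta>0$ score construction is a documented extension point; all
  validated numbers use $\theta=0$.
* Quota rounding (`round(n * pi)`) makes case-control zero-cell
  frequencies at extreme coverage sensitive to one case more or less;
  treat those cells as ±a few percent.
* The sample-size formulas assume a single binary exposure; adjusting
  for confounders requires the regression machinery the formulas
  deliberately avoid.
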