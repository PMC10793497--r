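# tnddesign

Design and analysis tools for **test-negative design (TND)** and
case-control vaccine-effectiveness studies, aimed at biostatisticians and
epidemiologists planning observational VE evaluations (influenza,
COVID-19, rotavirus, …).

In a TND, patients tested for the target pathogen during routine care are
enrolled; test-positives are cases, test-negatives are controls, and
vaccine effectiveness is estimated as VE = 1 − OR, the odds ratio of
testing positive comparing vaccinated with unvaccinated patients. Unlike
a case-control study, the case:control ratio is not fixed by the
investigator — the percent positivity π is random. Highly effective
vaccines additionally empty the vaccinated-case cell `a` of the 2×2
table, which breaks Wald-type inference. This package implements:

* **Tests** of `H0: VE ≤ θ` vs `H1: VE > θ` (one-sided, lower-tail):
  the Wald statistic
  `T_W = [ln(ad/bc) − ln(1−θ)] / √(1/a + 1/b + 1/c + 1/d)`,
  its continuity-corrected version (a constant δ added to each cell), and
  the logistic **score** statistic, which at θ = 0 is
  `T_S = (ad − bc)√n / √((a+c)(b+d)(a+b)(c+d))`
  — the signed square root of the Pearson chi-square — and stays defined
  with a zero cell as long as all margins are positive.
* **Sample sizes** matched to each test: the Fleiss-type Wald size `n_W`,
  its Yates-corrected inflation `n_C`, the case-control score size
  `n_S = (z_{1−γ}σ₁ + z_{1−α}σ₀)² / (p_I − p_N)²`, and a **TND-specific
  score size** `n_p`: the smallest `n ≥ n_S` whose power, averaged over
  the binomially random positivity
  (`Σ_k Φ([z_α σ₀ − (p_I−p_N)√n]/σ̃₁(k/n)) · Bin(k; n, π)`),
  reaches the target.
* A **hazard-based simulator** of the source population (all-or-none
  vaccine, exponential positive-illness times, Poisson negative-test
  process, calendar-time enrolment) and a **Monte-Carlo harness** for
  power, type-I error, zero-cell frequency, continuity-correction bias
  sweeps and score-statistic spread diagnostics.

See `vignettes/tnd-design-methods.Rmd` for the model, assumptions and
numerical choices.

## Worked example

Plan a study expecting 95% VE at 10% vaccination coverage, with
test-positive hazard 0.001/day, test-negative hazard 0.002/day, a 100-day
season, one-sided α = 0.025 and 80% power:

```r
library(tnddesign)
d <- design_inputs(ve = 0.95, p_n = 0.1)

sample_size(d, "wald")
#> wald sample size: n = 228 total tests
#>   p_I = 0.00552, p_N = 0.10000, positivity pi = 0.30100
sample_size(d, "score")
#> score sample size: n = 179 total tests
sample_size(d, "tnd_score")
#> tnd_score sample size: n = 228 total tests
```

Only about 0.55% of cases are expected to be vaccinated (`p_I`), and about
30% of tests to be positive. The score test needs 179 tests if the
case:control split were fixed, but the TND's random split costs power at
high VE: the binomial-mixture calculation raises the recommendation to
228 tests.

Analyse a realized table (1 vaccinated case, 19 vaccinated controls, 61
unvaccinated cases, 147 unvaccinated controls):

```r
score_test(contingency_table(1, 19, 61, 147))
#> score test of H0: VE <= 0 (one-sided alpha = 0.025)
#>   statistic = -2.33535, p = 0.0097627, reject H0
```

Check the design by simulation (the same machinery behind the shipped
acceptance numbers, here at 2,000 replicates):

```r
p <- sim_protocol("tnd", 228, d)
estimate_power(p, "score", reps = 2000, seed = 42)
#> TND, score test, n = 228, 2000 replicates
#>   rejection rate 0.8810 (MC SE 0.0072) at one-sided alpha 0.025
#>   zero vaccinated-case rate 0.6755; intractable rate 0.0000
```

Two thirds of correctly sized replicates contain **zero** vaccinated
cases — the plain Wald test is unusable there, while the score test keeps
its power. A thin command-line front end over the same functions ships in
`inst/cli/tnddesign.R` (subcommands `test`, `samplesize`, `simulate`,
`power`, `zero-rate`, `cc-sweep`, `score-spread`).

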