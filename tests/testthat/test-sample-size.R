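test_that("Wald sample size reproduces the standard-scenario values", {
  expected <- c(228, 74, 45, 37, 54)
  for (i in seq_along(pn_grid)) {
    s <- std_derived(0.95, pn_grid[i])
    expect_identical(wald_sample_size(s$p_i, pn_grid[i], s$pi)$n, as.integer(expected[i]))
  }
  # unrounded value just below the ceiling for the 30% coverage case
  s <- std_derived(0.95, 0.3)
  expect_equal(wald_sample_size(s$p_i, 0.3, s$pi)$unrounded_n, 73.951016,
               tolerance = 1e-6)
  expect_error(wald_sample_size(0.3, 0.3, 0.5), "infinite")
})

test_that("continuity-corrected Wald size inflates by the expected factor", {
  s <- std_derived(0.95, 0.3)
  r <- cc_wald_sample_size(s$p_i, 0.3, s$pi)
  expect_identical(r$n, 92L)               # 91.899 rounded up
  expect_equal(r$unrounded_n, 91.898892, tolerance = 1e-6)
  # inflation between 20% and 50% across the 95%-effectiveness scenarios
  for (pn in pn_grid) {
    si <- std_derived(0.95, pn)
    nw <- wald_sample_size(si$p_i, pn, si$pi)$unrounded_n
    nc <- cc_wald_sample_size(si$p_i, pn, si$pi)$unrounded_n
    expect_gt(nc / nw, 1.2)
    expect_lt(nc / nw, 1.5)
  }
  # the correction vanishes as the Wald size grows (small effect)
  nw <- wald_sample_size(0.48, 0.5, 0.5)$unrounded_n
  nc <- cc_wald_sample_size(0.48, 0.5, 0.5)$unrounded_n
  expect_lt(nc / nw, 1.03)
})

test_that("score sample size matches its formula on the scenario grid", {
  # frozen values from the closed form at the standard hazards
  cases <- list(
    list(ve = 0.95, pn = 0.1, n = 179L), list(ve = 0.95, pn = 0.3, n = 63L),
    list(ve = 0.95, pn = 0.5, n = 42L),  list(ve = 0.95, pn = 0.7, n = 36L),
    list(ve = 0.95, pn = 0.9, n = 53L),  list(ve = 0.90, pn = 0.1, n = 225L),
    list(ve = 0.90, pn = 0.3, n = 81L),  list(ve = 0.90, pn = 0.5, n = 55L),
    list(ve = 0.90, pn = 0.7, n = 50L),  list(ve = 0.90, pn = 0.9, n = 82L))
  for (cs in cases) {
    s <- std_derived(cs$ve, cs$pn)
    expect_identical(score_sample_size(s$p_i, cs$pn, s$pi)$n, cs$n)
  }
  # independent re-derivation of the two SD terms for one cell
  s <- std_derived(0.95, 0.3)
  r <- score_sample_size(s$p_i, 0.3, s$pi)
  pi <- s$pi; p_i <- s$p_i
  s0 <- sqrt((pi * p_i + (1 - pi) * 0.3) * (pi * (1 - p_i) + (1 - pi) * 0.7) /
               (pi * (1 - pi)))
  s1 <- sqrt(p_i * (1 - p_i) * 0.3 * 0.7 /
               ((pi * p_i * (1 - p_i) + (1 - pi) * 0.3 * 0.7) * pi * (1 - pi)))
  expect_equal(r$sigma0, s0, tolerance = 1e-12)
  expect_equal(r$sigma1, s1, tolerance = 1e-12)
  expect_equal(r$unrounded_n,
               (qnorm(0.8) * s1 + qnorm(0.975) * s0)^2 / (p_i - 0.3)^2,
               tolerance = 1e-12)
})

test_that("sample sizes are ordered and symmetric across the design grid", {
  for (ve in ve_grid) for (pn in pn_grid) {
    s <- std_derived(ve, pn)
    ns <- score_sample_size(s$p_i, pn, s$pi)
    nw <- wald_sample_size(s$p_i, pn, s$pi)
    np <- tnd_score_sample_size(s$p_i, pn, s$pi)
    expect_lte(ns$n, nw$n)
    expect_gte(np$n, ns$n)
    # relabelling the groups with pi <-> 1 - pi leaves each size unchanged
    expect_identical(wald_sample_size(pn, s$p_i, 1 - s$pi)$n, nw$n)
    expect_identical(score_sample_size(pn, s$p_i, 1 - s$pi)$n, ns$n)
  }
})

test_that("TND binomial-mixture power behaves like a power function", {
  s <- std_derived(0.95, 0.1)
  # bracketing that pins the proposed size at the standard scenario
  expect_gte(tnd_power(228, s$p_i, 0.1, s$pi), 0.8)
  expect_lt(tnd_power(227, s$p_i, 0.1, s$pi), 0.8)
  # below target at the case-control score size when effectiveness is high
  ns <- score_sample_size(s$p_i, 0.1, s$pi)$n
  expect_lt(tnd_power(ns, s$p_i, 0.1, s$pi), 0.8)
  # monotone in n from the score size past the proposed size
  for (ve in c(0.90, 0.95)) for (pn in c(0.1, 0.5, 0.9)) {
    si <- std_derived(ve, pn)
    n0 <- score_sample_size(si$p_i, pn, si$pi)$n
    n1 <- tnd_score_sample_size(si$p_i, pn, si$pi)$n + 50
    pw <- vapply(n0:n1, tnd_power, numeric(1), p_i = si$p_i, p_n = pn, pi = si$pi)
    expect_true(all(diff(pw) > 0))
    expect_true(all(pw >= 0 & pw <= 1))
  }
  # boundary terms carry negligible binomial mass in these designs
  expect_lt(dbinom(0, 228, s$pi) + dbinom(228, 228, s$pi), 1e-9)
  # converges to the fixed-positivity normal-approximation power for large n
  big_n <- 5000
  sg <- tnddesign:::score_sd_terms(s$p_i, 0.1, s$pi)
  s1_fixed <- sqrt(s$p_i * (1 - s$p_i) / s$pi + 0.1 * 0.9 / (1 - s$pi) +
                     2 * s$p_i * 0.1)
  fixed_pow <- pnorm((qnorm(0.025) * sg[["sigma0"]] -
                        (s$p_i - 0.1) * sqrt(big_n)) / s1_fixed)
  expect_equal(tnd_power(big_n, s$p_i, 0.1, s$pi), fixed_pow, tolerance = 1e-4)
})

test_that("proposed TND score size reproduces the high-effectiveness grid", {
  expected <- list("0.95" = c(228, 75, 46, 39, 62),
                   "0.9"  = c(268, 91, 60, 54, 95))
  for (ve_chr in names(expected)) {
    ve <- as.numeric(ve_chr)
    for (i in seq_along(pn_grid)) {
      s <- std_derived(ve, pn_grid[i])
      r <- tnd_score_sample_size(s$p_i, pn_grid[i], s$pi)
      expect_identical(r$n, as.integer(expected[[ve_chr]][i]))
      expect_identical(r$method, "tnd_score")
    }
  }
})

test_that("the sample_size wrapper derives inputs from the design object", {
  d <- std_design(0.95, 0.1)
  expect_identical(sample_size(d, "wald")$n, 228L)
  expect_identical(sample_size(d, "score")$n, 179L)
  expect_identical(sample_size(d, "tnd_score")$n, 228L)
  # overrides bypass the hazard-based derivation
  expect_identical(sample_size(d, "score", pi = 0.5, p_i = 0.2)$n,
                   score_sample_size(0.2, 0.1, 0.5)$n)
})
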