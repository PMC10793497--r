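test_that("protocol construction sizes the population and quotas correctly", {
  d <- std_design(0.95, 0.1)
  p <- sim_protocol("tnd", 228, d)
  expect_identical(p$N, 797L)
  expect_equal(p$pi, expected_positivity(d))
  pc <- sim_protocol("cct", 228, d)
  expect_identical(pc$case_quota, 69L)    # round(228 * 0.301)
  expect_error(sim_protocol("cct", 2, design_inputs(0.5, 0.3, lambda_n = 0)),
               "quota")
  expect_error(sim_protocol("tnd", 0, d), "positive integer")
})

test_that("population histories respect the structural vaccine model", {
  d <- std_design(0.95, 0.1)
  p <- sim_protocol("tnd", 228, d)
  set.seed(1)
  ev <- simulate_population(p)
  # protection only occurs inside the vaccinated block of round(N * p_n)
  expect_length(ev$protected_individual, 797L)
  expect_true(all(which(ev$protected_individual) <= round(797 * 0.1)))
  # event-level vaccination flags agree with the individual assignment
  expect_identical(ev$vaccinated, ev$id <= round(797 * 0.1))
  # events arrive in non-decreasing calendar time
  expect_true(all(diff(ev$time) >= 0))
  # protected individuals never test positive
  pos_ids <- ev$id[ev$positive]
  expect_false(any(ev$protected_individual[pos_ids]))
  # at most one positive test per person, at most 3 negative tests
  expect_lte(max(table(pos_ids)), 1)
  neg_ids <- ev$id[!ev$positive]
  expect_lte(max(table(neg_ids)), 3)
  # a perfect vaccine yields no vaccinated positives
  pperf <- sim_protocol("tnd", 50, design_inputs(1, 0.5))
  set.seed(2)
  evp <- simulate_population(pperf)
  expect_identical(sum(evp$positive & evp$vaccinated), 0L)
  # no negative-test hazard: every event is positive
  pno <- sim_protocol("tnd", 20, design_inputs(0.5, 0.3, lambda_n = 0))
  set.seed(3)
  evn <- simulate_population(pno)
  expect_true(all(evn$positive))
  out <- sample_tnd(evn, 20)
  expect_identical(out$table$b + out$table$d, 0L)
})

test_that("event counts match their closed-form means", {
  d <- std_design(0.95, 0.1)
  p <- sim_protocol("tnd", 228, d)
  set.seed(42)
  reps <- 200
  pos_by_tau <- mult_neg <- numeric(reps)
  for (r in seq_len(reps)) {
    ev <- simulate_population(p)
    unvax_pos <- ev$positive & !ev$vaccinated & ev$time <= d$tau
    pos_by_tau[r] <- sum(unvax_pos)
    neg_by_tau <- ev$id[!ev$positive & ev$time <= d$tau]
    mult_neg[r] <- sum(table(neg_by_tau) >= 2)
  }
  # unvaccinated positives by day tau: Binomial(N(1-p_n), 1 - exp(-Lambda_i))
  n_unvax <- 797 - round(797 * 0.1)
  attack <- 1 - exp(-0.1)
  expect_lt(abs(sum(pos_by_tau) - reps * n_unvax * attack),
            3 * sqrt(reps * n_unvax * attack * (1 - attack)))
  # individuals with 2+ negative tests by day tau: Poisson(0.2) upper tail
  p2 <- 1 - ppois(1, 0.2)
  expect_lt(abs(sum(mult_neg) - reps * 797 * p2),
            3 * sqrt(reps * 797 * p2 * (1 - p2)))
  expect_lt(mean(mult_neg) / 797, 0.025)  # rare, but ~1.75%, not <1%
})

test_that("TND sampling fixes the total and only the total", {
  d <- std_design(0.95, 0.3)
  p <- sim_protocol("tnd", 74, d)
  set.seed(5)
  pos <- replicate(400, {
    out <- sample_tnd(simulate_population(p), 74)
    expect_identical(out$table$n, 74L)
    expect_false(out$truncated)
    out$realized_positivity
  })
  # case counts vary across replicates but average to the planned positivity
  expect_gt(var(pos), 0)
  expect_lt(abs(mean(pos) - p$pi), 3 * sqrt(p$pi * (1 - p$pi) / (74 * 400)))
  # asking for more tests than the horizon holds flags truncation
  set.seed(6)
  ev <- simulate_population(p)
  big <- sample_tnd(ev, length(ev$time) + 10)
  expect_true(big$truncated)
})

test_that("case-control sampling fixes both margins at their quotas", {
  d <- std_design(0.95, 0.3)
  p <- sim_protocol("cct", 74, d)
  set.seed(7)
  a_vals <- replicate(400, {
    out <- sample_cct(simulate_population(p), 74, p$pi)
    expect_identical(out$table$n_tp, p$case_quota)
    expect_identical(out$table$n_tn, 74L - p$case_quota)
    out$table$a
  })
  # vaccinated cases approximate Binomial(quota, p_i)
  p_i <- case_vax_fraction(0.3, 0.95)
  m <- p$case_quota
  expect_lt(abs(mean(a_vals) - m * p_i),
            3 * sqrt(m * p_i * (1 - p_i) / 400))
})

test_that("null calibration: cases mirror coverage when the vaccine is inert", {
  d <- std_design(0, 0.3)
  for (des in c("tnd", "cct")) {
    p <- sim_protocol(des, 100, d)
    set.seed(11)
    frac <- replicate(300, {
      out <- simulate_study(p)
      out$table$a / max(out$table$n_tp, 1)
    })
    expect_lt(abs(mean(frac) - 0.3), 0.02)
  }
})

test_that("identical seeds reproduce identical replicates", {
  p <- sim_protocol("tnd", 100, std_design(0.7, 0.5))
  o1 <- simulate_study(p, seed = 123)
  o2 <- simulate_study(p, seed = 123)
  expect_identical(unclass(o1$table)[c("a", "b", "c", "d")],
                   unclass(o2$table)[c("a", "b", "c", "d")])
  expect_identical(o1$study_end_time, o2$study_end_time)
})
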