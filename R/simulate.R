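#' Simulation protocol for a TND or case-control study
#'
#' Fixes everything needed to generate one study replicate from the
#' hazard-based source-population model: the sampling design, the target
#' number of tests, and the design parameters. The source population size
#' is chosen via [population_size()] so that the expected number of tests
#' over the study period `tau` equals the target, keeping the simulated
#' study duration near `tau`.
#'
#' @param design `"tnd"` (first `n` tests in calendar order) or `"cct"`
#'   (fixed case quota `round(n * pi)` plus randomly sampled controls).
#' @param n Target total number of tests.
#' @param inputs A [design_inputs()] object.
#' @param max_negative_tests Cap on negative tests per individual.
#'   Default `3`.
#' @param horizon_multiple Events are generated on
#'   `[0, horizon_multiple * tau]` so that count-based stopping rarely runs
#'   out of events; shortfalls are flagged, never silent. Default `5`.
#' @return A `"sim_protocol"` object.
#' @examples
#' sim_protocol("tnd", 228, design_inputs(ve = 0.95, p_n = 0.1))
#' @export
sim_protocol <- function(design = c("tnd", "cct"), n, inputs,
                         max_negative_tests = 3, horizon_multiple = 5) {
  design <- match.arg(design)
  stopifnot(inherits(inputs, "tnd_design"))
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  pi <- expected_positivity(inputs)
  m <- round(n * pi)
  if (design == "cct" && (m < 1 || n - m < 1))
    stop("case-control quotas round(n*pi) and n - round(n*pi) must both be >= 1",
         call. = FALSE)
  structure(
    list(design = design, n = as.integer(n), inputs = inputs, pi = pi,
         case_quota = as.integer(m),
         N = population_size(n, inputs),
         max_negative_tests = max_negative_tests,
         horizon = horizon_multiple * inputs$tau),
    class = "sim_protocol"
  )
}

#' @export
print.sim_protocol <- function(x, ...) {
  cat(sprintf("%s protocol: n = %d tests from a source population of N = %d\n",
              toupper(x$design), x$n, x$N))
  if (x$design == "cct")
    cat(sprintf("  case quota %d, control quota %d\n",
                x$case_quota, x$n - x$case_quota))
  cat(sprintf("  expected positivity pi = %.4f; event horizon %g days\n",
              x$pi, x$horizon))
  invisible(x)
}

#' Simulate the event history of one source population
#'
#' Generates the full testing history of `N` health-care-seeking
#' individuals over the event horizon. A fixed `round(N * p_n)` subset is
#' vaccinated; under the all-or-none model each vaccinee is fully
#' protected independently with probability `ve`, the rest share the
#' unvaccinated hazard. Unprotected individuals experience at most one
#' test-positive illness, with an exponential event time at rate
#' `lambda_i` (immunity after infection). Test-negative illnesses arise as
#' a homogeneous Poisson process at rate `lambda_n` in everyone; only the
#' first `max_negative_tests` per person are kept. Individuals stay in the
#' at-risk population after a positive test.
#'
#' Draws come from the current R random-number stream: seed with
#' `set.seed()` before calling for reproducibility.
#'
#' @param protocol A [sim_protocol()] object.
#' @return A `"tnd_events"` list with parallel vectors `time` (days,
#'   sorted), `id` (individual index), `positive` and `vaccinated`
#'   (logical), plus the protection indicator `protected_individual` of
#'   length `N`.
#' @export
simulate_population <- function(protocol) {
  stopifnot(inherits(protocol, "sim_protocol"))
  inp <- protocol$inputs
  N <- protocol$N
  H <- protocol$horizon
  n_vax <- round(N * inp$p_n)
  vaccinated <- c(rep(TRUE, n_vax), rep(FALSE, N - n_vax))
  protected <- c(stats::runif(n_vax) < inp$ve, rep(FALSE, N - n_vax))

  # one positive event per unprotected individual, kept if on the horizon
  at_risk <- which(!protected)
  t_pos <- stats::rexp(length(at_risk), inp$lambda_i)
  keep <- t_pos <= H
  pos_id <- at_risk[keep]
  pos_time <- t_pos[keep]

  # negative events: Poisson counts, uniform order statistics, first k kept
  counts <- stats::rpois(N, inp$lambda_n * H)
  neg_id <- rep.int(seq_len(N), counts)
  neg_time <- stats::runif(length(neg_id), 0, H)
  o <- order(neg_id, neg_time)
  neg_id <- neg_id[o]
  neg_time <- neg_time[o]
  within_rank <- sequence(counts[counts > 0])
  sel <- within_rank <= protocol$max_negative_tests
  neg_id <- neg_id[sel]
  neg_time <- neg_time[sel]

  time <- c(pos_time, neg_time)
  id <- c(pos_id, neg_id)
  positive <- rep(c(TRUE, FALSE), c(length(pos_time), length(neg_time)))
  # ties have probability zero with continuous times; the (time, id,
  # positive-first) order below fixes a deterministic ordering regardless
  o <- order(time, id, !positive)
  structure(
    list(time = time[o], id = id[o], positive = positive[o],
         vaccinated = vaccinated[id[o]],
         protected_individual = protected, N = N),
    class = "tnd_events"
  )
}

new_sim_outcome <- function(a, b, c, d, design, end_time, truncated) {
  tab <- contingency_table(a, b, c, d)
  structure(
    list(table = tab, design = design,
         realized_positivity = if (tab$n > 0) tab$n_tp / tab$n else NA_real_,
         study_end_time = end_time, truncated = truncated),
    class = "sim_outcome"
  )
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("%s replicate (%s)\n", toupper(x$design),
              if (x$truncated) "TRUNCATED: event horizon exhausted" else
                sprintf("study end at day %.1f", x$study_end_time)))
  print(x$table)
  invisible(x)
}

#' Tabulate a TND replicate from an event history
#'
#' Takes the first `n` tests in calendar-time order, positives and
#' negatives interleaved — only the total test count is fixed, so the
#' case:control split is random — and cross-tabulates vaccination by test
#' result.
#'
#' @param events A [simulate_population()] result.
#' @param n Total number of tests to enrol.
#' @return A `"sim_outcome"` with the 2x2 table, the realized positivity,
#'   the study end time, and a `truncated` flag when fewer than `n` events
#'   existed on the horizon.
#' @export
sample_tnd <- function(events, n) {
  stopifnot(inherits(events, "tnd_events"))
  total <- length(events$time)
  truncated <- total < n
  take <- seq_len(min(n, total))
  pos <- events$positive[take]
  vax <- events$vaccinated[take]
  new_sim_outcome(sum(pos & vax), sum(!pos & vax),
                  sum(pos & !vax), sum(!pos & !vax),
                  "tnd",
                  if (length(take)) events$time[max(take)] else NA_real_,
                  truncated)
}

#' Tabulate a case-control replicate from an event history
#'
#' Enrols the first `round(n * pi)` positive tests in calendar-time order
#' as cases, and a simple random sample (without replacement, at the event
#' level) of `n - round(n * pi)` negative tests as controls, fixing the
#' case:control ratio by design.
#'
#' Control sampling uses the current R random-number stream.
#'
#' @inheritParams sample_tnd
#' @param pi Case fraction fixed by design (usually the
#'   [expected_positivity()] of the planning inputs).
#' @return A `"sim_outcome"`; `truncated` is set when either quota cannot
#'   be filled from the horizon.
#' @export
sample_cct <- function(events, n, pi) {
  stopifnot(inherits(events, "tnd_events"))
  m <- round(n * pi)
  if (m < 1 || n - m < 1)
    stop("quotas round(n*pi) and n - round(n*pi) must both be >= 1", call. = FALSE)
  pos_idx <- which(events$positive)
  neg_idx <- which(!events$positive)
  truncated <- length(pos_idx) < m || length(neg_idx) < n - m
  cases <- pos_idx[seq_len(min(m, length(pos_idx)))]
  n_ctrl <- min(n - m, length(neg_idx))
  controls <- neg_idx[sample.int(length(neg_idx), n_ctrl)]
  a <- sum(events$vaccinated[cases])
  b <- sum(events$vaccinated[controls])
  end_time <- if (length(cases)) events$time[max(cases)] else NA_real_
  new_sim_outcome(a, b, length(cases) - a, n_ctrl - b, "cct",
                  end_time, truncated)
}

#' Simulate one study replicate
#'
#' Convenience wrapper: generates a population event history and applies
#' the protocol's sampling rule.
#'
#' @param protocol A [sim_protocol()] object.
#' @param seed Optional integer seed applied with `set.seed()` first.
#' @return A `"sim_outcome"`.
#' @examples
#' p <- sim_protocol("tnd", 100, design_inputs(ve = 0.5, p_n = 0.3))
#' simulate_study(p, seed = 1)
#' @export
simulate_study <- function(protocol, seed = NULL) {
  stopifnot(inherits(protocol, "sim_protocol"))
  if (!is.null(seed)) set.seed(seed)
  events <- simulate_population(protocol)
  if (protocol$design == "tnd") sample_tnd(events, protocol$n)
  else sample_cct(events, protocol$n, protocol$pi)
}
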