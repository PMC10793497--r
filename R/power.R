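# Run `reps` independent study replicates and return the four cell counts
# plus bookkeeping columns. A single set.seed(seed) initializes the stream;
# replicate r consumes the next contiguous block of draws, so a given
# (protocol, reps, seed) triple is fully deterministic.
replicate_tables <- function(protocol, reps, seed) {
  stopifnot(inherits(protocol, "sim_protocol"), reps >= 1)
  set.seed(seed)
  out <- matrix(0L, nrow = reps, ncol = 5,
                dimnames = list(NULL, c("a", "b", "c", "d", "truncated")))
  for (r in seq_len(reps)) {
    events <- simulate_population(protocol)
    res <- if (protocol$design == "tnd") sample_tnd(events, protocol$n)
           else sample_cct(events, protocol$n, protocol$pi)
    out[r, ] <- c(res$table$a, res$table$b, res$table$c, res$table$d,
                  as.integer(res$truncated))
  }
  out
}

# Vectorized one-sided test decisions over a matrix of tables.
# Returns list(reject, tractable, statistic).
apply_test_vec <- function(tab, test, theta, delta, alpha, policy) {
  a <- tab[, "a"]; b <- tab[, "b"]; cc <- tab[, "c"]; d <- tab[, "d"]
  n <- a + b + cc + d
  z_crit <- stats::qnorm(alpha)
  shift <- log(1 - theta)
  cc_stat <- function(dl) {
    (log((a + dl) * (d + dl) / ((b + dl) * (cc + dl))) - shift) /
      sqrt(1 / (a + dl) + 1 / (b + dl) + 1 / (cc + dl) + 1 / (d + dl))
  }
  if (test == "score") {
    tractable <- pmin(a + cc, b + d, a + b, cc + d) > 0
    stat <- rep(NA_real_, length(a))
    if (theta == 0) {
      i <- which(tractable)
      stat[i] <- (a[i] * d[i] - b[i] * cc[i]) * sqrt(n[i]) /
        sqrt((a[i] + cc[i]) * (b[i] + d[i]) * (a[i] + b[i]) * (cc[i] + d[i]))
    } else {
      for (i in which(tractable))
        stat[i] <- constrained_score_stat(
          contingency_table(a[i], b[i], cc[i], d[i]), theta)
    }
  } else if (test == "cc_wald") {
    tractable <- rep(delta > 0, length(a)) | pmin(a, b, cc, d) > 0
    stat <- ifelse(tractable, cc_stat(delta), NA_real_)
  } else { # "wald" and "hybrid": zero cells handled by the policy
    whole <- pmin(a, b, cc, d) > 0
    stat <- rep(NA_real_, length(a))
    stat[whole] <- cc_stat(0)[whole]
    if (test == "hybrid" || policy == "substitute") {
      stat[!whole] <- cc_stat(delta)[!whole]
      tractable <- rep(TRUE, length(a))
    } else {           # count-as-nonrejection
      tractable <- whole
    }
  }
  tractable <- tractable & n > 0
  list(reject = tractable & is.finite(stat) & stat < z_crit,
       tractable = tractable, statistic = stat)
}

#' Monte-Carlo power of a test under a simulation protocol
#'
#' Simulates `reps` independent study replicates and reports the rejection
#' rate of the chosen one-sided test, together with the zero-cell rate
#' (replicates with no vaccinated test-positives), the intractability
#' rate, and bias/spread diagnostics for the log odds ratio.
#'
#' @param protocol A [sim_protocol()] object.
#' @param test `"score"`, `"wald"`, `"cc_wald"` or `"hybrid"` (Wald with
#'   continuity-corrected fallback on zero cells).
#' @param reps Number of replicates.
#' @param seed Integer seed; replicates consume consecutive blocks of a
#'   single stream seeded once.
#' @param theta Null margin. Default `0`.
#' @param delta Continuity correction where applicable. Default `0.5`.
#' @param alpha One-sided level; defaults to the protocol's design inputs.
#' @param policy How an intractable plain Wald statistic enters the power
#'   accounting: `"substitute"` the corrected statistic (default) or
#'   `"nonrejection"` (count as a failure to reject).
#' @return A `"power_summary"` list: `rejection_rate`, `mc_se` (binomial
#'   standard error), `zero_vax_case_rate`, `intractable_rate`,
#'   `truncated_rate`, `mean_logOR_bias` and `logOR_SE` (uncorrected log
#'   odds ratio over replicates with all cells positive, bias relative to
#'   `log(1 - ve)`), `replicates`, and a `config` echo.
#' @examples
#' p <- sim_protocol("cct", 74, design_inputs(ve = 0.95, p_n = 0.3))
#' estimate_power(p, "score", reps = 200, seed = 1)
#' @export
estimate_power <- function(protocol, test = c("score", "wald", "cc_wald", "hybrid"),
                           reps, seed, theta = 0, delta = 0.5, alpha = NULL,
                           policy = c("substitute", "nonrejection")) {
  test <- match.arg(test)
  policy <- match.arg(policy)
  if (is.null(alpha)) alpha <- protocol$inputs$alpha
  tab <- replicate_tables(protocol, reps, seed)
  dec <- apply_test_vec(tab, test, theta, delta, alpha, policy)
  rate <- mean(dec$reject)
  whole <- tab[, "a"] > 0 & tab[, "b"] > 0 & tab[, "c"] > 0 & tab[, "d"] > 0
  lor <- log(tab[whole, "a"] * tab[whole, "d"] /
               (tab[whole, "b"] * tab[whole, "c"]))
  structure(
    list(rejection_rate = rate,
         mc_se = sqrt(rate * (1 - rate) / reps),
         zero_vax_case_rate = mean(tab[, "a"] == 0),
         intractable_rate = mean(!dec$tractable),
         truncated_rate = mean(tab[, "truncated"] == 1),
         mean_logOR_bias = if (any(whole))
           mean(lor) - log(1 - protocol$inputs$ve) else NA_real_,
         logOR_SE = if (sum(whole) > 1) stats::sd(lor) else NA_real_,
         replicates = reps,
         config = list(design = protocol$design, test = test,
                       n = protocol$n, theta = theta, delta = delta,
                       alpha = alpha, policy = policy, seed = seed)),
    class = "power_summary"
  )
}

#' @export
print.power_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s, %s test, n = %d, %d replicates\n",
              toupper(cfg$design), cfg$test, cfg$n, x$replicates))
  cat(sprintf("  rejection rate %.4f (MC SE %.4f) at one-sided alpha %.4g\n",
              x$rejection_rate, x$mc_se, cfg$alpha))
  cat(sprintf("  zero vaccinated-case rate %.4f; intractable rate %.4f\n",
              x$zero_vax_case_rate, x$intractable_rate))
  invisible(x)
}

#' Frequency of zero vaccinated test-positive cases
#'
#' Fraction of simulated replicates in which the vaccinated test-positive
#' cell is empty — the event that makes the plain Wald statistic
#' intractable, common under high effectiveness and low coverage.
#'
#' @inheritParams estimate_power
#' @return A proportion in `[0, 1]`.
#' @export
zero_cell_rate <- function(protocol, reps, seed) {
  tab <- replicate_tables(protocol, reps, seed)
  mean(tab[, "a"] == 0)
}

#' Bias and spread of the log odds ratio across continuity corrections
#'
#' Simulates one set of replicates and, for each correction `delta` in the
#' grid, reports the mean bias of the corrected log odds ratio relative to
#' the true `log(1 - ve)` and its empirical standard deviation. The
#' `delta = 0` row is flagged intractable (bias and SE undefined) whenever
#' any replicate contains a zero cell.
#'
#' @inheritParams estimate_power
#' @param deltas Grid of continuity corrections, each `>= 0`.
#' @return A data frame with columns `delta`, `bias`, `se`, `intractable`.
#' @export
cc_sweep <- function(protocol, deltas, reps, seed) {
  if (any(deltas < 0)) stop("`deltas` must be >= 0", call. = FALSE)
  tab <- replicate_tables(protocol, reps, seed)
  true_lor <- log(1 - protocol$inputs$ve)
  any_zero <- any(pmin(tab[, "a"], tab[, "b"], tab[, "c"], tab[, "d"]) == 0)
  rows <- lapply(deltas, function(dl) {
    intractable <- dl == 0 && any_zero
    if (intractable) return(data.frame(delta = dl, bias = NA_real_,
                                       se = NA_real_, intractable = TRUE))
    lor <- log((tab[, "a"] + dl) * (tab[, "d"] + dl) /
                 ((tab[, "b"] + dl) * (tab[, "c"] + dl)))
    data.frame(delta = dl, bias = mean(lor) - true_lor,
               se = stats::sd(lor), intractable = FALSE)
  })
  do.call(rbind, rows)
}

#' Spread of the score statistic by realized number of test-positives
#'
#' Groups TND replicates by the realized number of test-positive cases and
#' reports the within-group standard deviation of the margin-zero score
#' statistic. In a case-control study this grouping is degenerate (the
#' case count is fixed); in a TND the spread grows with the case count,
#' which is the source of the extra variability the TND-specific sample
#' size corrects for.
#'
#' @inheritParams estimate_power
#' @param min_group Groups with fewer replicates are omitted. Default `30`.
#' @return A data frame with columns `n_tp`, `sd_score`, `replicates`;
#'   the overall SD across all tractable replicates is attached as
#'   attribute `"overall_sd"`.
#' @export
score_spread_by_positives <- function(protocol, reps, seed, min_group = 30) {
  tab <- replicate_tables(protocol, reps, seed)
  dec <- apply_test_vec(tab, "score", 0, 0.5, protocol$inputs$alpha,
                        "substitute")
  ok <- dec$tractable
  n_tp <- tab[ok, "a"] + tab[ok, "c"]
  stat <- dec$statistic[ok]
  groups <- split(stat, n_tp)
  keep <- lengths(groups) >= min_group
  out <- data.frame(n_tp = as.integer(names(groups)[keep]),
                    sd_score = vapply(groups[keep], stats::sd, numeric(1)),
                    replicates = lengths(groups)[keep],
                    row.names = NULL)
  attr(out, "overall_sd") <- stats::sd(stat)
  out
}
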