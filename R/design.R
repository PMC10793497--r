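#' Design parameters for a test-negative or case-control vaccine study
#'
#' Bundles the planning inputs shared by every sample-size, simulation and
#' power routine in the package: the assumed vaccine effectiveness, the
#' vaccination coverage among test-negatives (a proxy for population
#' coverage, since the vaccine is assumed to have no effect on test-negative
#' illness), the constant hazards of test-positive and test-negative
#' illness, the study duration, and the testing margin/error rates.
#'
#' @param ve Assumed vaccine effectiveness, a proportion in `[0, 1)`.
#'   VE is one minus the odds ratio of testing positive comparing
#'   vaccinated with unvaccinated patients.
#' @param p_n Expected vaccinated fraction among test-negative controls,
#'   in `(0, 1)`.
#' @param lambda_i Constant hazard (per day) of test-positive illness in
#'   unprotected individuals. Default `0.001`.
#' @param lambda_n Constant hazard (per day) of test-negative illness,
#'   identical in vaccinated and unvaccinated. Default `0.002`.
#' @param tau Study duration in days. Default `100`.
#' @param alpha One-sided significance level, in `(0, 0.5)`. Default `0.025`.
#' @param power Desired power `1 - gamma`, in `(0.5, 1)`. Default `0.8`.
#' @param theta Margin of the null hypothesis `H0: VE <= theta`, in `[0, 1)`.
#'   Default `0`.
#'
#' @return An object of class `"tnd_design"`: a validated list with the
#'   above fields plus the cumulative hazards `Lambda_i = lambda_i * tau`
#'   and `Lambda_n = lambda_n * tau`.
#' @examples
#' d <- design_inputs(ve = 0.95, p_n = 0.1)
#' expected_positivity(d)
#' @export
design_inputs <- function(ve, p_n, lambda_i = 0.001, lambda_n = 0.002,
                          tau = 100, alpha = 0.025, power = 0.8, theta = 0) {
  stopifnot(is.numeric(ve), length(ve) == 1, is.numeric(p_n), length(p_n) == 1)
  if (ve < 0 || ve > 1) stop("`ve` must lie in [0, 1]", call. = FALSE)
  if (p_n <= 0 || p_n >= 1) stop("`p_n` must lie in (0, 1)", call. = FALSE)
  if (lambda_i < 0) stop("`lambda_i` must be >= 0", call. = FALSE)
  if (lambda_n < 0) stop("`lambda_n` must be >= 0", call. = FALSE)
  if (tau <= 0 || !is.finite(tau)) stop("`tau` must be a positive, finite duration", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5)", call. = FALSE)
  if (power <= 0.5 || power >= 1) stop("`power` must lie in (0.5, 1)", call. = FALSE)
  if (alpha + (1 - power) >= 1) stop("`alpha` and `power` are inconsistent", call. = FALSE)
  if (theta < 0 || theta >= 1) stop("`theta` must lie in [0, 1)", call. = FALSE)
  structure(
    list(ve = ve, p_n = p_n, lambda_i = lambda_i, lambda_n = lambda_n,
         tau = tau, alpha = alpha, power = power, theta = theta,
         Lambda_i = lambda_i * tau, Lambda_n = lambda_n * tau),
    class = "tnd_design"
  )
}

#' @export
print.tnd_design <- function(x, ...) {
  cat("Test-negative design inputs\n")
  cat(sprintf("  VE = %.3f, coverage p_N = %.3f, margin theta = %.3f\n",
              x$ve, x$p_n, x$theta))
  cat(sprintf("  hazards: lambda_I = %g/day, lambda_N = %g/day over tau = %g days\n",
              x$lambda_i, x$lambda_n, x$tau))
  cat(sprintf("  one-sided alpha = %.4f, target power = %.2f\n", x$alpha, x$power))
  invisible(x)
}

#' Expected vaccinated fraction among test-positive cases
#'
#' Inverts the odds-ratio relation of the design: under effectiveness `ve`
#' the odds of vaccination among cases are `(1 - ve)` times the odds among
#' controls, giving `p_I = p_n (1 - ve) / (1 - p_n * ve)`.
#'
#' @param p_n Vaccinated fraction among test-negatives, in `(0, 1)`.
#' @param ve Vaccine effectiveness, in `[0, 1)`.
#' @return The expected vaccinated fraction among test-positives, in
#'   `(0, p_n]`; equals `p_n` when `ve = 0`.
#' @examples
#' case_vax_fraction(0.3, 0.95)
#' @export
case_vax_fraction <- function(p_n, ve) {
  if (any(p_n <= 0 | p_n >= 1)) stop("`p_n` must lie in (0, 1)", call. = FALSE)
  if (any(ve < 0 | ve >= 1)) stop("`ve` must lie in [0, 1)", call. = FALSE)
  p_n * (1 - ve) / (1 - p_n * ve)
}

#' Expected percent positivity of a test-negative study
#'
#' The expected fraction of all tests that are positive, approximated from
#' the cumulative incidence of test-positive illness (depleted by
#' vaccination) and the cumulative hazard of test-negative illness:
#' `pi = A / (A + Lambda_N)` with
#' `A = (1 - p_n * ve) * (1 - exp(-Lambda_I))`.
#'
#' In a case-control study this plays the role of the fixed case fraction
#' `1 / (k + 1)` for a control:case ratio `k`; in a TND it is only the
#' expectation of a random positivity.
#'
#' @param inputs A [design_inputs()] object.
#' @return The expected positivity, in `(0, 1]`.
#' @export
expected_positivity <- function(inputs) {
  stopifnot(inherits(inputs, "tnd_design"))
  attack <- (1 - inputs$p_n * inputs$ve) * (1 - exp(-inputs$Lambda_i))
  denom <- attack + inputs$Lambda_n
  if (denom <= 0) stop("no tests expected: both incidence terms are zero", call. = FALSE)
  attack / denom
}

#' Expected 2x2 cell counts per source-population member
#'
#' Per-person expected contributions to the vaccination-by-result table
#' over the study period: vaccinated cases arise only from the unprotected
#' fraction `(1 - ve)` of vaccinees, and negative tests accrue at the
#' cumulative hazard `Lambda_N` irrespective of vaccination.
#'
#' @inheritParams expected_positivity
#' @return Named numeric vector `c(a, b, c, d)` of unit cell counts.
#' @export
unit_cell_counts <- function(inputs) {
  stopifnot(inherits(inputs, "tnd_design"))
  attack <- 1 - exp(-inputs$Lambda_i)
  c(a = inputs$p_n * (1 - inputs$ve) * attack,
    b = inputs$p_n * inputs$Lambda_n,
    c = (1 - inputs$p_n) * attack,
    d = (1 - inputs$p_n) * inputs$Lambda_n)
}

#' Source population size needed for a target number of tests
#'
#' The number of health-care-seeking individuals required so that the
#' expected number of tests over the study period is at least `n`:
#' the ceiling of `n` divided by the sum of the unit cell counts.
#'
#' @param n Target total number of tests (positive integer).
#' @inheritParams expected_positivity
#' @return Integer population size.
#' @examples
#' population_size(228, design_inputs(ve = 0.95, p_n = 0.1))
#' @export
population_size <- function(n, inputs) {
  stopifnot(inherits(inputs, "tnd_design"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  total <- sum(unit_cell_counts(inputs))
  if (total <= 0) stop("expected test count per person is zero", call. = FALSE)
  as.integer(ceiling(n / total))
}
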