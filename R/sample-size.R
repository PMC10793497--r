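new_ss_result <- function(n, method, unrounded_n, sigma0 = NA_real_,
                          sigma1 = NA_real_, p_i, p_n, pi, alpha, power) {
  structure(
    list(n = as.integer(n), method = method, unrounded_n = unrounded_n,
         sigma0 = sigma0, sigma1 = sigma1,
         p_i = p_i, p_n = p_n, pi = pi, alpha = alpha, power = power),
    class = "ss_result"
  )
}

#' @export
print.ss_result <- function(x, ...) {
  cat(sprintf("%s sample size: n = %d total tests\n", x$method, x$n))
  cat(sprintf("  p_I = %.5f, p_N = %.5f, positivity pi = %.5f\n",
              x$p_i, x$p_n, x$pi))
  cat(sprintf("  one-sided alpha = %.4g, target power = %.2f\n",
              x$alpha, x$power))
  invisible(x)
}

check_ss_inputs <- function(p_i, p_n, pi, alpha, power) {
  if (p_i <= 0 || p_i >= 1 || p_n <= 0 || p_n >= 1)
    stop("`p_i` and `p_n` must lie in (0, 1)", call. = FALSE)
  if (pi <= 0 || pi >= 1) stop("`pi` must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5)", call. = FALSE)
  if (power <= 0.5 || power >= 1) stop("`power` must lie in (0.5, 1)", call. = FALSE)
  if (p_i == p_n)
    stop("`p_i` equals `p_n`: no effect to detect, sample size is infinite",
         call. = FALSE)
  invisible(TRUE)
}

# Null and alternative SD terms of the score sample size. sigma0 pools the
# two groups under no group difference; sigma1 is the harmonic combination
# of the two binomial variances.
score_sd_terms <- function(p_i, p_n, pi) {
  s0sq <- (pi * p_i + (1 - pi) * p_n) *
    (pi * (1 - p_i) + (1 - pi) * (1 - p_n)) / (pi * (1 - pi))
  s1sq <- (p_i * (1 - p_i) * p_n * (1 - p_n) /
             (pi * p_i * (1 - p_i) + (1 - pi) * p_n * (1 - p_n))) /
    (pi * (1 - pi))
  c(sigma0 = sqrt(s0sq), sigma1 = sqrt(s1sq))
}

#' Fleiss-type Wald sample size for a two-group odds-ratio test
#'
#' Total number of tests required by the standard Wald test at one-sided
#' level `alpha` and power `power`, for case fraction `pi` and vaccinated
#' fractions `p_i` (cases) and `p_n` (controls). This is the classical
#' case-control formula re-parameterized for the TND, where `pi` is the
#' expected percent positivity.
#'
#' @param p_i Expected vaccinated fraction among test-positives.
#' @param p_n Expected vaccinated fraction among test-negatives.
#' @param pi Expected fraction of positives among all tests.
#' @param alpha One-sided significance level. Default `0.025`.
#' @param power Target power. Default `0.8`.
#' @return An `"ss_result"` with the rounded-up total `n` and the
#'   unrounded value.
#' @examples
#' d <- design_inputs(ve = 0.95, p_n = 0.1)
#' wald_sample_size(case_vax_fraction(d$p_n, d$ve), d$p_n,
#'                  expected_positivity(d))
#' @export
wald_sample_size <- function(p_i, p_n, pi, alpha = 0.025, power = 0.8) {
  check_ss_inputs(p_i, p_n, pi, alpha, power)
  za <- stats::qnorm(1 - alpha)
  zg <- stats::qnorm(power)
  pbar <- pi * p_i + (1 - pi) * p_n
  num <- (za * sqrt(pbar * (1 - pbar)) +
            zg * sqrt((1 - pi) * p_i * (1 - p_i) + pi * p_n * (1 - p_n)))^2
  n <- num / (pi * (1 - pi) * (p_i - p_n)^2)
  new_ss_result(ceiling(n), "wald", n, p_i = p_i, p_n = p_n, pi = pi,
                alpha = alpha, power = power)
}

#' Continuity-corrected (Yates) Wald sample size
#'
#' Inflates the standard Wald sample size to account for the Yates
#' continuity correction:
#' `n_C = (n_W / 4) * (1 + sqrt(1 + 2 / (pi (1 - pi) n_W |p_i - p_n|)))^2`.
#' The unrounded Wald value is used internally to avoid double rounding.
#'
#' @inheritParams wald_sample_size
#' @return An `"ss_result"`; `n` always exceeds the Wald sample size.
#' @export
cc_wald_sample_size <- function(p_i, p_n, pi, alpha = 0.025, power = 0.8) {
  check_ss_inputs(p_i, p_n, pi, alpha, power)
  nw <- wald_sample_size(p_i, p_n, pi, alpha, power)$unrounded_n
  n <- (nw / 4) *
    (1 + sqrt(1 + 2 / (pi * (1 - pi) * nw * abs(p_i - p_n))))^2
  new_ss_result(ceiling(n), "cc_wald", n, p_i = p_i, p_n = p_n, pi = pi,
                alpha = alpha, power = power)
}

#' Score sample size for a case-control study
#'
#' Sample size matched to the logistic-model score test:
#' `n_S = (z_{1-gamma} sigma1 + z_{1-alpha} sigma0)^2 / (p_i - p_n)^2`,
#' where `sigma0^2` pools the two groups under the null and `sigma1^2` is
#' the harmonic combination of the group-specific binomial variances under
#' the alternative. Treats the case fraction `pi` as fixed by design, as in
#' a case-control study.
#'
#' @inheritParams wald_sample_size
#' @return An `"ss_result"` including the `sigma0` and `sigma1` terms.
#' @export
score_sample_size <- function(p_i, p_n, pi, alpha = 0.025, power = 0.8) {
  check_ss_inputs(p_i, p_n, pi, alpha, power)
  s <- score_sd_terms(p_i, p_n, pi)
  n <- (stats::qnorm(power) * s[["sigma1"]] +
          stats::qnorm(1 - alpha) * s[["sigma0"]])^2 / (p_i - p_n)^2
  new_ss_result(ceiling(n), "score", n, sigma0 = s[["sigma0"]],
                sigma1 = s[["sigma1"]], p_i = p_i, p_n = p_n, pi = pi,
                alpha = alpha, power = power)
}

#' Power of the score test in a TND with random positivity
#'
#' In a TND the realized positivity `pi_hat = (a + c) / n` is random, not
#' fixed by design. The attainable power at total size `n` is the binomial
#' mixture
#' \deqn{\sum_k \Phi\left(\frac{z_\alpha \sigma_0 - (p_I - p_N)\sqrt{n}}
#'   {\tilde\sigma_1(k/n)}\right) \binom{n}{k} \pi^k (1-\pi)^{n-k},}
#' where `sigma0` is held at its fixed-`pi` value (it is nearly constant in
#' `pi_hat`) and the alternative SD uses the multinomial form
#' `sigma1_tilde^2(x) = p_i(1-p_i)/x + p_n(1-p_n)/(1-x) + 2 p_i p_n`.
#' The boundary terms `k = 0` and `k = n` — tables with an empty case or
#' control column, where the test is undefined — contribute zero rejection
#' probability; their binomial weight is negligible in practical designs.
#'
#' @param n Total number of tests (positive integer).
#' @inheritParams wald_sample_size
#' @return The attained power, in `[0, 1]`.
#' @export
tnd_power <- function(n, p_i, p_n, pi, alpha = 0.025) {
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  check_ss_inputs(p_i, p_n, pi, alpha, 0.8)
  sigma0 <- score_sd_terms(p_i, p_n, pi)[["sigma0"]]
  if (n == 1) return(0)  # only boundary terms exist
  k <- seq_len(n - 1)
  x <- k / n
  sigma1_tilde <- sqrt(p_i * (1 - p_i) / x + p_n * (1 - p_n) / (1 - x) +
                         2 * p_i * p_n)
  z <- (stats::qnorm(alpha) * sigma0 - (p_i - p_n) * sqrt(n)) / sigma1_tilde
  sum(stats::pnorm(z) * stats::dbinom(k, n, pi))
}

#' Proposed TND score sample size
#'
#' Smallest total number of tests at or above the case-control score
#' sample size whose binomial-mixture power ([tnd_power()]) reaches the
#' target. This accounts for the extra variability of the random
#' case:control split in a TND, which erodes power at high vaccine
#' effectiveness; the search increments `n` by one from the score sample
#' size.
#'
#' @inheritParams wald_sample_size
#' @param max_multiple Search cap as a multiple of the score sample size;
#'   exceeding it raises a non-convergence error. Default `100`.
#' @return An `"ss_result"` with `method = "tnd_score"`; `unrounded_n` is
#'   the integer found (the search is inherently integer-valued).
#' @examples
#' d <- design_inputs(ve = 0.95, p_n = 0.1)
#' tnd_score_sample_size(case_vax_fraction(d$p_n, d$ve), d$p_n,
#'                       expected_positivity(d))
#' @export
tnd_score_sample_size <- function(p_i, p_n, pi, alpha = 0.025, power = 0.8,
                                  max_multiple = 100) {
  base <- score_sample_size(p_i, p_n, pi, alpha, power)
  n <- base$n
  cap <- max_multiple * base$n
  while (tnd_power(n, p_i, p_n, pi, alpha) < power) {
    n <- n + 1
    if (n > cap)
      stop("TND score sample size search did not converge below ",
           cap, " tests", call. = FALSE)
  }
  new_ss_result(n, "tnd_score", as.numeric(n), sigma0 = base$sigma0,
                sigma1 = base$sigma1, p_i = p_i, p_n = p_n, pi = pi,
                alpha = alpha, power = power)
}

#' Sample size from design inputs
#'
#' Convenience wrapper deriving `p_i` and `pi` from a [design_inputs()]
#' object (or accepting overrides) and dispatching to the requested
#' sample-size method.
#'
#' @param inputs A [design_inputs()] object.
#' @param method One of `"wald"`, `"cc_wald"`, `"score"`, `"tnd_score"`.
#' @param pi Optional positivity override; defaults to
#'   [expected_positivity()] of `inputs`.
#' @param p_i Optional override of the case vaccination fraction; defaults
#'   to [case_vax_fraction()].
#' @return An `"ss_result"`.
#' @examples
#' sample_size(design_inputs(ve = 0.95, p_n = 0.1), "tnd_score")
#' @export
sample_size <- function(inputs,
                        method = c("wald", "cc_wald", "score", "tnd_score"),
                        pi = NULL, p_i = NULL) {
  stopifnot(inherits(inputs, "tnd_design"))
  method <- match.arg(method)
  if (is.null(pi)) pi <- expected_positivity(inputs)
  if (is.null(p_i)) p_i <- case_vax_fraction(inputs$p_n, inputs$ve)
  fn <- switch(method, wald = wald_sample_size, cc_wald = cc_wald_sample_size,
               score = score_sample_size, tnd_score = tnd_score_sample_size)
  fn(p_i, inputs$p_n, pi, alpha = inputs$alpha, power = inputs$power)
}
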