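#' A 2x2 vaccination-by-test-result table
#'
#' Cell counts follow the usual layout for vaccine case-control and
#' test-negative data: `a` vaccinated test-positives, `b` vaccinated
#' test-negatives, `c` unvaccinated test-positives, `d` unvaccinated
#' test-negatives. The vaccine-effectiveness point estimate is one minus
#' the odds ratio, `1 - (a d) / (b c)`, defined only when `b c > 0`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `"vax_table"` with the four counts and the
#'   margins `n_tp = a + c` (tests positive), `n_tn = b + d` and total `n`.
#' @examples
#' contingency_table(2, 20, 10, 40)
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(
    list(a = counts[["a"]], b = counts[["b"]], c = counts[["c"]], d = counts[["d"]],
         n_tp = counts[["a"]] + counts[["c"]],
         n_tn = counts[["b"]] + counts[["d"]],
         n = sum(counts)),
    class = "vax_table"
  )
}

#' @export
print.vax_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("vaccinated", "unvaccinated"),
                              c("test+", "test-")))
  print(m)
  if (x$b * x$c > 0)
    cat(sprintf("VE estimate (1 - OR): %.4f\n", 1 - (x$a * x$d) / (x$b * x$c)))
  invisible(x)
}

new_test_result <- function(statistic, method, theta, alpha, delta = NA_real_,
                            tractable = TRUE, branch = NA_character_) {
  z_crit <- stats::qnorm(alpha)  # lower-tail critical value
  reject <- isTRUE(tractable) && is.finite(statistic) && statistic < z_crit
  structure(
    list(statistic = if (tractable) statistic else NA_real_,
         p_value = if (tractable) stats::pnorm(statistic) else NA_real_,
         method = method, branch = branch, theta = theta, delta = delta,
         alpha = alpha, z_crit = z_crit,
         tractable = tractable, reject = reject),
    class = "tnd_test"
  )
}

#' @export
print.tnd_test <- function(x, ...) {
  cat(sprintf("%s test of H0: VE <= %.3g (one-sided alpha = %.4g)\n",
              x$method, x$theta, x$alpha))
  if (!x$tractable) {
    cat("  statistic intractable for this table\n")
  } else {
    cat(sprintf("  statistic = %.5f, p = %.5g, %s\n", x$statistic, x$p_value,
                if (x$reject) "reject H0" else "fail to reject H0"))
  }
  invisible(x)
}

#' One-sided Wald test of a vaccine-effectiveness margin
#'
#' Tests `H0: VE <= theta` against `H1: VE > theta` via the log odds ratio
#' with its Delta-method standard error:
#' `T_W = (ln(ad/bc) - ln(1 - theta)) / sqrt(1/a + 1/b + 1/c + 1/d)`.
#' Effectiveness above the margin pushes the log odds ratio below
#' `ln(1 - theta)`, so the rejection region is the lower tail,
#' `T_W < qnorm(alpha)`. The statistic is intractable whenever any cell
#' count is zero.
#'
#' @param table A [contingency_table()].
#' @param theta Null-hypothesis margin, in `[0, 1)`. Default `0`.
#' @param alpha One-sided significance level. Default `0.025`.
#' @return A `"tnd_test"` result with fields `statistic`, `p_value`,
#'   `reject`, `tractable`, `method`.
#' @examples
#' wald_test(contingency_table(2, 20, 10, 40))
#' @export
wald_test <- function(table, theta = 0, alpha = 0.025) {
  stopifnot(inherits(table, "vax_table"))
  check_theta_alpha(theta, alpha)
  if (table$n == 0 || min(table$a, table$b, table$c, table$d) == 0)
    return(new_test_result(NA_real_, "wald", theta, alpha, tractable = FALSE))
  lor <- log(table$a * table$d / (table$b * table$c))
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  new_test_result((lor - log(1 - theta)) / se, "wald", theta, alpha)
}

#' Continuity-corrected Wald test
#'
#' As [wald_test()] after adding a constant `delta` to every cell
#' (Yates' correction uses `delta = 0.5`). This keeps the statistic
#' defined in sparse tables at the cost of biasing the log odds ratio
#' towards the null.
#'
#' @inheritParams wald_test
#' @param delta Continuity correction added to each cell, `>= 0`.
#'   Default `0.5`.
#' @return A `"tnd_test"` result.
#' @examples
#' cc_wald_test(contingency_table(0, 20, 10, 40))
#' @export
cc_wald_test <- function(table, theta = 0, delta = 0.5, alpha = 0.025) {
  stopifnot(inherits(table, "vax_table"))
  check_theta_alpha(theta, alpha)
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (table$n == 0 ||
      (delta == 0 && min(table$a, table$b, table$c, table$d) == 0))
    return(new_test_result(NA_real_, "cc_wald", theta, alpha, delta = delta,
                           tractable = FALSE))
  a <- table$a + delta; b <- table$b + delta
  cc <- table$c + delta; d <- table$d + delta
  lor <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  new_test_result((lor - log(1 - theta)) / se, "cc_wald", theta, alpha,
                  delta = delta)
}

#' Score test from the simple logistic model
#'
#' Score test of `H0: VE <= theta` based on the logistic regression of test
#' result on vaccination status, with the variance evaluated under the
#' null. With margin `theta = 0` the statistic has the closed form
#' `T_S = (ad - bc) sqrt(n) / sqrt((a+c)(b+d)(a+b)(c+d))`, whose square is
#' the Pearson chi-square statistic; it remains defined with a single zero
#' cell as long as all four margins are positive. For `theta > 0` the
#' intercept is profiled under the constraint that the slope equals
#' `ln(1 - theta)` and the slope score is standardized by the expected
#' information.
#'
#' @inheritParams wald_test
#' @return A `"tnd_test"` result.
#' @examples
#' score_test(contingency_table(0, 20, 10, 40))  # tractable despite a = 0
#' @export
score_test <- function(table, theta = 0, alpha = 0.025) {
  stopifnot(inherits(table, "vax_table"))
  check_theta_alpha(theta, alpha)
  if (table$n == 0 ||
      min(table$n_tp, table$n_tn, table$a + table$b, table$c + table$d) == 0)
    return(new_test_result(NA_real_, "score", theta, alpha, tractable = FALSE))
  if (theta == 0) {
    stat <- (table$a * table$d - table$b * table$c) * sqrt(table$n) /
      sqrt(table$n_tp * table$n_tn *
             (table$a + table$b) * (table$c + table$d))
    return(new_test_result(stat, "score", theta, alpha))
  }
  new_test_result(constrained_score_stat(table, theta), "score", theta, alpha)
}

# Score statistic for a general margin: outcome = test-positive, covariate =
# vaccination. Under H0 the slope is fixed at log(1 - theta); the intercept
# solves its own score equation and the slope score is standardized by the
# profiled expected information.
constrained_score_stat <- function(table, theta) {
  slope <- log(1 - theta)
  nv <- table$a + table$b   # vaccinated tests
  nu <- table$c + table$d   # unvaccinated tests
  intercept_score <- function(b0) {
    (table$a - nv * stats::plogis(b0 + slope)) +
      (table$c - nu * stats::plogis(b0))
  }
  b0 <- stats::uniroot(intercept_score, c(-50, 50), tol = 1e-12)$root
  p1 <- stats::plogis(b0 + slope)
  p0 <- stats::plogis(b0)
  u <- table$a - nv * p1
  w1 <- nv * p1 * (1 - p1)
  w0 <- nu * p0 * (1 - p0)
  u / sqrt(w1 * w0 / (w1 + w0))
}

#' Wald test with continuity-corrected fallback
#'
#' Applies the standard Wald test when all four cells are positive and
#' substitutes the continuity-corrected version when any cell is zero —
#' the usual practice when the plain Wald statistic is intractable in
#' sparse tables. The `branch` field of the result records which
#' statistic was used.
#'
#' @inheritParams cc_wald_test
#' @return A `"tnd_test"` result with `method = "hybrid_wald"`.
#' @export
hybrid_wald_test <- function(table, theta = 0, delta = 0.5, alpha = 0.025) {
  stopifnot(inherits(table, "vax_table"))
  if (delta <= 0) stop("`delta` must be > 0 for the fallback branch", call. = FALSE)
  if (min(table$a, table$b, table$c, table$d) > 0) {
    res <- wald_test(table, theta, alpha)
    branch <- "wald"
  } else {
    res <- cc_wald_test(table, theta, delta, alpha)
    branch <- "cc_wald"
  }
  res$method <- "hybrid_wald"
  res$branch <- branch
  res$delta <- delta
  res
}

check_theta_alpha <- function(theta, alpha) {
  if (theta < 0 || theta >= 1) stop("`theta` must lie in [0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5)", call. = FALSE)
  invisible(TRUE)
}
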