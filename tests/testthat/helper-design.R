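# Standard planning scenario used throughout the suite: constant hazards
# 0.001/day (test-positive, unprotected) and 0.002/day (test-negative)
# over a 100-day study, one-sided alpha 0.025, target power 0.8.
std_design <- function(ve, p_n, ...) {
  design_inputs(ve = ve, p_n = p_n, lambda_i = 0.001, lambda_n = 0.002,
                tau = 100, ...)
}

# Derived (p_i, pi) pair for the standard scenario.
std_derived <- function(ve, p_n) {
  d <- std_design(ve, p_n)
  list(p_i = case_vax_fraction(p_n, ve), pi = expected_positivity(d), d = d)
}

ve_grid <- c(0.30, 0.50, 0.70, 0.90, 0.95)
pn_grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)

# Random 2x2 tables with all-positive margins (zero cells allowed).
random_margin_tables <- function(n_tables, seed) {
  set.seed(seed)
  out <- vector("list", n_tables)
  i <- 1
  while (i <= n_tables) {
    counts <- rpois(4, lambda = sample(c(2, 5, 20, 80), 4, replace = TRUE))
    tab <- contingency_table(counts[1], counts[2], counts[3], counts[4])
    if (min(tab$n_tp, tab$n_tn, tab$a + tab$b, tab$c + tab$d) > 0) {
      out[[i]] <- tab
      i <- i + 1
    }
  }
  out
}
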