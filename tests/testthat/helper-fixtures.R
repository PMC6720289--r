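# Shared fixtures: all test panels are built in code.

# A small random panel with uniform scores on [0, 100], reproducible.
random_panel <- function(n, m, seed) {
  withr::with_seed(seed, {
    indicator_panel(matrix(round(stats::runif(n * m, 0, 100), 4), n, m))
  })
}

# Assert every gp_solution invariant:
#   - weights on the simplex, nonnegative
#   - complementarity d- * d+ = 0 after post-processing
#   - goal identity MEP_i + d-_ij - d+_ij = epi_ij
#   - MEP_i within the country's own score range (hence [0, 100])
#   - accounting Z = sum_j D_j; Z_weighted = Z when alpha = beta = 1
#   - closed-form objective agrees with the LP optimum
expect_solution_ok <- function(sol, panel, tol = 1e-6) {
  expect_s3_class(sol, "gp_solution")
  w <- sol$weights
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(sol$dev_neg >= 0))
  expect_true(all(sol$dev_pos >= 0))
  expect_true(all(sol$dev_neg * sol$dev_pos == 0))
  resid <- unclass(panel) - (sol$mep + sol$dev_neg - sol$dev_pos)
  expect_lt(max(abs(resid)), 1e-9)
  expect_true(all(sol$mep >= apply(panel, 1L, min) - 1e-9))
  expect_true(all(sol$mep <= apply(panel, 1L, max) + 1e-9))
  expect_equal(sol$Z, sum(sol$disagreements), tolerance = 1e-12)
  if (all(sol$config$alpha == 1) && all(sol$config$beta == 1)) {
    expect_equal(sol$Z_weighted, sol$Z, tolerance = 1e-12)
  }
  lam <- sol$lam
  closed <- lam * sol$Z_weighted + (1 - lam) * sol$D
  expect_equal(closed, sol$objective, tolerance = tol)
  invisible(sol)
}
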