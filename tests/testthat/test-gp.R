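# Solver tests.  Each solve goes through the LP backend; expect_solution_ok
# asserts the full invariant set (simplex weights, complementarity, goal
# identity, MEP bounds, accounting, LP/closed-form agreement) on every one.

test_that("a single indicator is fit exactly by all three models", {
  ka <- known_answer_panel("single_indicator")
  for (sol in list(solve_wgp(ka$panel), solve_minmax(ka$panel),
                   solve_extended(ka$panel, 0.5))) {
    expect_solution_ok(sol, ka$panel)
    expect_equal(unname(sol$weights), ka$expected$w)
    expect_equal(sol$Z, ka$expected$Z)
    expect_equal(sol$D, ka$expected$D)
    expect_equal(sol$mep, ka$expected$mep)
  }
})

test_that("duplicate indicator columns are fit exactly (Z = 0)", {
  ka <- known_answer_panel("duplicate_columns")
  sol <- solve_wgp(ka$panel)
  expect_solution_ok(sol, ka$panel)
  expect_equal(sol$Z, 0, tolerance = 1e-9)
  expect_equal(sol$mep, ka$expected$mep, tolerance = 1e-9)
})

test_that("L1 and MINMAX optima are never beaten by the lattice oracle", {
  for (seed in c(101, 102)) {
    p <- random_panel(4, 3, seed = seed)
    wgp <- expect_solution_ok(solve_wgp(p), p)
    mm <- expect_solution_ok(solve_minmax(p), p)
    gaps_z <- gaps_d <- numeric(0)
    for (step in c(0.1, 0.01)) {
      gz <- grid_oracle(p, step, criterion = "Z_weighted")$value
      gd <- grid_oracle(p, step, criterion = "D")$value
      expect_gte(gz, wgp$Z_weighted - 1e-9)
      expect_gte(gd, mm$D - 1e-9)
      gaps_z <- c(gaps_z, gz - wgp$Z_weighted)
      gaps_d <- c(gaps_d, gd - mm$D)
    }
    # refining the lattice cannot increase the gap
    expect_lte(gaps_z[2], gaps_z[1] + 1e-9)
    expect_lte(gaps_d[2], gaps_d[1] + 1e-9)
  }
})

test_that("the extended model interpolates between the L1 and MINMAX optima", {
  p <- random_panel(5, 3, seed = 103)
  wgp <- solve_wgp(p)
  mm <- solve_minmax(p)
  ext <- solve_extended_batch(p, c(0, 0.5, 1))
  for (s in ext) expect_solution_ok(s, p)
  expect_equal(ext[[3]]$Z_weighted, wgp$Z_weighted, tolerance = 1e-8)
  expect_equal(ext[[1]]$D, mm$D, tolerance = 1e-8)
  # the lambda = 0.5 solution minimizes the composite: it must not lose to
  # either endpoint solution under its own objective
  comp <- function(s) 0.5 * s$Z_weighted + 0.5 * s$D
  expect_lte(comp(ext[[2]]), comp(wgp) + 1e-6)
  expect_lte(comp(ext[[2]]), comp(mm) + 1e-6)
  expect_error(solve_extended(p, 1.5), "lam")
  expect_error(solve_extended(p, -0.1), "lam")
})

test_that("permuting countries permutes MEP and leaves objectives unchanged", {
  p <- random_panel(6, 3, seed = 104)
  perm <- c(4, 1, 6, 2, 5, 3)
  q <- indicator_panel(unclass(p)[perm, ])
  a <- solve_wgp(p)
  b <- solve_wgp(q)
  expect_equal(b$Z_weighted, a$Z_weighted, tolerance = 1e-9)
  expect_equal(b$D, a$D, tolerance = 1e-9)
  expect_equal(unname(b$mep), unname(a$mep[perm]), tolerance = 1e-9)
  expect_equal(b$disagreements, a$disagreements, tolerance = 1e-9)
})

test_that("asymmetric deviation penalties change the optimum as configured", {
  p <- random_panel(6, 3, seed = 105)
  cfg <- deviation_config(3, alpha = c(1, 0, 1), beta = c(1, 1, 0))
  sol <- expect_solution_ok(solve_wgp(p, cfg), p)
  # penalized sum cannot exceed the fully-penalized one at the same weights
  ev_full <- evaluate_weights(p, sol$weights)
  expect_lte(sol$Z_weighted, ev_full$Z + 1e-9)
  # and the optimum cannot beat the grid oracle under the same config
  go <- grid_oracle(p, 0.01, config = cfg, criterion = "Z_weighted")
  expect_gte(go$value, sol$Z_weighted - 1e-9)
  mm <- expect_solution_ok(solve_minmax(p, cfg), p)
  god <- grid_oracle(p, 0.01, config = cfg, criterion = "D")
  expect_gte(god$value, mm$D - 1e-9)
})

test_that("the L1 model agrees with constrained median regression", {
  skip_if_not_installed("quantreg")
  p <- random_panel(8, 3, seed = 106)
  sol <- solve_wgp(p)
  # L1 weight estimation is a median regression of the stacked indicator
  # scores on the country score profiles, with simplex-constrained
  # coefficients: an independent interior-point route to the same optimum.
  n <- nrow(p)
  m <- ncol(p)
  X <- unclass(p)[rep(seq_len(n), m), ]
  y <- as.vector(unclass(p))
  R <- rbind(rep(1, m), rep(-1, m), diag(m))
  r <- c(1 - 1e-9, -1 - 1e-9, rep(0, m))
  fit <- quantreg::rq.fit.fnc(X, y, R = R, r = r, tau = 0.5)
  w_rq <- pmax(fit$coefficients, 0)
  w_rq <- w_rq / sum(w_rq)
  expect_equal(evaluate_weights(p, w_rq)$Z_weighted, sol$Z_weighted,
               tolerance = 1e-6)
})

test_that("an unknown solver backend is rejected", {
  p <- known_answer_panel("single_indicator")$panel
  expect_error(solve_wgp(p, solver = "simplex"), "unknown solver")
})
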