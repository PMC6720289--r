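test_that("the lambda grid is inclusive and index-built", {
  p <- random_panel(4, 2, seed = 201)
  sr <- sweep_lambda(p, step = 0.5)
  expect_equal(sr$lam_grid, c(0, 0.5, 1))
  expect_length(sr$solutions, 3L)
  # default grid: 101 points, endpoints exact (no accumulation drift)
  nsteps <- floor((1 - 0) / 0.01 + 1e-9)
  expect_equal(nsteps, 100L)
})

test_that("a degenerate grid reduces to the single requested model", {
  p <- random_panel(5, 3, seed = 202)
  sr <- sweep_lambda(p, lam_start = 1, lam_end = 1, step = 0.01)
  expect_equal(sr$lam_grid, 1)
  wgp <- solve_wgp(p)
  expect_equal(sr$solutions[[1]]$Z_weighted, wgp$Z_weighted,
               tolerance = 1e-8)
})

test_that("per-country summaries bracket the endpoint MEPs and are ordered", {
  p <- random_panel(6, 3, seed = 203)
  sr <- sweep_lambda(p, step = 0.25)
  s <- sr$mep_summary
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                    s$median <= s$q3 & s$q3 <= s$max))
  expect_true(all(sr$mep[, 1] >= s$min - 1e-12 & sr$mep[, 1] <= s$max + 1e-12))
  expect_true(all(sr$mep[, ncol(sr$mep)] >= s$min - 1e-12 &
                    sr$mep[, ncol(sr$mep)] <= s$max + 1e-12))
})

test_that("a single-indicator panel sweeps to a constant MEP", {
  p <- known_answer_panel("single_indicator")$panel
  sr <- sweep_lambda(p, step = 0.5)
  expect_equal(sr$mep_summary$min, sr$mep_summary$max)
  expect_equal(sr$mep_summary$median, unname(unclass(p)[, 1]))
})

test_that("sweeping twice gives bit-identical results", {
  p <- random_panel(5, 3, seed = 204)
  a <- sweep_lambda(p, step = 0.5)
  b <- sweep_lambda(p, step = 0.5)
  expect_identical(a$mep, b$mep)
  expect_identical(lapply(a$solutions, `[[`, "weights"),
                   lapply(b$solutions, `[[`, "weights"))
})

test_that("rank_countries sorts by descending median, ties alphabetical", {
  fake <- structure(list(mep_summary = data.frame(
    country = c("B", "A", "C"),
    min = c(1, 1, 9), q1 = c(2, 2, 9), median = c(20, 20, 80),
    q3 = c(3, 3, 9), max = c(4, 4, 9))), class = "gp_sweep")
  rk <- rank_countries(fake)
  expect_equal(rk$country, c("C", "A", "B"))
  expect_equal(rk$rank, 1:3)
})

test_that("category weights sum the member indicator weights per lambda", {
  p <- random_panel(6, 3, seed = 205)
  colnames(p) <- c("I1", "I2", "I3")
  sr <- sweep_lambda(p, step = 0.5)
  # all indicators in one category: weight 1 at every lambda
  h1 <- hierarchy(data.frame(
    objective = "O", objective_code = "O", objective_weight = 1,
    category = "C", category_code = "C", category_weight = 1,
    indicator = c("I1", "I2", "I3"), indicator_code = c("I1", "I2", "I3"),
    indicator_weight = c(0.4, 0.3, 0.3)))
  cw1 <- category_weights(sr, h1)
  expect_equal(unname(cw1$C), rep(1, 3), tolerance = 1e-9)
  # split categories: sums match the solution weights, rows sum to 1
  h2 <- hierarchy(data.frame(
    objective = "O", objective_code = "O", objective_weight = 1,
    category = c("C1", "C1", "C2"), category_code = c("C1", "C1", "C2"),
    category_weight = c(0.7, 0.7, 0.3),
    indicator = c("I1", "I2", "I3"), indicator_code = c("I1", "I2", "I3"),
    indicator_weight = c(0.5, 0.5, 1)))
  cw2 <- category_weights(sr, h2)
  for (k in seq_along(sr$lam_grid)) {
    w <- sr$solutions[[k]]$weights
    expect_equal(cw2$C1[k], unname(w[["I1"]] + w[["I2"]]), tolerance = 1e-9)
  }
  expect_equal(unname(cw2$C1 + cw2$C2), rep(1, 3), tolerance = 1e-6)
  rng <- attr(cw2, "range")
  expect_equal(rng$min, pmin(rng$min, rng$max))
  # mismatched leaves are an error
  colnames(p)[1] <- "ZZ"
  expect_error(category_weights(sweep_lambda(p, lam_start = 1, lam_end = 1),
                                h1), "do not match")
})

test_that("epi_score applies fixed hierarchy weights, optionally normalized", {
  h <- epi_hierarchy()
  codes <- h$indicator_code
  perfect <- indicator_panel(matrix(100, 1, 24, dimnames = list("A", codes)))
  expect_equal(unname(epi_score(perfect, h, normalize = TRUE)), 1)
  expect_equal(unname(epi_score(perfect, h)), 100)
  # single-indicator hierarchy: the score is that indicator
  h1 <- hierarchy(data.frame(
    objective = "O", objective_code = "O", objective_weight = 1,
    category = "C", category_code = "C", category_weight = 1,
    indicator = "I1", indicator_code = "I1", indicator_weight = 1))
  p1 <- indicator_panel(matrix(c(30, 60), 2, 1,
                               dimnames = list(c("A", "B"), "I1")))
  expect_equal(unname(epi_score(p1, h1)), c(30, 60))
  expect_equal(unname(epi_score(p1, h1, normalize = TRUE)), c(0.3, 0.6))
})

test_that("fixed-weight scoring with a GP weight vector recovers its MEP", {
  p <- random_panel(5, 3, seed = 206)
  sol <- solve_extended(p, 0.5)
  expect_equal(aggregate_mep(p, sol$weights), sol$mep)
})
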