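test_that("panel construction enforces completeness, bounds and uniqueness", {
  p <- indicator_panel(matrix(c(10, 50, 30, 70), 2, 2),
                       country_ids = c("A", "B"),
                       indicator_codes = c("X1", "X2"))
  expect_equal(n_countries(p), 2L)
  expect_equal(n_indicators(p), 2L)

  expect_error(indicator_panel(matrix(c(10, NA), 1, 2)), "missing")
  expect_error(indicator_panel(matrix(c(10, 101), 1, 2)), "out of \\[0, 100\\]")
  expect_error(indicator_panel(matrix(-1, 1, 1)), "out of \\[0, 100\\]")
  expect_error(indicator_panel(matrix(1, 2, 1), country_ids = c("A", "A")),
               "duplicate country")
  expect_error(indicator_panel(matrix(1, 1, 2),
                               indicator_codes = c("X", "X")),
               "duplicate indicator")
  expect_error(indicator_panel(matrix(numeric(0), 0, 1)), "at least one")
})

test_that("a 1x1 panel with value 50 is a valid minimal panel", {
  p <- indicator_panel(matrix(50, 1, 1))
  expect_equal(unname(unclass(p)), matrix(50, 1, 1))
})

test_that("load_panel reads the CSV dialect and drops incomplete rows", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("country,X1,X2",
               "A,10,30",
               "B,50,",
               "C,20,80"), csv)
  expect_error(load_panel(csv), "missing")
  expect_message(p <- load_panel(csv, drop_incomplete = TRUE),
                 "dropped 1 of 3")
  expect_equal(rownames(p), c("A", "C"))
  expect_equal(n_countries(p), 2L)

  writeLines(c("country,X1", "A,"), csv)
  expect_error(load_panel(csv, drop_incomplete = TRUE), "no complete rows")
  writeLines(c("nation,X1", "A,5"), csv)
  expect_error(load_panel(csv), "country column")
  expect_equal(unname(drop(unclass(load_panel(csv, country_col = "nation")))),
               5)
  writeLines(c("country,X1", "A,abc"), csv)
  expect_error(load_panel(csv), "non-numeric")
})

test_that("write_panel / load_panel round-trips bit-identically", {
  p <- random_panel(7, 4, seed = 11)
  # include awkward values: exact integers and full-precision doubles
  p[1, 1] <- 50
  p[2, 2] <- 100 / 3
  csv <- tempfile(fileext = ".csv")
  write_panel(p, csv)
  q <- load_panel(csv)
  expect_identical(unclass(q), unclass(p))
})

test_that("aggregate_mep computes the weighted sum and respects bounds", {
  p <- indicator_panel(rbind(c(10, 30), c(50, 70)))
  expect_equal(unname(aggregate_mep(p, c(0.5, 0.5))), c(20, 60))
  # unit weight vector picks out a column
  expect_equal(unname(aggregate_mep(p, c(0, 1))), unname(p[, 2]))
  # constant rows are fixed points of any aggregation
  pc <- indicator_panel(matrix(42, 1, 5))
  expect_equal(unname(aggregate_mep(pc, rep(0.2, 5))), 42)
  # named weights are aligned by indicator code
  p2 <- indicator_panel(rbind(c(10, 30)), indicator_codes = c("A", "B"))
  expect_equal(unname(aggregate_mep(p2, c(B = 1, A = 0))), 30)

  expect_error(aggregate_mep(p, c(0.5, 0.6)), "sum to 1")
  expect_error(aggregate_mep(p, c(-0.5, 1.5)), "nonnegative")
  expect_error(aggregate_mep(p, c(1, 0, 0)), "length")
})

test_that("aggregate_mep is scale-equivariant", {
  p <- random_panel(5, 3, seed = 4)
  w <- c(0.2, 0.5, 0.3)
  half <- indicator_panel(unclass(p) / 2)
  expect_equal(aggregate_mep(half, w), aggregate_mep(p, w) / 2)
})
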