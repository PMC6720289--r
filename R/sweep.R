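#' Lambda sweep of the extended goal program
#'
#' Solves the extended model over an inclusive grid of lambda values
#' (default `0, 0.01, ..., 1`, i.e. 101 solves) and summarizes the
#' resulting per-country MEP distributions.  The grid is constructed by
#' index (`lam_k = lam_start + k * step`) so that floating-point drift
#' cannot push the endpoint off 1.  All solves share one backend
#' invocation.
#'
#' @inheritParams solve_wgp
#' @param lam_start,lam_end grid endpoints, `0 <= lam_start <= lam_end <= 1`.
#' @param step positive grid spacing.
#' @return A `gp_sweep` object: list with `lam_grid`, `solutions` (one
#'   `gp_solution` per lambda), `mep` (n x n_lambda matrix of MEP values)
#'   and `mep_summary` (data.frame with per-country `min`, `q1`, `median`,
#'   `q3`, `max` across lambda; quartiles use the type-7 convention).
#' @seealso [rank_countries()], [category_weights()]
#' @export
sweep_lambda <- function(panel, config = NULL, lam_start = 0, lam_end = 1,
                         step = 0.01, solver = "highs",
                         solver_opts = list()) {
  validate_panel(panel)
  stopifnot(lam_start >= 0, lam_end <= 1, lam_start <= lam_end, step > 0)
  nsteps <- floor((lam_end - lam_start) / step + 1e-9)
  lam_grid <- lam_start + step * (0:nsteps)
  lam_grid[length(lam_grid)] <- min(lam_grid[length(lam_grid)], lam_end)
  solutions <- solve_extended_batch(panel, lam_grid, config, solver,
                                    solver_opts)
  mep <- vapply(solutions, function(s) s$mep, numeric(nrow(panel)))
  if (nrow(panel) == 1L) mep <- matrix(mep, nrow = 1L)
  rownames(mep) <- rownames(panel)
  colnames(mep) <- format(lam_grid)
  qs <- t(apply(mep, 1L, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), type = 7L, names = FALSE))
  mep_summary <- data.frame(country = rownames(panel),
                            min = qs[, 1L], q1 = qs[, 2L], median = qs[, 3L],
                            q3 = qs[, 4L], max = qs[, 5L],
                            row.names = NULL, stringsAsFactors = FALSE)
  structure(list(lam_grid = lam_grid, solutions = solutions, mep = mep,
                 mep_summary = mep_summary),
            class = "gp_sweep")
}

#' @export
print.gp_sweep <- function(x, ...) {
  cat(sprintf(
    "gp_sweep: %d lambda values in [%g, %g], %d countries, %d indicators\n",
    length(x$lam_grid), min(x$lam_grid), max(x$lam_grid),
    nrow(x$mep), length(x$solutions[[1L]]$weights)))
  zs <- vapply(x$solutions, `[[`, numeric(1L), "Z_weighted")
  ds <- vapply(x$solutions, `[[`, numeric(1L), "D")
  cat(sprintf("  Z_weighted: %s -> %s   D: %s -> %s (lambda low -> high)\n",
              format(zs[1L]), format(zs[length(zs)]),
              format(ds[1L]), format(ds[length(ds)])))
  invisible(x)
}

#' Rank countries by median MEP across the lambda sweep
#'
#' Countries are sorted by descending median MEP; exact ties are broken
#' alphabetically by country identifier.
#'
#' @param sr a [sweep_lambda()] result.
#' @return data.frame with columns `rank`, `country`, `median`, `min`,
#'   `max` (MEP in index points).
#' @export
rank_countries <- function(sr) {
  stopifnot(inherits(sr, "gp_sweep"))
  s <- sr$mep_summary
  ord <- order(-s$median, s$country)
  out <- s[ord, c("country", "median", "min", "max")]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Aggregate sweep weights by issue category
#'
#' For every lambda in the sweep, sums the estimated indicator weights over
#' the issue categories of a hierarchy (e.g. the Air Quality weight is the
#' sum of the HAD, PME and PMW weights).  Category weights sum to 1 at
#' every lambda.
#'
#' @param sr a [sweep_lambda()] result.
#' @param h a [hierarchy()] whose leaf set equals the panel's indicators.
#' @return A `gp_category_weights` object: data.frame with one row per
#'   lambda (`lam` column) and one column per category code, with the
#'   per-category min/max over lambda in attribute `"range"`.
#' @export
category_weights <- function(sr, h) {
  stopifnot(inherits(sr, "gp_sweep"))
  validate_hierarchy(h)
  codes <- names(sr$solutions[[1L]]$weights)
  if (!setequal(codes, h$indicator_code)) {
    stop("hierarchy leaves do not match the panel's indicators; missing: ",
         paste(setdiff(codes, h$indicator_code), collapse = ", "),
         " / extra: ",
         paste(setdiff(h$indicator_code, codes), collapse = ", "),
         call. = FALSE)
  }
  cat_of <- indicator_categories(h)[codes]
  cats <- unique(indicator_categories(h))
  W <- t(vapply(sr$solutions, `[[`, numeric(length(codes)), "weights"))
  agg <- vapply(cats, function(cc) {
    rowSums(W[, cat_of == cc, drop = FALSE])
  }, numeric(nrow(W)))
  if (nrow(W) == 1L) agg <- matrix(agg, nrow = 1L, dimnames = list(NULL, cats))
  out <- data.frame(lam = sr$lam_grid, agg, check.names = FALSE)
  rng <- data.frame(category = cats,
                    min = apply(agg, 2L, min),
                    max = apply(agg, 2L, max),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, range = rng, class = c("gp_category_weights", "data.frame"))
}

#' Fixed-hierarchy (EPI-style) composite score
#'
#' Applies the hierarchy's composite weights (e.g. the published EPI
#' weights, see [epi_hierarchy()]) to the panel — the conventional
#' fixed-weight benchmark against which the goal-programming scores are
#' compared.
#'
#' @param panel an [indicator_panel()].
#' @param h a [hierarchy()] whose leaf set equals the panel's indicators.
#' @param normalize if `TRUE`, scores are divided by 100 to land in
#'   \[0, 1\]; otherwise they stay on the 0-100 indicator scale.
#' @return Named numeric vector of per-country scores.
#' @export
epi_score <- function(panel, h, normalize = FALSE) {
  validate_panel(panel)
  w <- composite_weights(h)
  if (!setequal(names(w), colnames(panel))) {
    stop("hierarchy leaves do not match the panel's indicators",
         call. = FALSE)
  }
  s <- aggregate_mep(panel, w[colnames(panel)])
  if (normalize) s / 100 else s
}
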