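# Construction and solution of the goal-programming linear programs.
#
# Variable blocks (all nonnegative), for a panel with n countries and m
# indicators:
#   w    [m]      indicator weights
#   d-   [n*m]    negative deviations, column-major: index m + (j-1)*n + i
#   d+   [n*m]    positive deviations:               m + n*m + (j-1)*n + i
#   D_j  [m]      per-indicator disagreement:        m + 2*n*m + j
#   Z    [1]      total disagreement
#   D    [1]      supremum disagreement (bound by the cap rows)
#
# Equality rows:
#   goal rows (n*m):   sum_k epi_ik w_k + d-_ij - d+_ij = epi_ij
#   simplex row (1):   sum_j w_j = 1
#   accounting (m):    sum_i (d-_ij + d+_ij) - D_j = 0
#   accounting (1):    sum_j D_j - Z = 0
# Inequality rows (MINMAX / extended only, m):
#   sum_i (alpha_j d-_ij + beta_j d+_ij) - D <= 0
#
# Objectives:
#   L1 (weighted):   sum_ij (alpha_j d-_ij + beta_j d+_ij)   [= Z_weighted]
#   MINMAX:          D
#   extended(lam):   lam * Z_weighted + (1 - lam) * D

# Build the shared constraint system.  with_cap adds the MINMAX cap rows.
gp_lp_spec <- function(panel, config, with_cap) {
  n <- nrow(panel)
  m <- ncol(panel)
  nm <- n * m
  ncol_lp <- 2L * m + 2L * nm + 2L
  col_dn <- function(r) m + r                 # r = (j-1)*n + i
  col_dp <- function(r) m + nm + r
  col_Dj <- m + 2L * nm + seq_len(m)
  col_Z <- m + 2L * nm + m + 1L
  col_D <- m + 2L * nm + m + 2L
  r_all <- seq_len(nm)

  # goal rows: w block (dense in w), then the two deviation entries
  i_w <- rep(r_all, m)
  j_w <- rep(seq_len(m), each = nm)
  v_w <- as.vector(panel[rep(seq_len(n), m), ])
  i_eq <- c(i_w, r_all, r_all,
            rep(nm + 1L, m),
            rep(nm + 1L + rep(seq_len(m), each = n), 2L),
            rep(nm + 1L + seq_len(m), 1L),
            rep(nm + m + 2L, m), nm + m + 2L)
  j_eq <- c(j_w, col_dn(r_all), col_dp(r_all),
            seq_len(m),
            c(col_dn(r_all), col_dp(r_all)),
            col_Dj,
            col_Dj, col_Z)
  v_eq <- c(v_w, rep(1, nm), rep(-1, nm),
            rep(1, m),
            rep(1, 2L * nm),
            rep(-1, m),
            rep(1, m), -1)
  b_eq <- c(as.vector(panel), 1, rep(0, m), 0)

  lp <- list(ncol = ncol_lp,
             A_eq = list(i = i_eq, j = j_eq, v = v_eq),
             b_eq = b_eq,
             n = n, m = m, col_D = col_D)
  if (with_cap) {
    rj <- rep(seq_len(m), each = n)
    keep_a <- config$alpha[rj] != 0
    keep_b <- config$beta[rj] != 0
    lp$A_ub <- list(
      i = c(rj[keep_a], rj[keep_b], seq_len(m)),
      j = c(col_dn(r_all)[keep_a], col_dp(r_all)[keep_b],
            rep(col_D, m)),
      v = c(config$alpha[rj][keep_a], config$beta[rj][keep_b], rep(-1, m)))
    lp$b_ub <- rep(0, m)
  }
  lp
}

# Dense objective vector for the extended objective at a given lambda.
# lam = 1 is the pure L1 objective, lam = 0 the pure MINMAX objective.
gp_objective <- function(lp, config, lam) {
  n <- lp$n
  m <- lp$m
  cvec <- numeric(lp$ncol)
  if (lam > 0) {
    rj <- rep(seq_len(m), each = n)
    cvec[m + seq_len(n * m)] <- lam * config$alpha[rj]
    cvec[m + n * m + seq_len(n * m)] <- lam * config$beta[rj]
  }
  if (lam < 1) cvec[lp$col_D] <- 1 - lam
  cvec
}

# Turn one backend solution into a gp_solution via closed-form
# post-processing of its weight vector.
as_gp_solution <- function(panel, config, sol, lam, model, w_tol = 1e-6) {
  if (is.null(sol$status) || sol$status != 0L) {
    stop("LP solver did not return an optimal solution (status ",
         sol$status, "): ", sol$message, call. = FALSE)
  }
  m <- ncol(panel)
  w <- as.numeric(sol$x[seq_len(m)])
  if (any(w < -w_tol) || abs(sum(w) - 1) > w_tol) {
    stop(sprintf(
      "solver weight vector violates the simplex beyond tolerance %g", w_tol),
      call. = FALSE)
  }
  # clean up solver round-off, then renormalize exactly
  w <- pmax(w, 0)
  w <- w / sum(w)
  ev <- evaluate_weights(panel, w, config)
  structure(list(
    weights = stats::setNames(w, colnames(panel)),
    mep = ev$mep,
    dev_neg = ev$dev_neg,
    dev_pos = ev$dev_pos,
    disagreements = ev$disagreements,
    Z = ev$Z,
    Z_weighted = ev$Z_weighted,
    D = ev$D,
    lam = lam,
    model = model,
    config = config,
    objective = sol$objective,
    solver_status = sol$message), class = "gp_solution")
}

#' @export
print.gp_solution <- function(x, digits = 4L, ...) {
  cat(sprintf("gp_solution [%s%s]: %d countries x %d indicators\n",
              x$model,
              if (x$model == "extended") sprintf(", lambda = %g", x$lam)
              else "",
              length(x$mep), length(x$weights)))
  cat(sprintf("  Z = %s   Z_weighted = %s   D = %s\n",
              format(x$Z, digits = digits),
              format(x$Z_weighted, digits = digits),
              format(x$D, digits = digits)))
  nz <- sum(x$weights > 1e-9)
  cat(sprintf("  %d of %d indicators with nonzero weight; top weights:\n",
              nz, length(x$weights)))
  print(round(sort(x$weights, decreasing = TRUE)[seq_len(min(5L, nz))],
              digits))
  invisible(x)
}

#' Solve the weighted (L1) goal program
#'
#' Estimates indicator weights by minimizing the penalized sum of all
#' absolute deviations between each country's composite score and each of
#' its indicator scores,
#' `Z_weighted = sum_j sum_i (alpha_j d-_ij + beta_j d+_ij)`, subject to the
#' goal equations, `sum w_j = 1` and nonnegativity.  This consensus model
#' favors indicators aligned with the majority trend.
#'
#' The weight vector of a linear program need not be unique (degenerate
#' optima do occur, and zero weights are legitimate); the objective values
#' `Z_weighted`, `Z` and `D` are the canonical quantities.  Returned
#' deviations are post-processed to complementarity (`d- * d+ = 0`
#' elementwise) by re-deriving them from the weight vector in closed form.
#'
#' @param panel an [indicator_panel()].
#' @param config a [deviation_config()]; defaults to penalizing both
#'   deviation directions for every indicator.
#' @param solver LP backend name; `"highs"` (SciPy's HiGHS via the system
#'   python) is the only built-in backend.
#' @param solver_opts named list of options passed to the backend (e.g.
#'   feasibility tolerances).
#' @return A `gp_solution` with fields `weights`, `mep`, `dev_neg`,
#'   `dev_pos`, `disagreements` (D_j), `Z`, `Z_weighted`, `D`, `lam`,
#'   `model`, `config`, `objective` (raw LP optimum) and `solver_status`.
#' @seealso [solve_minmax()], [solve_extended()], [evaluate_weights()]
#' @export
solve_wgp <- function(panel, config = NULL, solver = "highs",
                      solver_opts = list()) {
  validate_panel(panel)
  config <- as_deviation_config(config, panel)
  lp <- gp_lp_spec(panel, config, with_cap = FALSE)
  sols <- lp_solve_backend(lp, list(gp_objective(lp, config, lam = 1)),
                           solver, solver_opts)
  as_gp_solution(panel, config, sols[[1L]], lam = 1, model = "wgp")
}

#' Solve the MINMAX (L-infinity) goal program
#'
#' Minimizes the supremum disagreement `D`, i.e. the largest penalized
#' deviation sum `sum_i (alpha_j d-_ij + beta_j d+_ij)` over indicators,
#' subject to the same goal equations and simplex constraint as
#' [solve_wgp()] plus the m cap rows that define `D`.  This model favors
#' the most conflicting indicators; `Z` is reported from the accounting
#' identity but is not optimized.
#'
#' @inheritParams solve_wgp
#' @return A `gp_solution`; see [solve_wgp()].
#' @export
solve_minmax <- function(panel, config = NULL, solver = "highs",
                         solver_opts = list()) {
  validate_panel(panel)
  config <- as_deviation_config(config, panel)
  lp <- gp_lp_spec(panel, config, with_cap = TRUE)
  sols <- lp_solve_backend(lp, list(gp_objective(lp, config, lam = 0)),
                           solver, solver_opts)
  as_gp_solution(panel, config, sols[[1L]], lam = 0, model = "minmax")
}

#' Solve the extended (lambda-parametric) goal program
#'
#' Minimizes the convex mix `lam * Z_weighted + (1 - lam) * D` over the
#' union of the constraints of the weighted and MINMAX models.  `lam = 1`
#' recovers the [solve_wgp()] optimum and `lam = 0` the [solve_minmax()]
#' optimum; intermediate values trade consensus against attention to the
#' most conflicting indicators.  The two terms are mixed on their natural
#' (unnormalized) scales.
#'
#' @inheritParams solve_wgp
#' @param lam mixing parameter in \[0, 1\].
#' @return A `gp_solution`; see [solve_wgp()].
#' @export
solve_extended <- function(panel, lam, config = NULL, solver = "highs",
                           solver_opts = list()) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1) {
    stop("lam must be a single number in [0, 1]", call. = FALSE)
  }
  solve_extended_batch(panel, lam, config, solver, solver_opts)[[1L]]
}

# Solve the extended model for a whole vector of lambda values with one
# backend invocation (constraints are shared; only the objective changes).
solve_extended_batch <- function(panel, lams, config = NULL,
                                 solver = "highs", solver_opts = list()) {
  validate_panel(panel)
  config <- as_deviation_config(config, panel)
  stopifnot(all(lams >= 0 & lams <= 1))
  lp <- gp_lp_spec(panel, config, with_cap = TRUE)
  objs <- lapply(lams, function(l) gp_objective(lp, config, l))
  sols <- lp_solve_backend(lp, objs, solver, solver_opts)
  out <- vector("list", length(lams))
  for (k in seq_along(lams)) {
    out[[k]] <- tryCatch(
      as_gp_solution(panel, config, sols[[k]], lam = lams[k],
                     model = "extended"),
      error = function(e) {
        stop(sprintf("lambda = %g: %s", lams[k], conditionMessage(e)),
             call. = FALSE)
      })
  }
  out
}
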