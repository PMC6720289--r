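#' Closed-form goal-programming quantities for a fixed weight vector
#'
#' For a fixed weight vector the goal equations determine every other
#' quantity without optimization: `MEP_i = sum_j w_j epi_ij`, the residual
#' `r_ij = epi_ij - MEP_i` splits into complementary deviations
#' `d-_ij = max(r_ij, 0)` and `d+_ij = max(-r_ij, 0)`, the per-indicator
#' disagreement is `D_j = sum_i (d-_ij + d+_ij)`, the total disagreement is
#' `Z = sum_j D_j`, the penalized deviation sum is
#' `Z_weighted = sum_j (alpha_j sum_i d-_ij + beta_j sum_i d+_ij)` and the
#' supremum disagreement is `D = max_j (alpha_j sum_i d-_ij +
#' beta_j sum_i d+_ij)`.  This evaluator is deterministic and solver-free;
#' the LP solvers use it to post-process their weight vectors, and the grid
#' oracle uses it to brute-force small instances.
#'
#' @param panel an [indicator_panel()].
#' @param w weight vector on the simplex (see [aggregate_mep()]).
#' @param config a [deviation_config()]; default penalizes both directions.
#' @return A list with elements `mep`, `dev_neg`, `dev_pos` (n x m),
#'   `disagreements` (named `D_j` vector), `Z`, `Z_weighted`, `D`.
#' @examples
#' p <- indicator_panel(matrix(c(10, 50, 30, 70), 2, 2))
#' ev <- evaluate_weights(p, c(0.5, 0.5))
#' ev$Z  # 40
#' ev$D  # 20
#' @export
evaluate_weights <- function(panel, w, config = NULL) {
  validate_panel(panel)
  config <- as_deviation_config(config, panel)
  w <- check_weights(w, panel)
  mep <- drop(panel %*% w)
  resid <- panel - mep          # column-wise recycling: r_ij = epi_ij - MEP_i
  dev_neg <- pmax(resid, 0)
  dev_pos <- pmax(-resid, 0)
  sn <- colSums(dev_neg)
  sp <- colSums(dev_pos)
  caps <- config$alpha * sn + config$beta * sp
  Dj <- sn + sp
  names(Dj) <- names(caps) <- colnames(panel)
  list(mep = mep, dev_neg = dev_neg, dev_pos = dev_pos,
       disagreements = Dj, Z = sum(Dj), Z_weighted = sum(caps),
       D = max(caps))
}

# Vectorized evaluation of many weight vectors at once (rows of W).
# Returns a list of numeric vectors Z_weighted, Z, D (length nrow(W)).
# Used by the grid oracle; kept internal.
evaluate_many <- function(panel, W, config) {
  mep <- tcrossprod(panel, W)               # n x g
  g <- ncol(mep)
  zw <- z <- numeric(g)
  d <- rep(-Inf, g)
  for (j in seq_len(ncol(panel))) {
    r <- panel[, j] - mep                   # n x g
    sn <- colSums(pmax(r, 0))
    sp <- colSums(pmax(-r, 0))
    cap <- config$alpha[j] * sn + config$beta[j] * sp
    zw <- zw + cap
    z <- z + sn + sp
    d <- pmax(d, cap)
  }
  list(Z_weighted = zw, Z = z, D = d)
}

#' Brute-force simplex-grid oracle
#'
#' Exhaustively evaluates [evaluate_weights()] on the lattice
#' `{w : w_j = k_j * step, sum w_j = 1}` and returns the minimizer of the
#' requested criterion.  Because the lattice is a subset of the simplex, the
#' oracle minimum is always an upper bound on the corresponding LP optimum;
#' the gap shrinks with `step`.  Intended for verification on small
#' instances only — the lattice size `choose(1/step + m - 1, m - 1)` is
#' guarded at 1e7.
#'
#' @param panel an [indicator_panel()].
#' @param step lattice spacing; `1/step` must be (nearly) integer.
#' @param config a [deviation_config()].
#' @param criterion `"Z_weighted"` (the L1 objective), `"D"` (the MINMAX
#'   objective) or `"composite"` (`lam * Z_weighted + (1 - lam) * D`).
#' @param lam mixing parameter, used only for `criterion = "composite"`.
#' @return list with `value` (best criterion value), `w` (best lattice
#'   weight vector, named), `step` and `criterion`.
#' @export
grid_oracle <- function(panel, step, config = NULL,
                        criterion = c("Z_weighted", "D", "composite"),
                        lam = NULL) {
  validate_panel(panel)
  config <- as_deviation_config(config, panel)
  criterion <- match.arg(criterion)
  if (criterion == "composite") {
    stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0, lam <= 1)
  }
  m <- ncol(panel)
  K <- round(1 / step)
  if (abs(K * step - 1) > 1e-9) {
    stop("1/step must be an integer", call. = FALSE)
  }
  size <- choose(K + m - 1, m - 1)
  if (size > 1e7) {
    stop(sprintf("simplex grid too large (%.3g points > 1e7)", size),
         call. = FALSE)
  }
  W <- simplex_lattice(K, m) / K
  ev <- evaluate_many(panel, W, config)
  val <- switch(criterion,
                Z_weighted = ev$Z_weighted,
                D = ev$D,
                composite = lam * ev$Z_weighted + (1 - lam) * ev$D)
  best <- which.min(val)
  list(value = val[best],
       w = stats::setNames(W[best, ], colnames(panel)),
       step = step, criterion = criterion)
}

# All compositions of K into m nonnegative parts, as a matrix of counts
# (rows sum to K).  Recursive on m with a vectorized two-part base case.
simplex_lattice <- function(K, m) {
  if (m == 1L) return(matrix(K, 1L, 1L))
  if (m == 2L) return(cbind(0:K, K:0, deparse.level = 0L))
  blocks <- lapply(0:K, function(k) {
    rest <- simplex_lattice(K - k, m - 1L)
    cbind(k, rest, deparse.level = 0L)
  })
  do.call(rbind, blocks)
}
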