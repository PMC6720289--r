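#' Specification for a synthetic indicator panel
#'
#' Describes a Gaussian-copula generator for country x indicator panels on
#' the 0-100 scale: a target correlation matrix controls the dependence
#' structure, and per-indicator target means and standard deviations (in
#' index points) control the marginals, which are beta-distributed (matched
#' by the method of moments) and hence bounded in \[0, 100\] with a mild
#' skew in the direction implied by the mean.  Means above 50 with large
#' spreads — the typical shape of standardized environmental indicators —
#' give left-skewed, platykurtic marginals.
#'
#' @param n_countries number of rows (>= 2).
#' @param n_indicators number of columns (>= 1).
#' @param corr target correlation matrix (m x m, symmetric, positive
#'   semidefinite, unit diagonal); default identity.
#' @param mean,sd target marginal mean / sd per indicator, recycled to
#'   length m; must satisfy `sd^2 < mean/100 * (1 - mean/100) * 100^2` (a
#'   bounded variable cannot be more dispersed than that).
#' @param country_ids,indicator_codes optional identifier vectors.
#' @param seed integer RNG seed; mandatory so that generation is
#'   reproducible by construction.
#' @return A `synth_spec` object.
#' @seealso [synth_panel()], [epi_synth_spec()]
#' @export
synth_spec <- function(n_countries, n_indicators, corr = NULL,
                       mean = 58, sd = 28,
                       country_ids = NULL, indicator_codes = NULL,
                       seed) {
  n <- as.integer(n_countries)
  m <- as.integer(n_indicators)
  if (is.na(n) || n < 2L) {
    stop("n_countries must be at least 2", call. = FALSE)
  }
  stopifnot(m >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(corr)) corr <- diag(m)
  corr <- as.matrix(corr)
  if (!isTRUE(all.equal(dim(corr), c(m, m), check.attributes = FALSE))) {
    stop("corr must be an m x m matrix", call. = FALSE)
  }
  if (max(abs(corr - t(corr))) > 1e-12 || any(abs(diag(corr) - 1) > 1e-12)) {
    stop("corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("corr is not positive semidefinite (eigenvalue %.6g)",
                 min(ev)), call. = FALSE)
  }
  mu <- rep_len(mean, m) / 100
  sg <- rep_len(sd, m) / 100
  bad <- which(sg^2 >= mu * (1 - mu))
  if (length(bad) > 0L) {
    stop("sd too large for a [0, 100]-bounded marginal at indicator ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nu <- mu * (1 - mu) / sg^2 - 1
  shape1 <- mu * nu
  shape2 <- (1 - mu) * nu
  structure(list(
    n = n, m = m, corr = corr,
    latent_corr = calibrate_latent(corr, shape1, shape2),
    shape1 = shape1, shape2 = shape2,
    mean = mu * 100, sd = sg * 100,
    country_ids = country_ids %||% sprintf("C%02d", seq_len(n)),
    indicator_codes = indicator_codes %||% sprintf("I%02d", seq_len(m)),
    seed = as.integer(seed)), class = "synth_spec")
}

# --- latent-correlation calibration --------------------------------------
#
# The beta marginal transform attenuates the Pearson correlation of the
# latent Gaussians (by a few percent for the broad marginals used here).
# To make the generated panel's correlations converge to the *target*
# matrix, each nonzero off-diagonal entry is calibrated: the map
# rho_target = g(rho_latent), with
#   g(rho) = corr( qbeta(pnorm(Z1)), qbeta(pnorm(Z2)) ),  (Z1,Z2) ~ N(0,rho)
# is evaluated by two-dimensional Gauss-Hermite quadrature and inverted by
# root finding (g is increasing and g(0) = 0).  If clipping negative
# eigenvalues of the calibrated matrix is needed it is followed by
# rescaling to unit diagonal.

# Gauss-Hermite nodes/weights (physicists'), via Golub-Welsch.
gauss_hermite <- function(k) {
  off <- sqrt(seq_len(k - 1L) / 2)
  J <- diag(0, k)
  J[cbind(seq_len(k - 1L), 2:k)] <- off
  J[cbind(2:k, seq_len(k - 1L))] <- off
  eg <- eigen(J, symmetric = TRUE)
  list(x = eg$values, w = sqrt(pi) * eg$vectors[1L, ]^2)
}

calibrate_latent <- function(corr, shape1, shape2, k = 32L) {
  m <- nrow(corr)
  off <- corr[upper.tri(corr)]
  if (all(off == 0)) return(corr)
  gh <- gauss_hermite(k)
  t_nodes <- sqrt(2) * gh$x            # E[g(Z)] = sum omega * g(t)
  omega <- gh$w / sqrt(pi)
  # standardized marginal transforms, tabulated once per indicator
  zs <- seq(-12, 12, by = 0.02)
  mu <- shape1 / (shape1 + shape2)
  sg <- sqrt(shape1 * shape2 /
               ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  f <- lapply(seq_len(m), function(j) {
    stats::splinefun(zs, (stats::qbeta(stats::pnorm(zs), shape1[j],
                                       shape2[j]) - mu[j]) / sg[j],
                     method = "monoH.FC")
  })
  fj_nodes <- lapply(f, function(fn) fn(t_nodes))
  # quadrature over the k x k node grid: rows are z1 nodes, the inner
  # integral over z2 | z1 is the matrix-vector product with omega
  attained <- function(rho, j, l) {
    s <- sqrt(max(1 - rho^2, 0))
    z2 <- outer(rho * t_nodes, s * t_nodes, `+`)
    B <- matrix(f[[l]](pmin(pmax(z2, -12), 12)), k, k)
    sum(omega * fj_nodes[[j]] * drop(B %*% omega))
  }
  latent <- corr
  for (j in seq_len(m - 1L)) {
    for (l in (j + 1L):m) {
      target <- corr[j, l]
      if (target == 0) next
      root <- tryCatch(
        stats::uniroot(function(r) attained(r, j, l) - target,
                       interval = c(-0.9999, 0.9999), tol = 1e-7),
        error = function(e) {
          stop(sprintf(
            "target correlation %.3f between indicators %d and %d is not attainable under the requested beta marginals",
            target, j, l), call. = FALSE)
        })
      latent[j, l] <- latent[l, j] <- root$root
    }
  }
  eg <- eigen(latent, symmetric = TRUE)
  if (min(eg$values) < 0) {
    v <- pmax(eg$values, 1e-10)
    latent <- eg$vectors %*% (v * t(eg$vectors))
    latent <- stats::cov2cor(latent)
  }
  latent
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "synth_spec: %d countries x %d indicators, seed %d\n", x$n, x$m, x$seed))
  off <- x$corr[upper.tri(x$corr)]
  if (length(off) > 0L) {
    cat(sprintf("  target correlations in [%.2f, %.2f]\n",
                min(off), max(off)))
  }
  invisible(x)
}

#' Generate a synthetic indicator panel
#'
#' Draws latent multivariate normals with the spec's target correlation
#' (via the eigendecomposition square root, so semidefinite targets are
#' allowed), maps them through the normal CDF to uniforms (Gaussian copula)
#' and through the per-indicator beta quantile functions to the 0-100
#' scale.  The marginal transform attenuates the attained correlations
#' slightly relative to the latent targets; empirical correlations converge
#' to (just under) the targets as n grows.  The generator restores the
#' caller's RNG state: same spec, same panel, bit for bit.
#'
#' @param spec a [synth_spec()].
#' @return An [indicator_panel()].
#' @examples
#' p <- synth_panel(synth_spec(20, 6, seed = 42))
#' range(p)  # within [0, 100]
#' @export
synth_panel <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  eg <- eigen(spec$latent_corr, symmetric = TRUE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  z <- matrix(stats::rnorm(spec$n * spec$m), spec$n, spec$m) %*% root
  u <- stats::pnorm(z)
  x <- vapply(seq_len(spec$m), function(j) {
    100 * stats::qbeta(u[, j], spec$shape1[j], spec$shape2[j])
  }, numeric(spec$n))
  x <- pmin(pmax(x, 0), 100)
  indicator_panel(x, country_ids = spec$country_ids,
                  indicator_codes = spec$indicator_codes)
}

#' Study-conditions synthetic panel specification
#'
#' The default conditions the package's analyses are exercised under: 91
#' countries x the 24 indicators of [epi_hierarchy()], marginal target
#' means and spreads set per indicator to the descriptive profile of the
#' 2018 EPI 91-country sample (means roughly 49-70 index points, sds 26-34
#' — broad, mostly left-skewed marginals), and a low-correlation dependence
#' structure (baseline 0.05) with one pronounced trade-off pair,
#' corr(UWD, WWT) = -0.49, and one pronounced synergy pair,
#' corr(TBN, PMW) = +0.48.
#'
#' @param seed integer RNG seed.
#' @return A [synth_spec()] with `n = 91`, `m = 24`.
#' @export
epi_synth_spec <- function(seed = 1L) {
  codes <- c("HAD", "PME", "PMW", "USD", "UWD", "PBD", "MPA", "TBN",
             "TBG", "SPI", "PAR", "SHI", "TCL", "FSS", "MTR", "DCT",
             "DPT", "DMT", "DNT", "DBT", "DST", "DXT", "WWT", "SNM")
  means <- c(53.95, 59.04, 58.85, 51.67, 61.46, 68.25, 60.58, 67.74,
             61.72, 48.98, 52.43, 70.36, 59.19, 57.92, 55.88, 69.43,
             58.24, 60.09, 57.32, 62.89, 66.77, 54.90, 60.22, 57.44)
  sds <- c(27.16, 33.55, 30.47, 29.88, 26.74, 26.44, 26.34, 29.60,
           27.78, 32.27, 28.78, 27.16, 29.15, 25.68, 28.47, 29.33,
           27.00, 27.75, 26.81, 29.98, 29.17, 28.39, 29.92, 28.65)
  m <- length(codes)
  corr <- matrix(0.05, m, m, dimnames = list(codes, codes))
  diag(corr) <- 1
  corr["UWD", "WWT"] <- corr["WWT", "UWD"] <- -0.49
  corr["TBN", "PMW"] <- corr["PMW", "TBN"] <- 0.48
  synth_spec(91L, m, corr = corr, mean = means, sd = sds,
             indicator_codes = codes, seed = seed)
}

#' Registry of tiny panels with analytically known answers
#'
#' Hand-constructed fixtures used to verify the solvers and the closed-form
#' evaluator against pencil-and-paper arithmetic:
#' \describe{
#'   \item{`"single_indicator"`}{n = 3, m = 1.  The single goal is exactly
#'     attainable: `w = 1`, all deviations zero, `Z = D = 0`, MEP equals
#'     the column.}
#'   \item{`"hand_2x2"`}{scores `rbind(c(10, 30), c(50, 70))`.  At
#'     `w = (0.5, 0.5)`: `MEP = (20, 60)`, `D_j = (20, 20)`, `Z = 40`,
#'     `D = 20`.}
#'   \item{`"duplicate_columns"`}{n = 4, two identical indicator columns:
#'     any simplex weights give `Z = 0` under the L1 model; MEP equals the
#'     shared column.}
#' }
#'
#' @param case_id one of the registered identifiers above.
#' @return list with elements `panel` (an [indicator_panel()]) and
#'   `expected` (named list of known quantities).
#' @export
known_answer_panel <- function(case_id) {
  switch(case_id,
    single_indicator = list(
      panel = indicator_panel(matrix(c(15, 60, 85), 3, 1),
                              country_ids = c("A", "B", "C"),
                              indicator_codes = "X1"),
      expected = list(w = 1, Z = 0, D = 0, mep = c(A = 15, B = 60, C = 85))),
    hand_2x2 = list(
      panel = indicator_panel(rbind(c(10, 30), c(50, 70)),
                              country_ids = c("A", "B"),
                              indicator_codes = c("X1", "X2")),
      expected = list(w = c(0.5, 0.5), mep = c(A = 20, B = 60),
                      disagreements = c(X1 = 20, X2 = 20), Z = 40, D = 20)),
    duplicate_columns = list(
      panel = indicator_panel(cbind(c(12, 37, 64, 90), c(12, 37, 64, 90)),
                              country_ids = c("A", "B", "C", "D"),
                              indicator_codes = c("X1", "X2")),
      expected = list(Z = 0, D = 0, mep = c(A = 12, B = 37, C = 64, D = 90))),
    stop("unknown case_id: ", case_id, call. = FALSE))
}
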