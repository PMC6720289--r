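#' Per-indicator descriptive statistics
#'
#' Mean, sample standard deviation (n-1 denominator), median, and
#' moment-based shape statistics per indicator: skewness
#' `g1 = m3 / m2^(3/2)` and excess kurtosis `g2 = m4 / m2^2 - 3`, with
#' `m_k` the population central moments (no small-sample bias adjustment;
#' a normal distribution has `g1 = g2 = 0`).  For a constant indicator the
#' sd is 0 and the shape statistics are `NaN`, with a warning.
#'
#' @param panel an [indicator_panel()] with at least 2 countries.
#' @return data.frame with columns `indicator`, `mean`, `sd`, `median`,
#'   `skewness`, `kurtosis`, one row per indicator.
#' @export
describe_panel <- function(panel) {
  validate_panel(panel)
  if (nrow(panel) < 2L) {
    stop("descriptive statistics need at least 2 countries", call. = FALSE)
  }
  m2 <- apply(panel, 2L, function(x) mean((x - mean(x))^2))
  m3 <- apply(panel, 2L, function(x) mean((x - mean(x))^3))
  m4 <- apply(panel, 2L, function(x) mean((x - mean(x))^4))
  if (any(m2 == 0)) {
    warning("constant indicator column(s): ",
            paste(colnames(panel)[m2 == 0], collapse = ", "),
            "; shape statistics are NaN", call. = FALSE)
  }
  data.frame(indicator = colnames(panel),
             mean = colMeans(panel),
             sd = apply(panel, 2L, stats::sd),
             median = apply(panel, 2L, stats::median),
             skewness = m3 / m2^1.5,
             kurtosis = m4 / m2^2 - 3,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation matrix of the indicators
#'
#' @param panel an [indicator_panel()] with at least 3 countries.  Constant
#'   columns yield `NA` correlations with a warning.
#' @return m x m symmetric matrix of Pearson coefficients with unit
#'   diagonal (for non-constant columns).
#' @export
indicator_correlations <- function(panel) {
  validate_panel(panel)
  if (nrow(panel) < 3L) {
    stop("correlations need at least 3 countries", call. = FALSE)
  }
  const <- apply(panel, 2L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant indicator column(s): ",
            paste(colnames(panel)[const], collapse = ", "),
            "; their correlations are NA", call. = FALSE)
  }
  suppressWarnings(stats::cor(unclass(panel), method = "pearson"))
}
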