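#' Deviation-penalty configuration
#'
#' Per indicator, `alpha[j] = 1` penalizes the negative deviation `d-`
#' (indicator above the composite score) and `beta[j] = 1` penalizes the
#' positive deviation `d+` (indicator below it).  Setting one of them to 0
#' leaves that direction unpenalized — useful when only over- or only
#' under-achievement of an indicator is unwanted.  At least one direction
#' must be penalized for every indicator, otherwise its deviations would be
#' costless and the disagreement accounting meaningless.
#'
#' The default (all ones) penalizes both directions symmetrically; under it
#' the optimized deviation sum equals the total disagreement Z.
#'
#' @param m number of indicators.
#' @param alpha,beta vectors of 0/1 penalties, recycled to length `m`.
#' @return A `deviation_config` object (list with `alpha` and `beta`).
#' @export
deviation_config <- function(m, alpha = 1, beta = 1) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  alpha <- as.numeric(rep_len(alpha, m))
  beta <- as.numeric(rep_len(beta, m))
  if (!all(alpha %in% c(0, 1)) || !all(beta %in% c(0, 1))) {
    stop("alpha and beta entries must be 0 or 1", call. = FALSE)
  }
  bad <- which(alpha + beta < 1)
  if (length(bad) > 0L) {
    stop("alpha + beta must be >= 1 for every indicator; violated at index ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "deviation_config")
}

#' @export
print.deviation_config <- function(x, ...) {
  cat(sprintf("deviation_config (m = %d): alpha = [%s], beta = [%s]\n",
              length(x$alpha), paste(x$alpha, collapse = " "),
              paste(x$beta, collapse = " ")))
  invisible(x)
}

# Coerce/validate a config against a panel.
as_deviation_config <- function(config, panel) {
  if (is.null(config)) return(deviation_config(ncol(panel)))
  if (!inherits(config, "deviation_config")) {
    stop("config must be created by deviation_config()", call. = FALSE)
  }
  if (length(config$alpha) != ncol(panel)) {
    stop(sprintf("deviation_config length %d != number of indicators %d",
                 length(config$alpha), ncol(panel)), call. = FALSE)
  }
  config
}
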