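#' Indicator panel: countries x standardized environmental indicators
#'
#' An `indicator_panel` holds a complete n x m matrix of indicator scores on
#' a 0-100 scale, one row per country and one column per indicator.  Scores
#' are assumed to be already standardized (as in the Environmental
#' Performance Index report); this package never transforms raw data.
#'
#' @param scores numeric matrix (or object coercible to one) of scores in
#'   \[0, 100\], with no missing values.
#' @param country_ids character vector of unique country identifiers, one
#'   per row.  Defaults to `rownames(scores)`.
#' @param indicator_codes character vector of unique indicator codes
#'   (conventionally three-letter acronyms such as `"HAD"`), one per column.
#'   Defaults to `colnames(scores)`.
#'
#' @return An object of class `indicator_panel`: a numeric matrix with
#'   `dimnames = list(country_ids, indicator_codes)`.
#' @examples
#' p <- indicator_panel(matrix(c(10, 50, 30, 70), 2, 2),
#'                      country_ids = c("A", "B"),
#'                      indicator_codes = c("X1", "X2"))
#' n_countries(p)
#' @export
indicator_panel <- function(scores, country_ids = rownames(scores),
                            indicator_codes = colnames(scores)) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (nrow(scores) < 1L || ncol(scores) < 1L) {
    stop("panel must have at least one country and one indicator",
         call. = FALSE)
  }
  if (is.null(country_ids)) {
    country_ids <- paste0("country", seq_len(nrow(scores)))
  }
  if (is.null(indicator_codes)) {
    indicator_codes <- paste0("ind", seq_len(ncol(scores)))
  }
  dimnames(scores) <- list(as.character(country_ids),
                           as.character(indicator_codes))
  class(scores) <- c("indicator_panel", "matrix", "array")
  validate_panel(scores)
  scores
}

#' Validate an indicator panel
#'
#' Checks the panel invariants: numeric, complete (no `NA`), all scores
#' finite and within \[0, 100\], at least one row and column, and unique
#' country and indicator identifiers.  Called by [indicator_panel()] and by
#' every operation that consumes a panel.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending row/column.
#' @export
validate_panel <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("panel scores must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("panel must have at least one country and one indicator",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate country identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate indicator codes: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(x) | x < 0 | x > 100, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "score out of [0, 100] or missing at country '%s', indicator '%s' (%s)",
      rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]],
      format(x[bad[1L, , drop = FALSE]])), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("indicator_panel: %d countries x %d indicators (0-100 scale)\n",
              nrow(x), ncol(x)))
  cat("indicators:", paste(colnames(x), collapse = " "), "\n")
  cat(sprintf("score range: [%.2f, %.2f]\n", min(x), max(x)))
  invisible(x)
}

#' Number of countries / indicators in a panel
#' @param panel an [indicator_panel()].
#' @return integer count.
#' @export
n_countries <- function(panel) nrow(panel)

#' @rdname n_countries
#' @export
n_indicators <- function(panel) ncol(panel)

#' Read an indicator panel from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row, one country
#' identifier column (default name `"country"`) and one numeric column per
#' indicator, decimal point `.`, no thousands separators.
#'
#' @param path path to the CSV file.
#' @param drop_incomplete if `TRUE`, rows containing any missing indicator
#'   value are dropped (the count of dropped rows is reported via
#'   `message()`); if `FALSE` (default) missing values are a validation
#'   error.
#' @param country_col name of the country-identifier column.
#' @return An [indicator_panel()].
#' @seealso [write_panel()] for the inverse operation.
#' @export
load_panel <- function(path, drop_incomplete = FALSE,
                       country_col = "country") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!country_col %in% names(df)) {
    stop(sprintf("country column '%s' not found (columns: %s)",
                 country_col, paste(names(df), collapse = ", ")),
         call. = FALSE)
  }
  ids <- as.character(df[[country_col]])
  df <- df[setdiff(names(df), country_col)]
  if (ncol(df) < 1L) stop("no indicator columns found", call. = FALSE)
  # an entirely empty numeric column is read as logical NA; keep it numeric
  df[] <- lapply(df, function(col) {
    if (is.logical(col) && all(is.na(col))) as.numeric(col) else col
  })
  not_num <- names(df)[!vapply(df, is.numeric, logical(1L))]
  if (length(not_num) > 0L) {
    stop("non-numeric indicator column(s): ",
         paste(not_num, collapse = ", "), call. = FALSE)
  }
  scores <- as.matrix(df)
  if (drop_incomplete) {
    keep <- stats::complete.cases(scores)
    if (sum(!keep) > 0L) {
      message(sprintf("load_panel: dropped %d of %d rows with missing values",
                      sum(!keep), nrow(scores)))
    }
    scores <- scores[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (nrow(scores) == 0L) {
    stop("no complete rows left in panel", call. = FALSE)
  }
  indicator_panel(scores, country_ids = ids)
}

#' Write an indicator panel to CSV
#'
#' Emits the dialect read by [load_panel()]: header row, first column
#' `country`, one column per indicator code.  Full double precision is kept
#' so that `load_panel(write_panel(p))` round-trips bit-identically.
#'
#' @param panel an [indicator_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  df <- data.frame(country = rownames(panel), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in colnames(panel)) df[[j]] <- format(panel[, j], digits = 17L,
                                               trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate indicator scores into a composite score
#'
#' Computes the weighted sum `score_i = sum_j w_j * epi_ij` for each
#' country.  With goal-programming-estimated weights this is the country's
#' Multicriteria Environmental Performance (MEP); with the fixed hierarchy
#' weights it is the EPI-style score.
#'
#' @param panel an [indicator_panel()].
#' @param w numeric weight vector of length `n_indicators(panel)`,
#'   nonnegative and summing to 1 (tolerance `1e-9`).  If named, names must
#'   match the panel's indicator codes (any order).
#' @return Named numeric vector of per-country scores.  Each value lies
#'   within the range of that country's own indicator scores (convex
#'   combination), hence in \[0, 100\].
#' @examples
#' p <- indicator_panel(matrix(c(10, 50, 30, 70), 2, 2))
#' aggregate_mep(p, c(0.5, 0.5))  # c(20, 60)
#' @export
aggregate_mep <- function(panel, w) {
  validate_panel(panel)
  w <- check_weights(w, panel)
  drop(panel %*% w)
}

# Check a weight vector against the simplex precondition and align it with
# the panel's indicator order.  Returns the aligned unnamed-ok numeric vector.
check_weights <- function(w, panel, tol = 1e-9) {
  if (!is.numeric(w)) stop("weights must be numeric", call. = FALSE)
  if (length(w) != ncol(panel)) {
    stop(sprintf("weight length %d != number of indicators %d",
                 length(w), ncol(panel)), call. = FALSE)
  }
  if (!is.null(names(w))) {
    if (!setequal(names(w), colnames(panel))) {
      stop("weight names do not match panel indicator codes", call. = FALSE)
    }
    w <- w[colnames(panel)]
  }
  if (any(w < -tol)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(w) - 1) > tol) {
    stop(sprintf("weights must sum to 1 (got %.12f)", sum(w)), call. = FALSE)
  }
  w
}
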