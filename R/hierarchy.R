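#' Weighted indicator hierarchy (policy objective > issue category > indicator)
#'
#' A `gp_hierarchy` is the three-level weighted tree used by EPI-style
#' composite indices: policy objectives carry relative weights that sum to 1;
#' the issue categories under each objective carry relative weights that sum
#' to 1; and the indicators under each category likewise.  The product of
#' the three relative weights along a root-to-leaf path is the indicator's
#' composite weight (see [composite_weights()]).
#'
#' @param x a data.frame with one row per indicator (leaf) and columns
#'   `objective`, `objective_code`, `objective_weight`, `category`,
#'   `category_code`, `category_weight`, `indicator`, `indicator_code`,
#'   `indicator_weight`.  Weight columns accept either fractions (`0.4`) or
#'   percentage strings (`"40%"`); both are normalized to fractions.
#' @return A `gp_hierarchy` object (the normalized data.frame).
#' @seealso [epi_hierarchy()] for the built-in 2018 EPI structure,
#'   [load_hierarchy()] to read one from YAML.
#' @export
hierarchy <- function(x) {
  need <- c("objective", "objective_code", "objective_weight",
            "category", "category_code", "category_weight",
            "indicator", "indicator_code", "indicator_weight")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("hierarchy is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  h <- as.data.frame(x)[need]
  for (col in grep("_weight$", need, value = TRUE)) {
    h[[col]] <- parse_weight(h[[col]])
  }
  class(h) <- c("gp_hierarchy", "data.frame")
  validate_hierarchy(h)
  h
}

# "40%" -> 0.40; numerics pass through.
parse_weight <- function(w) {
  if (is.numeric(w)) return(as.numeric(w))
  w <- trimws(as.character(w))
  pct <- grepl("%$", w)
  out <- suppressWarnings(as.numeric(sub("%$", "", w)))
  if (anyNA(out)) {
    stop("unparseable weight(s): ", paste(w[is.na(out)], collapse = ", "),
         call. = FALSE)
  }
  out[pct] <- out[pct] / 100
  out
}

#' Validate a hierarchy
#'
#' Checks that sibling relative weights sum to 1 at every level (tolerance
#' `1e-9`), that all weights lie in \[0, 1\] and that leaf indicator codes
#' are unique.
#'
#' @param h a [hierarchy()].
#' @param tol tolerance on each sum-to-one check.
#' @return `h`, invisibly.
#' @export
validate_hierarchy <- function(h, tol = 1e-9) {
  wcols <- c("objective_weight", "category_weight", "indicator_weight")
  for (col in wcols) {
    if (any(h[[col]] < 0 | h[[col]] > 1)) {
      stop(col, " outside [0, 1]", call. = FALSE)
    }
  }
  if (anyDuplicated(h$indicator_code)) {
    stop("duplicate indicator code(s): ",
         paste(unique(h$indicator_code[duplicated(h$indicator_code)]),
               collapse = ", "), call. = FALSE)
  }
  obj <- h[!duplicated(h$objective_code), ]
  if (abs(sum(obj$objective_weight) - 1) > tol) {
    stop(sprintf("objective weights sum to %.12f, not 1",
                 sum(obj$objective_weight)), call. = FALSE)
  }
  for (oc in obj$objective_code) {
    rows <- h[h$objective_code == oc, ]
    cats <- rows[!duplicated(rows$category_code), ]
    if (abs(sum(cats$category_weight) - 1) > tol) {
      stop(sprintf("category weights under objective '%s' sum to %.12f, not 1",
                   oc, sum(cats$category_weight)), call. = FALSE)
    }
    for (cc in cats$category_code) {
      leaves <- rows[rows$category_code == cc, ]
      if (abs(sum(leaves$indicator_weight) - 1) > tol) {
        stop(sprintf(
          "indicator weights under category '%s' sum to %.12f, not 1",
          cc, sum(leaves$indicator_weight)), call. = FALSE)
      }
    }
  }
  invisible(h)
}

#' @export
print.gp_hierarchy <- function(x, ...) {
  cat(sprintf(
    "gp_hierarchy: %d objectives, %d issue categories, %d indicators\n",
    length(unique(x$objective_code)), length(unique(x$category_code)),
    nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Composite per-indicator weights of a hierarchy
#'
#' The composite weight of each indicator is the product of the relative
#' weights along its root-to-leaf path (objective x category x indicator).
#' Composite weights sum to 1 across all indicators.
#'
#' @param h a [hierarchy()].
#' @return Named numeric vector, one entry per indicator code, in hierarchy
#'   order.
#' @examples
#' w <- composite_weights(epi_hierarchy())
#' w[["HAD"]]  # 0.40 * 0.65 * 0.40 = 0.104
#' @export
composite_weights <- function(h) {
  validate_hierarchy(h)
  w <- h$objective_weight * h$category_weight * h$indicator_weight
  names(w) <- h$indicator_code
  stopifnot(abs(sum(w) - 1) <= 1e-9)
  w
}

#' Issue-category membership of each indicator
#'
#' @param h a [hierarchy()].
#' @return Named character vector mapping indicator code to issue-category
#'   code.
#' @export
indicator_categories <- function(h) {
  stats::setNames(h$category_code, h$indicator_code)
}

#' The 2018 Environmental Performance Index hierarchy
#'
#' The fixed weighting scheme of the 2018 EPI report: 2 policy objectives
#' (Environmental Health 40%, Ecosystem Vitality 60%), 10 issue categories
#' and 24 indicators, with the published relative weights.  Composite
#' weights derived from it range from 10.4% (Household Solid Fuels, HAD)
#' down to 0.9% (N2O and Black Carbon emissions).
#'
#' @return A [hierarchy()] with 24 leaves.
#' @export
epi_hierarchy <- function() {
  r <- function(obj, oc, ow, cat, cc, cw, ind, ic, iw) {
    data.frame(objective = obj, objective_code = oc, objective_weight = ow,
               category = cat, category_code = cc, category_weight = cw,
               indicator = ind, indicator_code = ic, indicator_weight = iw,
               stringsAsFactors = FALSE)
  }
  hlt <- list(
    r("Environmental Health", "HLT", 0.40, "Air Quality", "AIR", 0.65,
      "Household Solid Fuels", "HAD", 0.40),
    r("Environmental Health", "HLT", 0.40, "Air Quality", "AIR", 0.65,
      "PM2.5 Exposure", "PME", 0.30),
    r("Environmental Health", "HLT", 0.40, "Air Quality", "AIR", 0.65,
      "PM2.5 Exceedance", "PMW", 0.30),
    r("Environmental Health", "HLT", 0.40, "Water & Sanitation", "H2O", 0.30,
      "Drinking Water", "UWD", 0.50),
    r("Environmental Health", "HLT", 0.40, "Water & Sanitation", "H2O", 0.30,
      "Sanitation", "USD", 0.50),
    r("Environmental Health", "HLT", 0.40, "Heavy Metals", "HMT", 0.05,
      "Lead Exposure", "PBD", 1.00))
  eco <- list(
    r("Ecosystem Vitality", "ECO", 0.60, "Biodiversity & Habitat", "BDH", 0.25,
      "Marine Protected Areas", "MPA", 0.20),
    r("Ecosystem Vitality", "ECO", 0.60, "Biodiversity & Habitat", "BDH", 0.25,
      "Biome Protection (National)", "TBN", 0.20),
    r("Ecosystem Vitality", "ECO", 0.60, "Biodiversity & Habitat", "BDH", 0.25,
      "Biome Protection (Global)", "TBG", 0.20),
    r("Ecosystem Vitality", "ECO", 0.60, "Biodiversity & Habitat", "BDH", 0.25,
      "Species Protection Index", "SPI", 0.20),
    r("Ecosystem Vitality", "ECO", 0.60, "Biodiversity & Habitat", "BDH", 0.25,
      "Representativeness Index", "PAR", 0.10),
    r("Ecosystem Vitality", "ECO", 0.60, "Biodiversity & Habitat", "BDH", 0.25,
      "Species Habitat Index", "SHI", 0.10),
    r("Ecosystem Vitality", "ECO", 0.60, "Forests", "FOR", 0.10,
      "Tree Cover Loss", "TCL", 1.00),
    r("Ecosystem Vitality", "ECO", 0.60, "Fisheries", "FSH", 0.10,
      "Fish Stock Status", "FSS", 0.50),
    r("Ecosystem Vitality", "ECO", 0.60, "Fisheries", "FSH", 0.10,
      "Regional Marine Trophic Index", "MTR", 0.50),
    r("Ecosystem Vitality", "ECO", 0.60, "Climate & Energy", "CCE", 0.30,
      "CO2 Emissions - Total", "DCT", 0.50),
    r("Ecosystem Vitality", "ECO", 0.60, "Climate & Energy", "CCE", 0.30,
      "CO2 Emissions - Power", "DPT", 0.20),
    r("Ecosystem Vitality", "ECO", 0.60, "Climate & Energy", "CCE", 0.30,
      "Methane Emissions", "DMT", 0.20),
    r("Ecosystem Vitality", "ECO", 0.60, "Climate & Energy", "CCE", 0.30,
      "N2O Emissions", "DNT", 0.05),
    r("Ecosystem Vitality", "ECO", 0.60, "Climate & Energy", "CCE", 0.30,
      "Black Carbon Emissions", "DBT", 0.05),
    r("Ecosystem Vitality", "ECO", 0.60, "Air Pollution", "APE", 0.10,
      "SO2 Emissions", "DST", 0.50),
    r("Ecosystem Vitality", "ECO", 0.60, "Air Pollution", "APE", 0.10,
      "NOX Emissions", "DXT", 0.50),
    r("Ecosystem Vitality", "ECO", 0.60, "Water Resources", "WRS", 0.10,
      "Wastewater Treatment", "WWT", 1.00),
    r("Ecosystem Vitality", "ECO", 0.60, "Agriculture", "AGR", 0.05,
      "Sustainable Nitrogen Management", "SNM", 1.00))
  hierarchy(do.call(rbind, c(hlt, eco)))
}

#' Read a hierarchy from a YAML file
#'
#' The file mirrors the three levels with `name`, `code`, `weight` per node:
#' a top-level `objectives:` list, each objective holding `categories:`,
#' each category holding `indicators:`.  Weights may be fractions or
#' percentage strings.
#'
#' @param path path to the YAML file.
#' @return A [hierarchy()].
#' @examples
#' path <- system.file("extdata", "epi2018_hierarchy.yaml", package = "gpmep")
#' h <- load_hierarchy(path)
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$objectives)) {
    stop("hierarchy YAML must have a top-level 'objectives' list",
         call. = FALSE)
  }
  rows <- list()
  for (obj in y$objectives) {
    for (cat in obj$categories) {
      for (ind in cat$indicators) {
        rows[[length(rows) + 1L]] <- data.frame(
          objective = obj$name, objective_code = obj$code,
          objective_weight = parse_weight(obj$weight),
          category = cat$name, category_code = cat$code,
          category_weight = parse_weight(cat$weight),
          indicator = ind$name, indicator_code = ind$code,
          indicator_weight = parse_weight(ind$weight),
          stringsAsFactors = FALSE)
      }
    }
  }
  hierarchy(do.call(rbind, rows))
}
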