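# Sparse-LP bridge.
#
# The goal programs are plain linear programs; they are handed, in sparse
# triplet form, to the HiGHS solver of the system Python's SciPy through
# inst/python/lp_solve.py.  Only generic LP solving crosses the bridge —
# model construction and all post-processing stay in R.  Constraints are
# shared across any number of objective vectors so that a lambda sweep costs
# a single interpreter start-up.

# Locate the python interpreter.  Overridable via options(gpmep.python=) or
# the GPMEP_PYTHON environment variable.
find_python <- function() {
  cand <- getOption("gpmep.python", Sys.getenv("GPMEP_PYTHON", ""))
  if (!nzchar(cand)) cand <- Sys.which("python")
  if (!nzchar(cand)) cand <- Sys.which("python3")
  if (!nzchar(cand)) {
    stop("no python interpreter found; the LP backend needs python with ",
         "scipy on the PATH (or set options(gpmep.python=))", call. = FALSE)
  }
  unname(cand)
}

# Solve one LP per objective vector under shared constraints.
#
# lp: list with ncol, A_eq/b_eq, optionally A_ub/b_ub, where each A_* is a
#     list(i =, j =, v =) of 1-based triplets.
# objectives: list of dense cost vectors (length ncol each).
# Returns a list (one element per objective) of list(status, message,
# objective, x).
lp_solve_backend <- function(lp, objectives, solver = "highs",
                             solver_opts = list()) {
  if (!identical(solver, "highs")) {
    stop(sprintf("unknown solver backend '%s' (available: highs)", solver),
         call. = FALSE)
  }
  opts <- utils::modifyList(
    list(primal_feasibility_tolerance = 1e-9,
         dual_feasibility_tolerance = 1e-9),
    solver_opts)
  payload <- list(
    ncol = lp$ncol,
    A_eq = list(i = lp$A_eq$i - 1L, j = lp$A_eq$j - 1L, v = lp$A_eq$v),
    b_eq = lp$b_eq,
    objectives = objectives,
    options = opts)
  if (!is.null(lp$A_ub)) {
    payload$A_ub <- list(i = lp$A_ub$i - 1L, j = lp$A_ub$j - 1L,
                         v = lp$A_ub$v)
    payload$b_ub <- lp$b_ub
  }
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = TRUE,
                       null = "null")
  script <- system.file("python", "lp_solve.py", package = "gpmep",
                        mustWork = TRUE)
  status <- suppressWarnings(
    system2(find_python(), c(shQuote(script), shQuote(fin), shQuote(fout)),
            stdout = TRUE, stderr = TRUE))
  if (!file.exists(fout)) {
    stop("LP backend failed: ", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  res$solutions
}
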