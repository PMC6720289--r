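Package: gpmep
Title: Goal-Programming Weights for Multicriteria Environmental Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective weighting and aggregation of standardized environmental
    performance indicators into a single Multicriteria Environmental
    Performance (MEP) score per country via goal programming.  Implements the
    weighted (L1) model, the MINMAX (L-infinity) model and the extended
    lambda-parametric compromise between them as linear programs with
    deviation variables, a lambda-sweep sensitivity analysis with
    median-based country ranking, issue-category weight aggregation, the
    fixed-hierarchy EPI-style comparison score, per-indicator descriptive
    statistics and correlations, and a Gaussian-copula synthetic panel
    generator for testing.  Linear programs are solved with the HiGHS solver
    through the SciPy installation of the system Python.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    quantreg,
    e1071,
    optparse
SystemRequirements: Python (>= 3.8) with SciPy (scipy.optimize.linprog,
    HiGHS) available on the PATH as 'python' or 'python3'.
Config/testthat/edition: 3
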