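# gpmep — goal-programming weights for multicriteria environmental performance

Composite environmental indices such as the Environmental Performance Index
(EPI) rank countries by aggregating standardized indicator scores with a
fixed, expert-chosen weighting hierarchy.  Those weights are one defensible
choice among many, and they ignore the correlation structure among
indicators: positively aligned indicators get double-counted, conflicting
ones get washed out.  `gpmep` is for researchers and index builders who want
the weights determined *objectively from the data*: it estimates indicator
weights by goal programming and aggregates them into a single Multicriteria
Environmental Performance (MEP) score per country, together with a
sensitivity analysis over the whole family of compromise models.

## The model

Let `epi_ij` be the score of country `i` (of `n`) on indicator `j` (of
`m`), standardized to 0–100, and let `w` be nonnegative weights with
`Σ_j w_j = 1`.  The composite score is `MEP_i = Σ_j w_j · epi_ij`.  Each
country × indicator pair gets a goal equation with deviation variables
`d⁻_ij, d⁺_ij ≥ 0`:

```
Σ_k w_k epi_ik + d⁻_ij − d⁺_ij = epi_ij        i = 1..n, j = 1..m
```

so `d⁻_ij − d⁺_ij = epi_ij − MEP_i`.  Per-indicator disagreement is
`D_j = Σ_i (d⁻_ij + d⁺_ij)`, the total is `Z = Σ_j D_j`, and binary
switches `α_j, β_j` select which deviation direction is penalized
(`Z_weighted = Σ_j Σ_i α_j d⁻_ij + β_j d⁺_ij`; by default both are).
Three linear programs share these constraints:

* **Weighted (L1) model** — `min Z_weighted`: a consensus solution aligned
  with the majority trend of the indicators (`solve_wgp()`);
* **MINMAX (L∞) model** — `min D` with `Σ_i α_j d⁻_ij + β_j d⁺_ij ≤ D`:
  protects the most conflicting indicators (`solve_minmax()`);
* **Extended model** — `min λ·Z_weighted + (1−λ)·D`, `λ ∈ [0,1]`, which
  recovers the L1 model at `λ = 1` and the MINMAX model at `λ = 0`
  (`solve_extended()`).

Sweeping λ (`sweep_lambda()`, by default 101 values) yields a *range* of
MEP values per country rather than a single crisp number; countries are
ranked by their median MEP (`rank_countries()`), weights are aggregated to
issue categories (`category_weights()`), and the fixed-hierarchy EPI-style
score (`epi_score()`, weights from `epi_hierarchy()` or a YAML file via
`load_hierarchy()`) serves as the conventional benchmark.  Descriptive
statistics and indicator correlations (`describe_panel()`,
`indicator_correlations()`) characterize the input panel, and a
Gaussian-copula generator (`synth_spec()` / `synth_panel()`) produces
0–100-scaled test panels with controlled correlation structure and skewed
marginals.

## Installation and requirements

```sh
R CMD INSTALL .
```

The linear programs are solved with HiGHS through the SciPy installation of
the system `python` (override with `options(gpmep.python = ...)` or
`GPMEP_PYTHON`).  R-side dependencies are `jsonlite` and `yaml`;
`quantreg`, `e1071`, `withr` and `optparse` are used only by the tests and
the command-line front end.  Run the tests with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "gpmep", load_package = "installed")'
```

## Worked example

```r
library(gpmep)

panel <- synth_panel(epi_synth_spec(seed = 1))   # 91 countries x 24 indicators
sol <- solve_wgp(panel)
sol
#> gp_solution [wgp]: 91 countries x 24 indicators
#>   Z = 52463   Z_weighted = 52463   D = 2616
#>   22 of 24 indicators with nonzero weight; top weights:
#>    DMT    DCT    USD    TBG    DST
#> 0.1030 0.0991 0.0732 0.0725 0.0666
```

`Z = 52463` is the total absolute disagreement (in index points) between
the fitted composite and all 91 × 24 indicator scores; the L1 model spreads
weight over 22 indicators, led by methane (`DMT`) and total CO2 (`DCT`)
emissions.  Two indicators receive zero weight — a normal outcome of
goal-programming estimation for indicators whose information is already
carried by correlated ones.  A λ sweep shows the consensus/conflict
trade-off and the induced ranking:

```r
sw <- sweep_lambda(panel, step = 0.1)
sw
#> gp_sweep: 11 lambda values in [0, 1], 91 countries, 24 indicators
#>   Z_weighted: 53473.63 -> 52463.05   D: 2298.115 -> 2615.895 (lambda low -> high)
head(rank_countries(sw), 3)
#>   rank country   median      min      max
#> 1    1     C33 80.33843 78.95840 85.95488
#> 2    2     C31 78.60638 77.92441 81.65206
#> 3    3     C47 77.37245 76.13400 78.46522
```

As λ rises, total disagreement `Z_weighted` falls (the consensus objective
takes over) while the worst-case disagreement `D` rises — the two models
genuinely trade off.  Each country's MEP is reported as a distribution over
λ (`min`/`median`/`max` above), so the ranking's stability is visible at a
glance.

A thin command-line front end over the same functions ships in
`inst/cli/gpmep.R` (`solve`, `sweep`, `rank`, `epi-score`, `describe`,
`synth` subcommands).

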