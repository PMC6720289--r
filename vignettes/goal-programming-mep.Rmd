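---
title: "Goal-programming estimation of composite environmental performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-programming estimation of composite environmental performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Composite indices of environmental performance aggregate many standardized
indicators (0–100 index points each) into one score per country.  The
aggregation weights are the contentious part: fixed expert weights embody a
single judgement and ignore how the indicators co-move.  `gpmep` instead
estimates the weights from the data by goal programming: the composite
score `MEP_i = Σ_j w_j epi_ij` is asked to be *simultaneously close to
every indicator*, and the weights are whatever simplex point makes that
tension smallest.

For every country–indicator pair a goal equation introduces nonnegative
deviation variables,

    Σ_k w_k epi_ik + d⁻_ij − d⁺_ij = epi_ij ,

so that `d⁻_ij − d⁺_ij = epi_ij − MEP_i` measures how far indicator `j`
sits above (`d⁻`) or below (`d⁺`) the composite for country `i`.  Summing
deviations per indicator gives the disagreement `D_j`, summing those gives
the total `Z`, and the largest penalized per-indicator sum is the supremum
disagreement `D`.  Three linear programs over `(w, d⁻, d⁺)` are provided:

* the **weighted (L1) model** minimizes
  `Z_weighted = Σ_j (α_j Σ_i d⁻_ij + β_j Σ_i d⁺_ij)` — a consensus
  solution that rewards agreement with the majority trend;
* the **MINMAX (L∞) model** minimizes `D` subject to
  `Σ_i (α_j d⁻_ij + β_j d⁺_ij) ≤ D` for every `j` — a protective solution
  driven by the most conflicting indicators;
* the **extended model** minimizes `λ·Z_weighted + (1−λ)·D` over the union
  of both constraint sets.

The two objective terms are mixed on their natural scales, without
normalization.  The display form of the compromise objective admits either
convention; the unnormalized form is the one under which the two stated
limit equivalences hold exactly — at `λ = 1` the `D` column has zero cost
and the program *is* the L1 model, at `λ = 0` the deviation costs vanish
and it *is* the MINMAX model — and it produces the expected monotone
trade-off (nonincreasing `Z_weighted`, nondecreasing `D` in `λ`), which the
test suite asserts.  Because `Z` is roughly `m` times the size of `D`, the
consensus term dominates for most of the λ range; that asymmetry is a
property of the model family, not an artifact.

## Tunable parameters

* `lam` (λ, dimensionless, in [0,1]): the consensus/conflict compromise.
  Default grid for `sweep_lambda()`: 0 to 1 in steps of 0.01 (101 solves),
  built by index (`λ_k = k·step`) so repeated addition cannot drift the
  endpoint off 1.
* `alpha`, `beta` (per indicator, binary): which deviation direction is
  unwanted.  Default all ones — both directions penalized, under which
  `Z_weighted = Z` identically.  `α_j = β_j = 0` is rejected at
  construction: it would make indicator `j`'s deviations costless and the
  disagreement accounting meaningless.
* Weight-sum tolerances: `1e-9` for validating user-supplied weight
  vectors (exact arithmetic is expected there), `1e-6` for accepting
  solver output (interior-point solutions satisfy the simplex only
  approximately).  Accepted solver weights are clipped at zero and
  renormalized before any reported quantity is computed.

## Solving and post-processing

The models are ordinary sparse linear programs (for 91 × 24 input:
4 418 variables, 2 210 equality rows, 24 cap rows).  They are handed in
triplet form to the HiGHS solver via the system Python's SciPy; only
generic LP solving crosses that bridge, with primal/dual feasibility
tolerances of `1e-9`.  All model construction and everything downstream of
the optimal weight vector stays in R: deviations, disagreements, `Z`,
`Z_weighted` and `D` are recomputed *in closed form* from `w`
(`evaluate_weights()`), which automatically enforces the complementarity
`d⁻_ij · d⁺_ij = 0` (an optimal basis never carries both, but a solver may
return an equivalent non-complementary split) and makes the accounting
identities `Z = Σ_j D_j` and `MEP_i ∈ [min_j epi_ij, max_j epi_ij]` exact
rather than approximate.  The closed-form objective is checked against the
LP optimum on every solve in the test suite (tolerance `1e-6`).

A λ sweep shares one backend invocation for all grid points, since only
the objective vector changes.  Re-running a sweep is bit-reproducible:
there is no randomness anywhere in the solve path.

**Degeneracy.**  The optimal *value* of each program is unique; the
optimal *weight vector* need not be.  Panels with strongly correlated
indicators produce flat faces, and zero weights are a routine outcome.
The package therefore treats `Z_weighted` and `D` as the canonical
quantities, reports whichever optimal basic solution the solver returns,
and makes no uniqueness claim for `w`; the verification suite compares
objective values, never weight vectors, except where a published weight
table is itself the target.

**Verification oracle.**  `grid_oracle()` enumerates the simplex lattice
`{w : w_j = k_j·step}` and minimizes the closed-form criterion by brute
force (guarded at 10⁷ lattice points).  The lattice is a subset of the
simplex, so the oracle can never beat the LP; the gap shrinks as the step
does.  The converse — how close the lattice gets to the LP — is limited by
resolution: with step `s` the best lattice point can sit `O(s)` away in
`‖·‖₁`, and the piecewise-linear objectives have slopes of order
`n · max(epi)` in `w`, so gaps of order `10⁻³`–`10⁻²` at `s = 0.001` are
the expected behavior whenever the optimum is interior, not a solver
deficiency.  Vertex optima (`w = e_j`, common on small uncorrelated
panels) give exactly zero gap.  An independent cross-check solves the L1
model as simplex-constrained median regression (`quantreg`) on one test
panel.

## Ranking, categories, and the fixed-weight benchmark

Countries are ranked by the median of their MEP values across the λ grid;
exact ties (which the sweep itself essentially never produces, but the
contract covers) break alphabetically by country identifier.  Distribution
summaries use type-7 quantiles — the convention choice affects only the
box edges of a summary, never the median ordering.  Issue-category weights
are the sums of member-indicator weights per λ.  The fixed-hierarchy score
applies composite weights — products of the relative weights along each
objective → category → indicator path, as in the 2018 EPI report whose
hierarchy ships both built-in (`epi_hierarchy()`) and as YAML — and
optionally rescales by 1/100 into [0,1] for comparison plots.

Panels are read from a plain CSV dialect (header, `country` column —
name configurable, since deposited datasets vary — one numeric column per
indicator).  Rows with any missing indicator are either an error or, with
`drop_incomplete = TRUE`, dropped with a reported count: the methodology
requires a complete matrix, and case-wise deletion is the standard
treatment that reduces a 180-country report to a ~91-country sample.

## The synthetic generator

`synth_panel()` emulates the statistical shape of standardized indicator
panels so that every module is testable without any download: a Gaussian
copula supplies the dependence structure, and beta marginals
(moment-matched to per-indicator target means/sds, then scaled to 0–100)
supply bounded, broad, typically left-skewed scores.  Because a nonlinear
marginal transform attenuates Pearson correlation, each nonzero target
entry is calibrated: the attained-correlation map is evaluated by 32-point
two-dimensional Gauss–Hermite quadrature on tabulated quantile transforms
and inverted by root finding, so empirical correlations converge to the
*requested* matrix as `n` grows (residual bias below ~0.01).  If
calibration pushes the latent matrix marginally off positive semidefinite,
its eigenvalues are clipped at zero and the diagonal rescaled.  Seeds are
mandatory, and the generator restores the caller's RNG state.

`epi_synth_spec()` fixes the study conditions used throughout the tests
and the acceptance script: 91 countries × the 24 standard indicator codes;
marginal targets set to the published descriptive profile of the
91-country EPI sample (means ≈ 49–70, sds ≈ 26–34 index points, giving
mostly left-skewed, platykurtic marginals); and a low-correlation
dependence baseline (0.05) with one strong trade-off pair,
corr(UWD, WWT) = −0.49, and one strong synergy pair,
corr(TBN, PMW) = +0.48.

What the generator does *not* emulate: the real panel's full correlation
matrix (only its magnitude profile and two pronounced pairs), any
country-level geography or development gradient, and the deterministic
identities of real countries.  Green tests on synthetic panels therefore
demonstrate correctness of the estimation machinery — optimality against
oracles, limit equivalences, accounting identities, reproducibility — not
agreement with any published country ranking; the published-number checks
run only against the actual deposited dataset when a local copy is
present.

## Problem sizes and degenerate inputs

The test suite exercises: hand-solvable panels (m = 1; duplicated columns;
a 2 × 2 panel with pencil-and-paper deviations), ~20 random small panels
(n ≤ 6, m ≤ 3) against the 0.001-step lattice oracle, 20 × 6 and 15 × 5
synthetic panels for limit/monotonicity/accounting properties, and the
full 91 × 24 × 101-λ sweep in the acceptance script.  Degenerate inputs
are defined errors, not silent results: empty panels, scores outside
[0, 100], missing values (unless dropped at load), duplicate identifiers,
non-simplex weights, sibling hierarchy weights not summing to 1,
λ outside [0, 1], non-PSD correlation targets (reported with the offending
eigenvalue), unattainable correlation targets, constant columns in
descriptive statistics (`NaN` shape statistics with a warning; sd is 0).

## Known limitations

* Optimal weight vectors are not unique under degeneracy; only objective
  values are stable across solvers and platforms.
* The LP backend requires a Python with SciPy on the PATH; there is no
  in-process fallback solver.
* Shape statistics use the population-moment conventions (`g1`, excess
  `g2`); bias-adjusted variants differ by `O(1/n)` and matter only for
  very small panels.
* The copula generator's calibration targets pairwise Pearson
  correlations; higher-order dependence (tail behavior, nonlinearity) is
  whatever the Gaussian copula implies.
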