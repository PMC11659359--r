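---
title: "Methods: the E-cadherin/Slug switch, its nondimensionalizations, and PRCC sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the E-cadherin/Slug switch, its nondimensionalizations, and PRCC sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emtsens)
```

## The model and its assumptions

`emtsens` studies a two-variable ODE model of the epithelial–mesenchymal
transition (EMT) in carcinoma cells.  Membrane-bound E-cadherin `E` and the
transcription factor Slug `S` (both ng/mL) interact through saturating Hill
terms:

* Slug represses E-cadherin production (`α₁ / (1 + (S/IC_S)^{n₁})`);
* cell–cell contact `C` (a neighbour count, treated as a continuous input)
  recruits E-cadherin to the membrane (`k₀ H(C/IC_C; n₂)` with
  `H(x; n) = xⁿ/(1+xⁿ)`);
* membrane E-cadherin suppresses Slug by sequestering β-catenin
  (`−k₁ H(E/IC_E; n₃)`);
* exogenous TGF-β `T` (ng/mL) activates Slug (`k₂ H(T/IC_T; n₄)`);
* both species decay linearly (`β₁`, `β₂`).

All Hill factors are evaluated as `xⁿ/(1+xⁿ)` and defined to be 0 at
`x = 0`; no 0/0 ambiguity arises because every exponent is at least 2.  The
Hill coefficients are structural constants (n₁ = 3, n₂ = 4, n₃ = 2, n₄ = 3)
and are never sampled.  The canonical parameter values and their sampling
ranges ship as plain-text config in `inst/extdata/` and are returned by
`emt_parameters()` and `build_ranges()`; the half-maximal constants are
`IC_S = 0.0192`, `IC_E = 0.010`, `IC_T = 3.64e-6` (ng/mL) and `IC_C = 2.17`
cells.

The model is bistable in the inputs: an epithelial state (high `E`, low `S`)
and a mesenchymal state (low `E`, high `S`) coexist over a window of
contact levels, giving a reversible switch in `C` and — because the
recovery fold would require negative TGF-β — an irreversible switch in `T`
at intermediate contact.

## Treatment design

Eight conditions per model frame: contact `C ∈ {0, 1, 2, 6}` cells crossed
with `T ∈ {0, 3.64e-6}` ng/mL.  Each contact level has a prescribed initial
state (`initial_conditions()`); readout is the state at `t = 10000` min.
Nondimensionally the same design is `μ ∈ {0, 0.46, 0.92, 2.76}` ×
`θ ∈ {0, 1}`.  The `μ` levels are the printed rounded treatment values, not
the exact quotients `C/IC_C` (0.4608…, 0.9217…, 2.7649…): the rounded
values are the stated simulation inputs, and the tabulated nondimensional
initial conditions are likewise used verbatim even where they differ in the
third decimal from the rescaled dimensional entries.

## Nondimensionalization

States and inputs rescale by their half-maximal constants (`E = IC_E e`,
`S = IC_S s`, `C = IC_C μ`, `T = IC_T θ`) and time by a characteristic
scale γ.  Seven admissible groupings define γ (`nondim_schemes()`), each
collapsing one of the seven grouped parameters

```
A1 = α₁γ/IC_E   K0 = k₀γ/IC_E   B1 = β₁γ
A2 = α₂γ/IC_S   K1 = k₁γ/IC_S   K2 = k₂γ/IC_S   B2 = β₂γ
```

to exactly 1; that grouping is marked unvaried.  `nondimensionalize()`
regenerates all grouped values from the dimensional table rather than
hard-coding the published ones, and `range_consistency()` compares the two:
they agree at print precision everywhere except one published Set 1 entry
(`K0 = 0.646`), which is internally inconsistent — `k₀/α₁` evaluates to
0.6432, and the published Set 2 `A1 = 1.555` is the reciprocal of 0.6432,
confirming the computed value.  The package reports 0.643 and flags the
corresponding published range as inconsistent rather than matching it.

Grouping *membership* is derived symbolically (`grouping_composition()`):
each grouping is an exponent vector over the dimensional parameters, with
the γ factor folded in and cancelled.  `IC_C` and `IC_T` rescale the inputs
and therefore appear in no grouping under any γ — whatever sensitivity the
dimensional analysis attributes to them is structurally invisible to every
nondimensional analysis.  This is computed, not asserted, and drives the
`lost_parameters` section of the study comparison.

In Sets 4 and 5 the unvaried grouping's counterpart (`K1` in Set 4, `A2` in
Set 5) also evaluates to 1.000 because `α₂ = k₁` in the baseline table;
it remains varied — "held at one" is a property of the γ choice, not of the
numeric value.

## Numerical choices

**Integration.**  lsoda with a compiled right-hand side and analytic
Jacobian, `rtol = 1e-10`, `atol = 1e-12`.  Dimensional steady states reach
~1e-4 ng/mL, and readouts are rounded to 1e-4, so integration error must
sit well below that grain.  Readout is strictly "state at `t_end`"
(default 10000) with a convergence flag (max |rhs| < 1e-9) as a
diagnostic — no early exit, so the protocol is reproduced even where a
trajectory is still drifting.  A test doubles `t_end` for every baseline
group and checks that no rounded readout changes.

**Rounding.**  Half-away-from-zero to the frame grain (1e-4 dimensional,
1e-2 nondimensional), e.g. `round_output(0.00005, "dimensional")` is 1e-4.
Rounding before ranking deliberately creates ties; all ranking uses
midranks.

**Equilibria.**  At a fixed point, `E` is an explicit function of `S`, so
fixed points are roots of a scalar residual `g(S)`.  The scan covers
`S ∈ [0, 2(α₂+k₂)/β₂]` (an upper bound no steady state can exceed) with
2000 points; each sign change is polished to 1e-12.  Stability comes from
the analytic 2×2 Jacobian: the trace is always negative, so the determinant
sign separates stable points from saddles.

**Folds.**  `trace_branches()` sweeps the control on a 600-point grid and
brackets changes in the equilibrium count.  Within a bracket,
`locate_fold()` does *not* rely on count bisection alone: when the merging
saddle–node pair is closer than the scan grid the count drops early, which
biases thresholds (by ~2% for the TGF-β folds, whose S-gap collapses
steeply).  Instead the fold is found from the tangency condition — the
control value at which the residual's tracked critical value crosses zero —
which is insensitive to scan resolution; the count change only seeds the
search.  Fold states are reported at the double root, where `g` and `g'`
vanish together.

With the canonical parameters the computed contact folds are
`L_M = 0.953144` and `L_E = 2.009008` cells, and the TGF-β thresholds are
`4.9146e-7` (C = 1) and `1.87570e-6` ng/mL (C = 2).  The commonly quoted
reference values 0.9532, 2.0090 and 1.8757e-6 agree to print precision;
the quoted C = 1 threshold of ≈ 5.02e-7 is approximate — an independent
30-digit tangency solve confirms 4.9146e-7 for these parameter values, and
the package reports the computed number.

## Latin hypercube sampling

Each varied parameter is sampled uniformly over `[0.9v, 1.1v]` (the
narrow-range design: ±10% around the values that produce bistability),
except four published shifted ranges — `α₂`, `k₁` dimensionally and `A2`,
`K1` in every set — which keep the 20% width but are displaced to preserve
monotone, nonnegative readouts under one-at-a-time variation.  The shifts
are stored as data; there is no formula for them.

The design stratifies each column into N equal cells with one uniform draw
per cell (`midpoint` mode replaces the jitter with cell centres for
deterministic tests).  Each column consumes an RNG substream derived from
the global seed and the column index, so (a) the same seed yields the same
unit draw in every model frame — frame comparisons are not confounded by
sampling noise — and (b) adding a column never perturbs existing ones.  An
independent-designs mode (`shared_design = FALSE`) is available.

The admissibility rule `N > 4K/3` is enforced strictly: for K = 11,
N = 15 is admitted and N = 14 rejected.  (A stricter "N > 15" reading for
K = 11 circulates; the package follows the inequality itself.)

## PRCC

The coefficient for parameter `j` against output `y` is the Pearson
correlation of the residuals from regressing `rank(X_j)` and `rank(y)` on
all other rank columns plus an intercept.  The double-regression route is
the implementation (stabler with heavy ties); the classical
inverse-correlation-matrix construction is kept in the test suite as an
independent oracle and the two agree to 1e-10 on random instances.  Outputs
constant after rounding yield an undefined coefficient, reported as `NA`
and never significant.  The significance cutoff is |ρ| ≥ 0.5; no p-values
or multiple-testing corrections are applied — the cutoff is the published
decision rule and is configurable.

`interparameter_prcc()` screens all column pairs, controlling for the
remaining K−2 columns, to confirm the design carries no hidden
relationships (max |ρᵢⱼ| ≈ 0.026 at N = 10000 on the 11-column design).

**Monotonicity.**  PRCC presumes each output is monotone in each parameter
varied alone.  `monotonicity_scan()` evaluates the rounded readouts on an
evenly spaced grid (default 50 points; the tests use 13–25) across each
sampling range and checks nonstrict monotonicity of the rounded sequence —
"nonstrict after rounding" is this package's criterion, since rounding is
precisely what absorbs sub-grain wiggle.  All tabulated ranges pass in all
treatment groups, in the dimensional frame and all seven sets.  At
(μ = 2.76, θ = 0) the A2-low/K1-high range ends still produce marginally
negative raw Slug steady states (≈ −0.005, rounding to 0.00); this is
reported via `negative_values` as a diagnostic and does not break
monotonicity.

## The study and its comparison

`run_study()` executes, per frame: ranges → LHS → 8 treatment groups ×
N integrations → rounded readouts → PRCC per output → significance grid.
`report_discrepancies()` then (1) flags every (group, output) cell where
the seven nondimensional significant-parameter sets are not literally
identical — note that this raw comparison also counts unavailability (the
γ-defining grouping cannot be flagged in its own set); and (2) lists
dimensional significances carried by parameters outside every grouping
(`IC_C`, `IC_T`).  The headline cells are the e-output at
(μ ∈ {0.46, 0.92}, θ = 0), where formulations genuinely disagree because
those conditions sit near the bistable boundary and the ±10% ranges
straddle it.

**Problem sizes.**  The published protocol is N = 10000 per frame; the test
suite and acceptance script run the pattern checks at N = 1000 and the
design-only screens at N = 10000.  N = 1000 was chosen after checking that
every asserted significance call is stable between N = 1000 and N = 10000;
coefficients sitting within ~0.05 of the cutoff are the only ones that
could flip, and none of the asserted ones do.

**What the magnitudes mean.**  With a deterministic model, the residual
left after partialling out the other parameters' rank-linear effects is
mostly quantization (output rounding) plus interaction structure, so
secondary-parameter coefficients are sensitive to the rounding grain and to
basin-hopping in the bistable groups.  Dominant-parameter calls are robust;
exact magnitudes in the 0.5–0.8 band are not portable across protocol
variants, which is worth keeping in mind when comparing significance grids
produced under different tolerances.

## What the generator does and does not emulate

The sampling module *is* the study's synthetic-input generator: uniform
marginals over the tabulated ranges, stratified, with the stated N rule.
It does not emulate features of laboratory data — measurement noise,
non-uniform or correlated parameter distributions (grouped nondimensional
parameters are in truth products of uniforms, a Discussion-level concern
explicitly out of scope), or cell-to-cell heterogeneity.  Passing tests
therefore certify the computational protocol, not biological measurement.

## Known limitations

* Two-parameter (C, T) bifurcation surfaces and continuation beyond
  codimension 1 are out of scope; `trace_branches()` is a sweep-based
  tracer adequate for a 2-state model, not a general continuation engine.
* Only the seven tabulated γ choices are supported; no symbolic
  nondimensionalization of arbitrary models.
* Sobol/eFAST/Morris indices and bootstrap confidence intervals on ρ are
  not implemented; the |ρ| = 0.5 rule is the only decision criterion.
* The quoted reference threshold for the C = 1 TGF-β fold (≈ 5.02e-7
  ng/mL) is not reproducible from the canonical parameter values (computed:
  4.9146e-7); the package reports computed values throughout.
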