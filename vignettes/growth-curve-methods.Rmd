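---
title: "Growth-curve methods in growplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve methods in growplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growplate)
```

growplate turns raw microtiter-plate (MTP) reader exports into per-well
growth metrics. This vignette is the package's own account of the methods:
the data model, the preprocessing chain, the fitting machinery, the metric
definitions, and the design choices made where more than one reasonable
convention exists.

## The data model

Every experiment is a strict hierarchy: an experiment holds runs, a run
holds plates, a plate holds wells, and a well holds repeated measures.
The canonical table has one row per (run, plate, well, runtime)
observation — plus an optional `measure_type` for instruments that report
more than one channel — and zero or more design columns (strain, drug,
dose, ...) that are constant within a well. Readers for long CSV, wide
(time × well) CSV and a Bioscreen-style dialect all land in this one shape,
which is what makes the downstream modules composable.

Conventions fixed here because file formats do not fix them:

* Well labels are canonicalized at ingest ("a1" → "A01"; numeric labels
  stay plain numbers), and all equality is on canonical form.
* Plate shape is inferred as the smallest standard plate (3×4, 4×6, 6×8,
  8×12, 16×24, or the numeric well count) covering the observed labels,
  unless a reader supplies it.
* Runtimes are absolute elapsed time in one experiment-wide unit (seconds,
  minutes or hours); `hh:mm:ss` literals are converted through seconds.
  A well need not start at runtime 0; any start ≥ 0 is accepted.
* Duplicate (run, plate, well, runtime, measure_type) keys are an error,
  never silently collapsed. Blank cells in wide layouts are dropped, not
  imputed.
* The Bioscreen dialect numbers wells 1–200; we assign 1–100 to plate "1"
  and 101–200 (renumbered 1–100) to plate "2", mirroring the instrument's
  two-cassette layout.
* When several measures and design files arrive together, designs attach
  to measures by longest common filename-stem prefix after stripping a
  trailing `_design`/`-design` token (`run1_design.csv` → `run1.csv`);
  ties are an error rather than a guess.

## Preprocessing

Six independent per-well options, applied in a fixed order: log-ratio
transform → running median → running mean → enforce-increasing →
background formula → calibration formula. Disabled steps are identities.

* **Log-ratio transform**: `log_b(y / min(y))`. Sigmoid growth theory is
  phrased in log(N/N0); the minimum is used instead of the first measure so
  a noisy first cycle cannot shift the whole curve. The minimum maps to
  exactly 0.
* **Running median, then running mean** with odd window widths smaller
  than the series length. The median removes single-cycle spikes (bubbles,
  condensation); the mean damps low-amplitude jitter. At the series edges
  the window shrinks symmetrically (widths 1, 3, ..., k), which preserves
  length and introduces no padding artifacts.
* **Enforce increasing** replaces any measure below its predecessor with
  that predecessor (the running maximum) — a guard against transient
  signal drops from aggregation or precipitation. It is idempotent.
* **Background and calibration formulas** are user-supplied expressions in
  a closed mini-language over the measure vector `y` and runtime `x`
  (details below), e.g. `y - 0.081`, `y - min(y)`, `y - mean(y[1:5])`.

The chain runs background correction after smoothing and the log
transform, following the panel order of the interactive workflow this
package mirrors; physically, background light scatter is pre-log, so when
a fixed blank value is to be subtracted it is cleaner to skip the log step
and subtract in the background formula instead. This caveat is deliberate
and documented rather than silently reordered.

Wells that fail a step (e.g. nonpositive values under a log) are flagged
and excluded from fitting rather than aborting the run; fitting also skips
wells with fewer than 5 usable points — below that a 3–4 parameter sigmoid
is not meaningfully constrained.

## The formula mini-language

Background correction, calibration and manual models all accept formulas,
but evaluating user text with the host language's `eval` would let a
config file execute arbitrary code. growplate instead parses formulas into
an explicit AST over a closed vocabulary — numbers; `y`, `x` and model
parameters; `+ - * / ^` with standard precedence (`^` right-associative,
binding tighter than unary minus); 1-based inclusive slices `y[a]`,
`y[a:b]`; and the functions min, max, mean, median, log, log2, log10, exp,
sqrt, abs — and interprets the AST directly. Nothing else parses, so a
formula cannot reach the filesystem or any name outside the vocabulary.
Aggregates reduce to a scalar and broadcast; slices are 1-based inclusive
(the convention of the surrounding ecosystem), and `log` of a nonpositive
value yields a missing value plus a per-well warning instead of a fatal
error. Model formulas have the shape `y ~ f(x; parameters)`; every free
name other than `x` becomes a parameter (both `~` and `?` are accepted as
the separator, since PDF renderings of model formulas often mangle the
tilde).

The test suite cross-checks this interpreter against an independent
oracle — base R evaluation of the same expression text in a sealed
environment — on 1000 randomized inputs per run.

## Fitting

* **Spline**: `stats::smooth.spline`, GCV-chosen smoothing parameter
  unless `spar` is given; the derivative is the spline's analytic
  derivative. Reported quality: `spar`, equivalent degrees of freedom
  `df`, the minimized criterion `crit`, the penalized residual sum of
  squares, and the GCV score under `cv.crit`. Duplicate time points (which
  can appear after unit conversion) are averaged with a warning.
* **Named sigmoids**: the Zwietering forms above, chosen because their
  coefficients are exactly the quantities practitioners report (A, μ, λ).
  Optimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) with box
  bounds A > 0, μ > 0, λ ≥ 0 (ν > 0), at most 200 iterations, relative
  tolerance 1e-8. Self-starts: A₀ = max(y); μ₀ = the largest
  finite-difference slope; λ₀ = the tangent x-intercept at the max-slope
  point clamped to [0, t_max]; ν₀ = 1. Non-convergence is reported
  (`isConv`, flagged well), never fatal, and the last iterate is kept so
  the well can still be inspected.
* **Manual models**: least squares on the AST-defined prediction function;
  starting values must cover every parameter. The curve derivative comes
  from symbolic differentiation of the model expression with respect to
  `x` when it is smooth and closed-form; otherwise central finite
  differences with step 1e-6 × range(x).
* **Quality statistics** for parametric fits are the Gaussian RSS-based
  set: logLik = −n/2·[ln(2π) + ln(RSS/n) + 1]; AIC = 2(p+1) − 2·logLik;
  BIC = ln(n)(p+1) − 2·logLik (the error variance counts as a parameter);
  deviance = RSS; df.residual = n − p; sigma = √(RSS/(n−p)); `finTol` is
  the optimizer's achieved relative tolerance. RSS is floored at 1e-300 so
  a perfect fit reports large finite statistics instead of overflowing.
  A weighted-least-squares hook exists internally, but the default (and
  only documented) behavior is uniform weights.

## Summary metrics

Metrics are read off a uniform grid of `grid_size` points (default 1000,
tunable) over the observed time domain; ties in a maximum resolve to the
first grid index, implementing "the time at which it first occurs".

* `max_y_x`, `max_y_y`: location and value of the curve maximum.
* `max_dy_m`, `max_dy_x`, `max_dy_y`: the maximum slope and its location.
* `max_dy_b = max_dy_y − max_dy_m·max_dy_x` and
  `max_dy_x0 = −max_dy_b / max_dy_m`: intercepts of the tangent at the
  maximum-slope point. For sigmoid fits, `max_dy_m ≈ μ` and
  `max_dy_x0 ≈ λ` by construction — the tests assert both within 1%.
* `fit_int`: trapezoidal integral of the fitted curve over the observed
  domain [t_min, t_max]. When the first measurement is later than 0 we do
  not extrapolate back to 0: a fit is never evaluated outside its support.
* `min_doubling_time = ln 2 / μ*`, with μ* the maximum specific growth
  rate d ln ŷ/dt over the grid. When measures were log_b-transformed
  upstream the fit is already on log scale and μ* = ln(b) × max slope.
  On linear-scale fits μ* = max ŷ′/ŷ, restricted to where ŷ exceeds 1% of
  its maximum: a sigmoid's specific rate diverges as ŷ → 0, so rates below
  the detection floor are numerical artifacts. The floor crossing is
  located by interpolation so the value is stable under grid refinement.
  The 1% convention matters only for linear-scale curves with a
  pronounced lag; with log-ratio preprocessing (the recommended route when
  doubling times are of interest) no guard is needed. Flat curves
  (max slope ≤ 1e-12) report missing tangent metrics and doubling time.

Grid choices are convergence-tested: doubling `grid_size` moves every
metric by far less than 0.1% on smooth fits.

## Reference/target grouping

Groups are written `[plate!]refs->targets`, one per line; each side is a
comma list of wells and inclusive rectangles (`B02:C03` = B02, B03, C02,
C03, row-major; numbered plates use integer ranges). Omitting the plate
prefix instantiates the group on every plate of the run; all grouped
plates must share one shape. Groups are named positionally (`g1`, `g2`,
... by line order, `plate!gk` when plate-scoped) since the shorthand has
no name field — a deterministic convention of this package. Applying
groups produces one row per (row × matching group) with `group` and
`is_ref` columns; a well listed on both sides of one spec is marked
`is_ref = TRUE` (it cannot be its own target within a group), wells may
appear in any number of groups, and per-(group, is_ref) means of every
numeric metric are computed with pairwise missing-value removal.

## The simulator

`sim_config()` defaults emulate the kind of chemical-genetic screen the
package targets: one 96-well (8 × 12) plate read every 15 min for 94
cycles (runtime in hours), Gompertz truth curves with per-well parameters
drawn uniformly from A ∈ [0.8, 1.4] OD, μ ∈ [0.1, 0.5] OD/h, λ ∈ [2, 8] h,
a baseline offset of 0.08 OD (a typical blank), Gaussian noise with
σ = 0.01 OD, rare single-cycle spikes (probability 0.01, height 0.3 OD),
and a 3 strain × 2 drug × 8-step two-fold dilution design from 50 µM down
to 0. Per-well random substreams are derived by hashing (run, plate,
well), so adding wells or reordering emission never changes another
well's draws; measures are quantized to 6 decimals like an instrument
export, which is what makes emitted text files round-trip exactly.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real data: evaporation and edge-well gradients,
spatial crosstalk, drift in blanks, non-linear OD-to-density response
(calibration exists precisely because real instruments need it), and
condition-dependent truth parameters (design variables are annotations,
not effects). Tests on simulated data validate the machinery, not any
biological claim.

Problem sizes in the shipped tests are chosen to keep the default suite
fast while still exercising every path: most fixtures are one small plate
(6–12 wells, 20–40 cycles), with one full-size 96-well × 94-cycle
recovery study per named model property.

## Output contract

`run_pipeline()` is deterministic: outputs are a pure function of the
config and the input bytes, and reruns are byte-identical. Column orders
are fixed (measures: run, plate, well, runtime, optional datetime and
measure_type, raw then preprocessed measure, design columns
alphabetically, then group columns; summary: keys, method, the metric
columns in a fixed order, coefficients, design, group columns). Missing
values serialize as empty fields. When groups are supplied, `measures.csv`
and `summary.csv` are the grouped views (one row per well × group) and
`group_means.csv` is added; `quality.csv` is always ungrouped. The run log
records every parse, join, fit and skip action.

## Known limitations

* One measure type is modeled at a time; joint multi-channel modeling is
  out of scope.
* No per-plate spatial normalization or imputation of missing cycles.
* Group comparisons stop at per-group means; no inferential statistics.
* The exact detection signatures of proprietary instrument dialects are
  not reproduced; the format registry is deliberately pluggable so such
  readers can be added without touching the pipeline.
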