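# growplate

Scriptable analysis of microbial growth curves from microtiter-plate (MTP)
experiments: tidy heterogeneous plate-reader exports and design files into
one canonical table, preprocess each well's curve, fit splines, sigmoid
growth models or arbitrary user models, extract per-well growth metrics and
fit-quality statistics, compare wells through a reference/target grouping
shorthand, and export everything as tidy CSVs.

## Who this is for

High-throughput screens (chemical genetics, drug interaction panels, strain
libraries) read optical density in 96- or 384-well plates every few minutes
for a day, producing thousands of growth curves per run. The bottleneck is
rarely the instrument — it is turning a pile of vendor-specific exports and
hand-made design spreadsheets into per-well fitness numbers you can rank
and plot. growplate is the batch/scripting counterpart to interactive
curve-inspection tools: everything is a plain function over a tibble, so
the full pipeline is reproducible and automatable.

## The model

Each well's preprocessed curve y(t) is summarized by one of five methods:

* **spline** (default, model-free): cubic smoothing spline, smoothing
  chosen by generalized cross-validation (GCV);
* **gompertz**, **logistic**, **richards**: sigmoid growth models in the
  Zwietering (A, μ, λ) reparameterization, where A is the asymptotic growth
  limit, μ the maximum growth rate (slope at the inflection tangent) and λ
  the lag time (x-intercept of that tangent):

  * Gompertz:  y = A · exp(−exp((μe/A)(λ−t) + 1))
  * logistic:  y = A / (1 + exp((4μ/A)(λ−t) + 2))
  * Richards:  y = A · [1 + ν·e^(1+ν) · exp((μ/A)(1+ν)^(1+1/ν)(λ−t))]^(−1/ν)

  fitted by bounded Levenberg–Marquardt least squares with self-starting
  initial values (Richards' extra shape ν reduces to the logistic at ν = 1);
* **manual**: any model expressible in a small, safe formula language,
  e.g. the Brody model `y ~ a - (a - w0) * exp(-k * x)`, with user-supplied
  starting values such as `"a = 1, w0 = 0.5, k = 0.00003"`.

From the fitted curve and its derivative, evaluated on a uniform grid, the
package reports `max_y_x`/`max_y_y` (time and value of the curve maximum),
`max_dy_m` (maximum slope), `max_dy_x`/`max_dy_y` (its location),
`max_dy_b`/`max_dy_x0` (tangent-line intercepts; `max_dy_x0` is the lag
time for sigmoids), `fit_int` (area under the fitted curve), the model
coefficients, and the minimum doubling time ln 2 / μ*, where μ* is the
maximum specific (log-scale) growth rate.

## Worked example

A seeded simulator stands in for an instrument: one 96-well plate, read
every 15 min for 94 cycles, Gompertz truth curves plus baseline, noise and
a 3 strain × 2 drug × 8-dose design — emitted as real files in any
supported dialect so the reader/join heuristics are exercised too.

```r
library(growplate)

cfg <- sim_config(seed = 42)
sim <- simulate_experiment(cfg)
emit_fixture_files(sim, "long_csv", "demo", cfg)

res <- run_pipeline(run_config(
  files  = c("demo/run1.csv", "demo/run1_design.csv"),
  units  = "hours",
  method = "gompertz",
  preprocess = preprocess_config(median_window = 3,
                                 background = "y-min(y)"),
  groups = "A01->A01:H12",
  outdir = "demo-out"))

experiment_summary(sim$measures)
#> # A tibble: 1 × 4
#>   run   n_plates n_wells n_measures
#> 1 run1         1      96       9024

dplyr::select(res$summary, well, A, mu, lambda, min_doubling_time,
              strain, dose_uM)[1:3, ]
#>   well      A    mu lambda min_doubling_time strain dose_uM
#> 1 A01   0.848 0.367   7.31             0.128 BY4743 50
#> 2 A02   0.913 0.273   6.92             0.185 BY4743 25
#> 3 A03   0.846 0.281   7.70             0.167 BY4743 12.5
```

Each row is one well: the culture in A01 grows to an asymptote of
OD ≈ 0.85 at a maximum rate of 0.37 OD/h after a ~7.3 h lag; at the point
of fastest specific growth it doubles every ~0.13 h. The `A01->A01:H12`
shorthand makes A01 the reference for all 96 wells, and the per-group means
land in `res$group_means` (and `group_means.csv`):

```r
res$group_means[, c("group", "is_ref", "n_wells", "mu", "fit_int")]
#>   group is_ref n_wells    mu fit_int
#> 1 g1    FALSE       95 0.294    17.3
#> 2 g1    TRUE         1 0.367    12.4
```

`run_pipeline()` writes `measures.csv` (raw + preprocessed values),
`summary.csv` (the metrics above), `quality.csv` (spar/df/GCV for splines;
sigma, isConv, finTol, logLik, AIC, BIC, deviance, df.residual for
parametric fits) and `run.log`. Plate-level figures come from
`plot_plate(res$summary, fill = "mu")`, per-well curve panels (with
translucent reference overlays) from `plot_well_curves()`, and single-fit
diagnostics from `autoplot()` on any fit object.

A thin command-line wrapper over the same functions lives at
`inst/cli/growplate` (subcommands `detect`, `simulate`, `run`).

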