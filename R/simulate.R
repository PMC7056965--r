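# Seeded synthetic experiments: sigmoid truth curves with baseline offset,
# Gaussian noise and occasional single-cycle spike artifacts, plus a
# factorial design, emitted in every supported file dialect. Per-well random
# substreams are derived by hashing (run, plate, well), so well order never
# changes the draws and the same config is byte-reproducible.

#' Simulation configuration
#'
#' Defaults emulate a typical chemical-genetic microtiter-plate screen: one
#' run of one 96-well (8 x 12) plate read every 15 min for 94 cycles
#' (runtime in hours), Gompertz truth curves with a small baseline offset
#' and measurement noise, and a design of 3 strains x 2 drugs x an 8-step
#' two-fold dilution series from 50 uM down to 0.
#'
#' @param seed Integer seed; all draws derive from it.
#' @param n_runs,n_plates Experiment size.
#' @param shape A [plate_shape()].
#' @param n_cycles Number of measurement cycles per well.
#' @param interval Time between cycles, in `units`.
#' @param units Runtime unit of the simulated experiment.
#' @param truth_model `"gompertz"`, `"logistic"`, `"richards"` or `"brody"`.
#' @param A_range,mu_range,lambda_range,nu_range Uniform ranges the per-well
#'   truth parameters are drawn from (for Brody: `a` from `A_range`, `k`
#'   from `mu_range`, `w0 = a/2`).
#' @param baseline Additive baseline offset (blank signal).
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param spike_prob,spike_height Per-cycle probability and size of additive
#'   single-point spike artifacts.
#' @param design Named list of design variables; their factorial combination
#'   is tiled row-major across each plate, or `NULL` for no design.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_runs = 1L, n_plates = 1L,
                       shape = plate_shape(8, 12), n_cycles = 94L,
                       interval = 0.25, units = "hours",
                       truth_model = c("gompertz", "logistic", "richards",
                                       "brody"),
                       A_range = c(0.8, 1.4), mu_range = c(0.1, 0.5),
                       lambda_range = c(2, 8), nu_range = c(0.7, 1.5),
                       baseline = 0.08, noise_sd = 0.01,
                       spike_prob = 0.01, spike_height = 0.3,
                       design = list(strain = c("BY4743", "opi3", "swd3"),
                                     drug = c("cmpd1", "cmpd2"),
                                     dose_uM = c(50 / 2^(0:6), 0))) {
  truth_model <- match.arg(truth_model)
  stopifnot(n_runs >= 1L, n_plates >= 1L, n_cycles >= 2L, interval > 0,
            noise_sd >= 0, spike_prob >= 0, spike_prob <= 1)
  check_runtime_unit(units)
  structure(list(seed = as.integer(seed), n_runs = as.integer(n_runs),
                 n_plates = as.integer(n_plates), shape = shape,
                 n_cycles = as.integer(n_cycles), interval = interval,
                 units = units, truth_model = truth_model,
                 A_range = A_range, mu_range = mu_range,
                 lambda_range = lambda_range, nu_range = nu_range,
                 baseline = baseline, noise_sd = noise_sd,
                 spike_prob = spike_prob, spike_height = spike_height,
                 design = design),
            class = "sim_config")
}

# Deterministic 31-bit substream seed from the master seed and well key.
well_seed <- function(seed, run, plate, well) {
  key <- paste(run, plate, well, sep = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + seed * 7919) %% 2147483647)
}

truth_curve <- function(t, model, p) {
  if (model == "brody") {
    p[["a"]] - (p[["a"]] - p[["w0"]]) * exp(-p[["k"]] * t)
  } else {
    growth_model(t, model, A = p[["A"]], mu = p[["mu"]],
                 lambda = p[["lambda"]], nu = p[["nu"]] %0% 1)
  }
}

draw_params <- function(config) {
  runif1 <- function(r) stats::runif(1L, r[1L], r[2L])
  if (config$truth_model == "brody") {
    a <- runif1(config$A_range)
    list(a = a, w0 = a / 2, k = runif1(config$mu_range))
  } else {
    p <- list(A = runif1(config$A_range), mu = runif1(config$mu_range),
              lambda = runif1(config$lambda_range))
    if (config$truth_model == "richards") p$nu <- runif1(config$nu_range)
    p
  }
}

#' Simulate a multi-plate growth experiment
#'
#' Per well, truth parameters are drawn from the configured ranges, the
#' truth model is evaluated at `n_cycles` times spaced `interval` apart
#' (starting at 0), and `baseline + noise + spikes` are added. Measures are
#' quantized to 6 decimals, like an instrument export, so emitted text files
#' round-trip exactly.
#'
#' @param config A [sim_config()].
#' @return List with `measures` (tidy measures tibble, including design
#'   columns) and `truth` (per-well true parameters).
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 1, shape = plate_shape(2, 3),
#'                                       n_cycles = 20))
#' sim$truth
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  t <- (seq_len(config$n_cycles) - 1L) * config$interval
  wells <- plate_wells(config$shape)
  conds <- if (is.null(config$design)) NULL else {
    grid <- rev(expand.grid(rev(config$design), stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE))
    grid[((seq_along(wells) - 1L) %% nrow(grid)) + 1L, , drop = FALSE]
  }
  measures <- list()
  truth <- list()
  for (r in seq_len(config$n_runs)) {
    run <- paste0("run", r)
    for (pl in seq_len(config$n_plates)) {
      plate <- as.character(pl)
      for (wi in seq_along(wells)) {
        w <- wells[wi]
        set.seed(well_seed(config$seed, run, plate, w))
        p <- draw_params(config)
        y <- config$baseline + truth_curve(t, config$truth_model, p)
        if (config$noise_sd > 0) {
          y <- y + stats::rnorm(length(t), 0, config$noise_sd)
        }
        if (config$spike_prob > 0) {
          hit <- stats::runif(length(t)) < config$spike_prob
          y[hit] <- y[hit] + config$spike_height
        }
        y <- as.numeric(sprintf("%.6f", y))
        rec <- tibble::tibble(run = run, plate = plate, well = w,
                              runtime = t, measure = y)
        if (!is.null(conds)) {
          rec <- dplyr::bind_cols(rec, conds[rep(wi, length(t)), , drop = FALSE])
        }
        measures[[length(measures) + 1L]] <- rec
        truth[[length(truth) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(run = run, plate = plate, well = w,
                         model = config$truth_model),
          tibble::as_tibble(p))
      }
    }
  }
  list(measures = as_tidy_measures(dplyr::bind_rows(measures),
                                   units = config$units),
       truth = dplyr::bind_rows(truth))
}

# ---- emission -----------------------------------------------------------

fmt_num <- function(x) sprintf("%.10g", x)

seconds_to_hms <- function(s) {
  s <- round(s)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Emit a simulated experiment as fixture files
#'
#' Writes one measures file per run in the requested dialect plus a design
#' file named `<run>_design.csv` (plate-shaped 'plater' layout for gridded
#' plates, generic CSV for numbered plates), exercising the multi-file join
#' heuristics. Emission is deterministic: the same simulation yields
#' byte-identical files.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dialect `"long_csv"`, `"wide_csv"` or `"bioscreen"`.
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used (for units and shape).
#' @return Character vector of written file paths, invisibly.
#' @export
emit_fixture_files <- function(sim, dialect = c("long_csv", "wide_csv",
                                                "bioscreen"),
                               dir, config) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  measures <- sim$measures
  design_cols <- setdiff(names(measures),
                         c("run", "plate", "well", "runtime", "measure",
                           "measure_type", "datetime"))
  unit_s <- runtime_unit_factors[[config$units]]
  paths <- character(0)
  for (run in unique(measures$run)) {
    m <- measures[measures$run == run, ]
    mpath <- file.path(dir, paste0(run, ".csv"))
    if (dialect == "long_csv") {
      lines <- c("run,plate,well,runtime,measure",
                 paste(m$run, m$plate, m$well, fmt_num(m$runtime),
                       fmt_num(m$measure), sep = ","))
    } else if (dialect == "wide_csv") {
      if (length(unique(m$plate)) != 1L || !is.null(config$shape$n_wells)) {
        stop("wide_csv emission needs a single gridded plate", call. = FALSE)
      }
      wide <- tidyr::pivot_wider(m[c("well", "runtime", "measure")],
                                 names_from = "well", values_from = "measure")
      lines <- c(paste(c("time", names(wide)[-1L]), collapse = ","),
                 apply(wide, 1L, function(r) {
                   paste(c(fmt_num(as.numeric(r[1L])),
                           sprintf("%.6f", as.numeric(r[-1L]))),
                         collapse = ",")
                 }))
    } else { # bioscreen
      if (is.null(config$shape$n_wells) || config$shape$n_wells > 100L ||
          length(unique(m$plate)) > 2L) {
        stop("bioscreen emission needs numbered plates of <= 100 wells",
             call. = FALSE)
      }
      m$bs_well <- as.integer(m$well) + ifelse(m$plate == "2", 100L, 0L)
      wide <- tidyr::pivot_wider(m[c("bs_well", "runtime", "measure")],
                                 names_from = "bs_well",
                                 values_from = "measure")
      lines <- c(paste(c("Time", names(wide)[-1L]), collapse = ","),
                 apply(wide, 1L, function(r) {
                   paste(c(seconds_to_hms(as.numeric(r[1L]) * unit_s),
                           sprintf("%.6f", as.numeric(r[-1L]))),
                         collapse = ",")
                 }))
    }
    writeLines(lines, mpath)
    paths <- c(paths, mpath)

    if (length(design_cols)) {
      dpath <- file.path(dir, paste0(run, "_design.csv"))
      one <- m[!duplicated(m$well), c("well", design_cols)]
      standard <- !is.null(config$shape$n_rows) &&
        any(vapply(standard_shapes, identical, logical(1),
                   c(config$shape$n_rows, config$shape$n_cols)))
      if (standard) {
        blocks <- lapply(design_cols, function(v) {
          vals <- stats::setNames(as.character(one[[v]]), one$well)
          rows <- vapply(seq_len(config$shape$n_rows), function(ri) {
            cells <- vapply(seq_len(config$shape$n_cols), function(ci) {
              w <- paste0(LETTERS[ri], sprintf("%02d", ci))
              if (w %in% names(vals)) vals[[w]] else ""
            }, character(1))
            paste(c(LETTERS[ri], cells), collapse = ",")
          }, character(1))
          c(paste(c(v, seq_len(config$shape$n_cols)), collapse = ","), rows)
        })
        lines <- unlist(lapply(seq_along(blocks), function(i) {
          if (i == 1L) blocks[[i]] else c("", blocks[[i]])
        }))
      } else {
        dd <- m[!duplicated(paste(m$plate, m$well)),
                c("plate", "well", design_cols)]
        dd[] <- lapply(dd, function(col) {
          if (is.numeric(col)) fmt_num(col) else as.character(col)
        })
        lines <- c(paste(c("plate", "well", design_cols), collapse = ","),
                   do.call(paste, c(dd, sep = ",")))
      }
      writeLines(lines, dpath)
      paths <- c(paths, dpath)
    }
  }
  invisible(paths)
}
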