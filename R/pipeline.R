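# End-to-end orchestration: config -> read/join -> preprocess -> fit ->
# summarize -> group -> three tidy CSVs plus a run log. Outputs are a pure
# function of the config and input bytes.

#' Pipeline run configuration
#'
#' @param files Character vector of measures and design file paths (kinds
#'   are detected from content).
#' @param units Runtime unit ("seconds", "minutes", "hours").
#' @param preprocess A [preprocess_config()].
#' @param method Estimation method ("spline", "gompertz", "logistic",
#'   "richards", "manual").
#' @param model,start Manual-mode model formula and start values (strings).
#' @param spar Optional spline smoothing parameter.
#' @param grid_size Metric evaluation grid size.
#' @param groups Optional group shorthand (multiline string; see
#'   [parse_group_shorthand()]).
#' @param outdir Output directory for the CSVs and run log.
#' @return A `run_config` list.
#' @export
run_config <- function(files, units = "seconds",
                       preprocess = preprocess_config(),
                       method = "spline", model = NULL, start = NULL,
                       spar = NULL, grid_size = 1000L, groups = NULL,
                       outdir = ".") {
  stopifnot(length(files) >= 1L, inherits(preprocess, "preprocess_config"))
  check_runtime_unit(units)
  structure(list(files = files, units = units, preprocess = preprocess,
                 method = method, model = model, start = start, spar = spar,
                 grid_size = as.integer(grid_size), groups = groups,
                 outdir = outdir),
            class = "run_config")
}

#' Read / write a run configuration file
#'
#' The YAML file uses the keys of [run_config()]; preprocessing options are
#' nested under `preprocess` with keys `log_base`, `median_window`,
#' `mean_window`, `enforce_increasing`, `background`, `calibration`. A
#' persisted config fully determines all pipeline outputs for fixed input
#' files.
#'
#' @param path YAML file path.
#' @param config A `run_config` (for writing).
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pp <- raw$preprocess %||% list()
  run_config(
    files = unlist(raw$files),
    units = raw$units %||% "seconds",
    preprocess = preprocess_config(
      log_base = pp$log_base %||% "none",
      median_window = pp$median_window %||% 1L,
      mean_window = pp$mean_window %||% 1L,
      enforce_increasing = isTRUE(pp$enforce_increasing),
      background = pp$background,
      calibration = pp$calibration),
    method = raw$method %||% "spline",
    model = raw$model, start = raw$start, spar = raw$spar,
    grid_size = raw$grid_size %||% 1000L,
    groups = if (is.null(raw$groups)) NULL
             else paste(unlist(raw$groups), collapse = "\n"),
    outdir = raw$outdir %||% ".")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  pp <- config$preprocess
  yaml::write_yaml(list(
    files = as.list(config$files), units = config$units,
    preprocess = list(log_base = as.character(pp$log_base),
                      median_window = pp$median_window,
                      mean_window = pp$mean_window,
                      enforce_increasing = pp$enforce_increasing,
                      background = pp$background,
                      calibration = pp$calibration),
    method = config$method, model = config$model, start = config$start,
    spar = config$spar, grid_size = config$grid_size,
    groups = config$groups, outdir = config$outdir), path)
  invisible(path)
}

design_columns <- function(table) {
  setdiff(names(table), c("run", "plate", "well", "runtime", "datetime",
                          "measure_type", "measure", "measure_raw",
                          "measure_preprocessed", "group", "is_ref"))
}

#' Run the whole analysis pipeline
#'
#' Reads and joins the input files, preprocesses every well, fits the chosen
#' method, extracts summary metrics and quality statistics, optionally
#' applies reference/target groups, and writes `measures.csv`,
#' `summary.csv`, `quality.csv` (and `group_means.csv` when groups are
#' given) plus a `run.log` of parse/join/skip actions to `config$outdir`.
#' Rerunning an identical config on identical inputs yields byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the output tibbles (`measures`, `summary`,
#'   `quality`, `group_means`), the fit table (`fits`) and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  table <- join_experiment(config$files, units = config$units)
  log <- c(log, attr(table, "log"))
  withCallingHandlers(
    {
      pp <- preprocess_measures(table, config$preprocess)
      fits <- fit_growth_curves(pp, method = config$method,
                                model = config$model, start = config$start,
                                spar = config$spar)
    },
    warning = function(w) {
      note("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  log_base <- if (identical(config$preprocess$log_base, "none")) NULL
              else config$preprocess$log_base
  summary <- summarize_growth_curves(fits, grid_size = config$grid_size,
                                     log_base = log_base)
  quality <- quality_growth_curves(fits)
  note("fitted ", sum(!vapply(fits$fit, is.null, logical(1))), " of ",
       nrow(fits), " wells with method '", config$method, "'")

  dcols <- sort(design_columns(pp))
  if (length(dcols)) {
    per_well <- dplyr::distinct(
      pp[c("run", "plate", "well", dcols)],
      .data$run, .data$plate, .data$well, .keep_all = TRUE)
    summary <- dplyr::left_join(summary, per_well,
                                by = c("run", "plate", "well"))
  }

  measures_out <- dplyr::rename(pp, measure_raw = "measure")
  lead <- intersect(c("run", "plate", "well", "runtime", "datetime",
                      "measure_type", "measure_raw", "measure_preprocessed"),
                    names(measures_out))
  measures_out <- measures_out[c(lead, dcols)]
  mcols <- intersect(metric_columns, names(summary))
  summary <- summary[c("run", "plate", "well", "method", mcols, dcols)]

  gmeans <- NULL
  if (!is.null(config$groups) && nzchar(trimws(config$groups))) {
    shape <- infer_plate_shape(unique(table$well))
    specs <- parse_group_shorthand(config$groups, shape,
                                   plates = unique(table$plate))
    note("parsed ", length(specs), " group spec(s)")
    withCallingHandlers(
      {
        summary <- apply_groups(summary, specs)
        measures_out <- apply_groups(measures_out, specs)
      },
      warning = function(w) {
        note("warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    gmeans <- group_means(summary)
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measures = file.path(config$outdir, "measures.csv"),
             summary = file.path(config$outdir, "summary.csv"),
             quality = file.path(config$outdir, "quality.csv"))
  readr::write_csv(measures_out, paths[["measures"]], na = "")
  readr::write_csv(summary, paths[["summary"]], na = "")
  readr::write_csv(quality, paths[["quality"]], na = "")
  if (!is.null(gmeans)) {
    paths[["group_means"]] <- file.path(config$outdir, "group_means.csv")
    readr::write_csv(gmeans, paths[["group_means"]], na = "")
  }
  paths[["log"]] <- file.path(config$outdir, "run.log")
  writeLines(log, paths[["log"]])

  invisible(list(measures = measures_out, summary = summary,
                 quality = quality, group_means = gmeans, fits = fits,
                 paths = paths, log = log))
}
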