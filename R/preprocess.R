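# Six-step per-well preprocessing chain, applied in fixed order:
# log-ratio transform -> running median -> running mean -> enforce
# increasing -> background formula -> calibration formula.

#' Log-ratio transform of a measure vector
#'
#' Computes `log_base(y / min(y))`, so the minimum measure maps to exactly 0.
#' The minimum is used rather than the first measure to be robust to noisy
#' initial readings. Sigmoid growth models assume this kind of log(N/N0)
#' scale.
#'
#' @param y Numeric measure vector, all values > 0.
#' @param base Log base: a number, or `"e"`/`"2"`/`"10"`.
#' @return Transformed vector; if any `y <= 0` the input is returned
#'   unchanged with a warning (the well should be flagged upstream).
#' @examples
#' log_ratio_transform(c(2, 4, 8), base = 2)
#' @export
log_ratio_transform <- function(y, base = exp(1)) {
  base <- resolve_log_base(base)
  if (any(y <= 0, na.rm = TRUE)) {
    warning("nonpositive measures; log-ratio transform skipped for this well",
            call. = FALSE)
    return(y)
  }
  log(y / min(y, na.rm = TRUE), base = base)
}

resolve_log_base <- function(base) {
  if (is.character(base)) {
    base <- switch(base,
      "e" = exp(1), "2" = 2, "10" = 10,
      stop("unknown log base '", base, "'; use 2, 'e' or 10", call. = FALSE))
  }
  if (!is.numeric(base) || base <= 0 || base == 1) {
    stop("log base must be a positive number != 1", call. = FALSE)
  }
  base
}

check_window <- function(k, n, what) {
  if (length(k) != 1L || k != round(k) || k < 1L || k %% 2L == 0L || k >= n) {
    stop(what, " window must be an odd integer >= 1 and less than the number ",
         "of points per well (", n, "); got ", k, call. = FALSE)
  }
  as.integer(k)
}

running_window <- function(y, k, fun) {
  n <- length(y)
  h <- (k - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    # window shrinks symmetrically at the edges: width 1, 3, ..., k
    hw <- min(h, i - 1L, n - i)
    out[i] <- fun(y[(i - hw):(i + hw)])
  }
  out
}

#' Running median and running mean smoothing
#'
#' Centered windows of odd width `k`; at the edges the window shrinks
#' symmetrically (widths 1, 3, ..., k), so the output has the input's length
#' and no padding artifacts. Median smoothing removes high-amplitude spikes
#' at single time points; mean smoothing damps low-amplitude high-frequency
#' noise. The two are typically applied in that order.
#'
#' @param y Numeric vector.
#' @param k Odd window width, `1 <= k < length(y)`.
#' @return Smoothed vector, same length as `y`.
#' @examples
#' running_median(c(0, 0, 10, 0, 0), k = 3)
#' @export
running_median <- function(y, k) {
  k <- check_window(k, length(y), "median")
  if (k == 1L) return(y)
  running_window(y, k, stats::median)
}

#' @rdname running_median
#' @export
running_mean <- function(y, k) {
  k <- check_window(k, length(y), "mean")
  if (k == 1L) return(y)
  running_window(y, k, mean)
}

#' Force a measure vector to be non-decreasing
#'
#' Each measure smaller than its predecessor is replaced by that predecessor,
#' i.e. the running maximum. This reduces bias from bubbles, aggregation or
#' precipitation artifacts that transiently depress the optical signal.
#'
#' @param y Numeric vector.
#' @return Non-decreasing vector, same length.
#' @examples
#' enforce_increasing(c(1, 2, 1.5, 3))
#' @export
enforce_increasing <- function(y) {
  cummax(y)
}

#' Preprocessing configuration
#'
#' Bundles the six preprocessing options. Windows must be odd and smaller
#' than the number of points per well; `log_base = "none"` (or `NULL`)
#' disables the log-ratio transform; `background` and `calibration` are
#' well-mode formula strings (see [parse_formula()]) or `NULL`.
#'
#' @param log_base `"none"`, `"2"`, `"e"`, `"10"` or a number.
#' @param median_window,mean_window Odd integer window widths (1 = off).
#' @param enforce_increasing Logical.
#' @param background,calibration Optional formula strings over `y` and `x`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(log_base = "none", median_window = 1L,
                              mean_window = 1L, enforce_increasing = FALSE,
                              background = NULL, calibration = NULL) {
  if (!identical(log_base, "none") && !is.null(log_base)) resolve_log_base(log_base)
  for (f in c(background, calibration)) parse_formula(f, "well")
  structure(list(log_base = log_base %||% "none",
                 median_window = as.integer(median_window),
                 mean_window = as.integer(mean_window),
                 enforce_increasing = isTRUE(enforce_increasing),
                 background = background, calibration = calibration),
            class = "preprocess_config")
}

#' Preprocess one well's measures
#'
#' Applies the chain in fixed order: log-ratio transform, running median,
#' running mean, enforce-increasing, background formula, calibration formula.
#' Disabled steps are identities.
#'
#' @param y Numeric measure vector.
#' @param x Numeric runtime vector (used by formulas), same length.
#' @param config A [preprocess_config()].
#' @return Preprocessed vector, same length as `y`.
#' @export
preprocess_well <- function(y, x = seq_along(y), config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- y
  if (!identical(config$log_base, "none")) {
    out <- log_ratio_transform(out, config$log_base)
  }
  if (config$median_window > 1L) out <- running_median(out, config$median_window)
  if (config$mean_window > 1L) out <- running_mean(out, config$mean_window)
  if (config$enforce_increasing) out <- enforce_increasing(out)
  if (!is.null(config$background)) out <- eval_well_formula(config$background, out, x)
  if (!is.null(config$calibration)) out <- eval_well_formula(config$calibration, out, x)
  out
}

#' Preprocess every well of a tidy measures table
#'
#' Adds a `measure_preprocessed` column next to the raw `measure`. Wells
#' whose preprocessing fails, or that end up with fewer than `min_points`
#' finite values, are flagged in the `excluded_wells` attribute (and a
#' warning) so downstream fitting can skip them.
#'
#' @param table Tidy measures tibble.
#' @param config A [preprocess_config()].
#' @param min_points Minimum finite points a well must retain (default 5).
#' @return The table with a `measure_preprocessed` column; attribute
#'   `excluded_wells` lists flagged (run, plate, well) keys.
#' @export
preprocess_measures <- function(table, config = preprocess_config(),
                                min_points = 5L) {
  stopifnot(inherits(config, "preprocess_config"))
  excluded <- character(0)
  out <- table |>
    dplyr::group_by(.data$run, .data$plate, .data$well) |>
    dplyr::group_modify(function(df, key) {
      label <- paste(key$run, key$plate, key$well, sep = "/")
      res <- tryCatch(
        preprocess_well(df$measure, df$runtime, config),
        error = function(e) {
          warning("well ", label, " failed preprocessing: ",
                  conditionMessage(e), call. = FALSE)
          rep(NA_real_, nrow(df))
        })
      if (sum(is.finite(res)) < min_points) excluded <<- c(excluded, label)
      df$measure_preprocessed <- res
      df
    }) |>
    dplyr::ungroup()
  if (length(excluded)) {
    warning("well(s) with fewer than ", min_points,
            " usable points excluded from fitting: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  attr(out, "units") <- attr(table, "units")
  attr(out, "excluded_wells") <- excluded
  out
}
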