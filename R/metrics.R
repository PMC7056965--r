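# Per-well summary metrics extracted from a fitted curve on a uniform
# evaluation grid, plus per-group means.

metric_columns <- c("max_y_x", "max_y_y", "max_dy_m", "max_dy_x", "max_dy_y",
                    "max_dy_b", "max_dy_x0", "fit_int", "A", "mu", "lambda",
                    "nu", "min_doubling_time")

#' Summary metrics of a fitted growth curve
#'
#' Evaluates the fit and its derivative on a uniform grid of `grid_size`
#' points over the observed time domain and extracts:
#' \describe{
#'   \item{max_y_x, max_y_y}{time (first occurrence) and value of the curve
#'     maximum}
#'   \item{max_dy_m}{maximum slope of the curve}
#'   \item{max_dy_x, max_dy_y}{location of the maximum slope on the curve}
#'   \item{max_dy_b}{y-intercept of the tangent line at the maximum slope:
#'     `max_dy_y - max_dy_m * max_dy_x`}
#'   \item{max_dy_x0}{x-intercept of that tangent, `-max_dy_b / max_dy_m`
#'     (the lag time for sigmoid curves)}
#'   \item{fit_int}{trapezoidal integral of the fitted curve over the
#'     observed domain (area under the curve)}
#'   \item{A, mu, lambda, nu}{model coefficients, when the method provides
#'     them}
#'   \item{min_doubling_time}{see [min_doubling_time()]}
#' }
#' Maxima are taken at the first grid index attaining the global maximum.
#' For flat curves (max slope <= 1e-12) the tangent intercepts and doubling
#' time are `NA`.
#'
#' @param fit A `gc_fit`.
#' @param grid_size Number of grid points (default 1000).
#' @param log_base Log base of the preprocessing, if measures were
#'   log-transformed upstream (passed to [min_doubling_time()]).
#' @return A one-row tibble with the metric columns above.
#' @export
summarize_fit <- function(fit, grid_size = 1000L, log_base = NULL) {
  stopifnot(inherits(fit, "gc_fit"))
  grid <- seq(fit$domain[1L], fit$domain[2L], length.out = grid_size)
  yhat <- fit$predict(grid)
  dy <- fit$derivative(grid)

  i_ymax <- which.max(yhat)
  out <- tibble::tibble(
    max_y_x = grid[i_ymax],
    max_y_y = yhat[i_ymax],
    max_dy_m = NA_real_, max_dy_x = NA_real_, max_dy_y = NA_real_,
    max_dy_b = NA_real_, max_dy_x0 = NA_real_,
    fit_int = sum(diff(grid) * (utils::head(yhat, -1L) + utils::tail(yhat, -1L)) / 2),
    A = fit$coefficients[["A"]] %0% NA_real_,
    mu = fit$coefficients[["mu"]] %0% NA_real_,
    lambda = fit$coefficients[["lambda"]] %0% NA_real_,
    nu = fit$coefficients[["nu"]] %0% NA_real_,
    min_doubling_time = NA_real_)

  i_dmax <- which.max(dy)
  m <- dy[i_dmax]
  if (is.finite(m) && m > 1e-12) {
    out$max_dy_m <- m
    out$max_dy_x <- grid[i_dmax]
    out$max_dy_y <- yhat[i_dmax]
    out$max_dy_b <- out$max_dy_y - m * out$max_dy_x
    out$max_dy_x0 <- -out$max_dy_b / m
    out$min_doubling_time <- min_doubling_time(fit, log_base = log_base,
                                               grid = grid, yhat = yhat,
                                               dy = dy)
  }
  out
}

`%0%` <- function(a, b) tryCatch(a, error = function(e) b)

#' Minimum doubling time of a fitted curve
#'
#' `ln(2) / mu_star`, where `mu_star` is the maximum specific (log-scale)
#' growth rate over the evaluation grid. On a linear-scale fit,
#' `mu_star = max d ln(f)/dt = max f'/f`, evaluated only where the fitted
#' curve exceeds 1 percent of its maximum: a sigmoid's specific rate
#' diverges as the curve approaches zero, so values below the detection
#' floor are numerical artifacts, not growth rates. (With log-ratio
#' preprocessing the metric needs no such guard; prefer that route when
#' doubling times are of interest.) If the measures were already
#' log_b-transformed upstream, the fit is on log scale and
#' `mu_star = ln(b) * max f'`.
#'
#' @param fit A `gc_fit`.
#' @param log_base Upstream log base (number, or `"2"`/`"e"`/`"10"`), or
#'   `NULL` for linear-scale measures.
#' @param grid,yhat,dy Optional precomputed evaluation grid.
#' @param grid_size Grid size when not precomputed.
#' @return The minimum doubling time in the runtime unit, or `NA` when the
#'   maximum specific growth rate is not positive.
#' @examples
#' t <- seq(0, 200, length.out = 100)
#' f <- fit_spline(t, exp(0.02 * t))
#' min_doubling_time(f) # ~ log(2) / 0.02
#' @export
min_doubling_time <- function(fit, log_base = NULL, grid = NULL, yhat = NULL,
                              dy = NULL, grid_size = 1000L) {
  if (is.null(grid)) {
    grid <- seq(fit$domain[1L], fit$domain[2L], length.out = grid_size)
    yhat <- fit$predict(grid)
    dy <- fit$derivative(grid)
  }
  if (!is.null(log_base) && !identical(log_base, "none")) {
    b <- resolve_log_base(log_base)
    mu_star <- log(b) * max(dy, na.rm = TRUE)
  } else {
    floor_y <- 0.01 * max(c(yhat[is.finite(yhat)], 0))
    pos <- is.finite(yhat) & yhat > 0 & yhat >= floor_y & is.finite(dy)
    if (!any(pos)) return(NA_real_)
    rates <- dy[pos] / yhat[pos]
    # the maximum often sits exactly at the floor crossing; evaluate the fit
    # at the interpolated crossing time so the result is grid-stable
    cross <- which(!pos[-length(pos)] & pos[-1L])
    for (i in cross) {
      if (is.finite(yhat[i]) && yhat[i + 1L] != yhat[i]) {
        tc <- grid[i] + (floor_y - yhat[i]) / (yhat[i + 1L] - yhat[i]) *
          (grid[i + 1L] - grid[i])
        fc <- fit$predict(tc)
        if (is.finite(fc) && fc > 0) {
          rates <- c(rates, fit$derivative(tc) / fc)
        }
      }
    }
    mu_star <- max(rates)
  }
  if (!is.finite(mu_star) || mu_star <= 0) return(NA_real_)
  log(2) / mu_star
}

#' Summarize every fitted well of an experiment
#'
#' Maps [summarize_fit()] over a fit table from [fit_growth_curves()].
#'
#' @param fits Tibble with run/plate/well/method and a `fit` list-column.
#' @param grid_size Evaluation grid size per well.
#' @param log_base Upstream log base (see [min_doubling_time()]).
#' @return Tibble: run, plate, well, method, then the metric columns.
#' @export
summarize_growth_curves <- function(fits, grid_size = 1000L, log_base = NULL) {
  rows <- purrr::pmap(fits, function(run, plate, well, method, fit) {
    if (is.null(fit)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(run = run, plate = plate, well = well, method = method),
      summarize_fit(fit, grid_size = grid_size, log_base = log_base))
  })
  dplyr::bind_rows(rows)
}

#' Quality statistics for every fitted well
#'
#' @param fits Tibble from [fit_growth_curves()].
#' @return Tibble: run, plate, well, method, then the method's quality
#'   columns (spline: spar, df, crit, penalized_rss, cv.crit; parametric:
#'   sigma, isConv, finTol, logLik, AIC, BIC, deviance, df.residual).
#' @export
quality_growth_curves <- function(fits) {
  rows <- purrr::pmap(fits, function(run, plate, well, method, fit) {
    if (is.null(fit)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(run = run, plate = plate, well = well, method = method),
      quality_stats(fit))
  })
  dplyr::bind_rows(rows)
}

#' Per-group means of summary metrics
#'
#' Given a summary table carrying `group` and `is_ref` columns (see
#' [apply_groups()]), computes the mean of every numeric metric within each
#' (group, is_ref) stratum. Missing values are excluded pairwise; `n_wells`
#' counts the wells in the stratum.
#'
#' @param summary Grouped summary tibble.
#' @return Tibble with one row per (group, is_ref) stratum.
#' @export
group_means <- function(summary) {
  if (!all(c("group", "is_ref") %in% names(summary))) {
    stop("summary table must carry group/is_ref columns; see apply_groups()",
         call. = FALSE)
  }
  summary |>
    dplyr::group_by(.data$group, .data$is_ref) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      dplyr::across(dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
}
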