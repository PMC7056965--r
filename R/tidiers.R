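# broom-style accessors for fitted curves.

#' Turn model objects into tidy tibbles
#'
#' `tidy()` returns one row per model coefficient; `glance()` returns a
#' one-row summary with the fit-quality statistics (see [quality_stats()]).
#'
#' @param x A fitted object (here: a `gc_fit`).
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.gc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy
#' @export
glance.gc_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method, n_points = x$n_points,
                   converged = x$converged),
    quality_stats(x))
}

#' Plot a fitted growth curve over its data
#'
#' Points are the (preprocessed) measures, the solid line the fitted curve,
#' and the shaded segments the residual error.
#'
#' @param object A `gc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gc_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$data$x, y = object$data$y,
                       yhat = object$predict(object$data$x))
  grid <- tibble::tibble(x = seq(object$domain[1L], object$domain[2L],
                                 length.out = 200L))
  grid$yhat <- object$predict(grid$x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x, y = .data$y,
                                       yend = .data$yhat),
                          color = "red", alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$yhat)) +
    ggplot2::labs(x = "runtime", y = "measure",
                  title = paste(object$method, "fit")) +
    ggplot2::theme_minimal()
}
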