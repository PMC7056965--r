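# Curve fitting: model-free smoothing spline, the three named sigmoid growth
# models in the Zwietering (A, mu, lambda) reparameterization, and arbitrary
# user models from the formula mini-language. Nonlinear least squares is
# Levenberg-Marquardt (minpack.lm::nls.lm) with box bounds.

# ---- named sigmoid models ----------------------------------------------

# Zwietering-reparameterized models: A = asymptote, mu = maximum slope,
# lambda = lag time (x-intercept of the tangent at the inflection point).
named_models <- list(
  gompertz = list(
    params = c("A", "mu", "lambda"),
    fn = function(t, p) {
      u <- (p[["mu"]] * exp(1) / p[["A"]]) * (p[["lambda"]] - t) + 1
      p[["A"]] * exp(-exp(u))
    },
    grad = function(t, p) {
      u <- (p[["mu"]] * exp(1) / p[["A"]]) * (p[["lambda"]] - t) + 1
      p[["mu"]] * exp(1) * exp(u) * exp(-exp(u))
    }
  ),
  logistic = list(
    params = c("A", "mu", "lambda"),
    fn = function(t, p) {
      v <- (4 * p[["mu"]] / p[["A"]]) * (p[["lambda"]] - t) + 2
      p[["A"]] / (1 + exp(v))
    },
    grad = function(t, p) {
      v <- (4 * p[["mu"]] / p[["A"]]) * (p[["lambda"]] - t) + 2
      4 * p[["mu"]] * exp(v) / (1 + exp(v))^2
    }
  ),
  richards = list(
    params = c("A", "mu", "lambda", "nu"),
    fn = function(t, p) {
      nu <- p[["nu"]]
      cc <- (p[["mu"]] / p[["A"]]) * (1 + nu)^(1 + 1 / nu)
      w <- nu * exp(1 + nu) * exp(cc * (p[["lambda"]] - t))
      p[["A"]] * (1 + w)^(-1 / nu)
    },
    grad = function(t, p) {
      nu <- p[["nu"]]
      cc <- (p[["mu"]] / p[["A"]]) * (1 + nu)^(1 + 1 / nu)
      w <- nu * exp(1 + nu) * exp(cc * (p[["lambda"]] - t))
      (p[["A"]] * cc / nu) * w * (1 + w)^(-1 / nu - 1)
    }
  )
)

#' Evaluate a named sigmoid growth model
#'
#' The Gompertz, logistic and Richards models in the (A, mu, lambda)
#' reparameterization, where A is the asymptotic growth limit, mu the maximum
#' slope and lambda the lag time (x-intercept of the tangent line at the
#' point of maximum slope). Richards has the additional shape parameter nu
#' (nu = 1 reduces it to the logistic).
#'
#' @param t Numeric time vector.
#' @param model `"gompertz"`, `"logistic"` or `"richards"`.
#' @param A,mu,lambda,nu Model parameters.
#' @return Numeric vector of model values.
#' @examples
#' growth_model(0:10, "gompertz", A = 1, mu = 0.5, lambda = 2)
#' @export
growth_model <- function(t, model, A, mu, lambda, nu = 1) {
  m <- named_models[[match.arg(model, names(named_models))]]
  m$fn(t, list(A = A, mu = mu, lambda = lambda, nu = nu))
}

# Heuristic self-starting estimates shared by all named models:
# A0 = max(y); mu0 = largest finite-difference slope; lambda0 = x-intercept
# of the tangent through the max-slope point, clamped to [0, t_max]; nu0 = 1.
self_start <- function(x, y, params) {
  slopes <- diff(y) / diff(x)
  ok <- is.finite(slopes)
  mu0 <- if (any(ok)) max(slopes[ok]) else NA_real_
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- max(abs(y)) / diff(range(x))
  i <- which.max(replace(slopes, !ok, -Inf))
  tstar <- (x[i] + x[i + 1L]) / 2
  ystar <- (y[i] + y[i + 1L]) / 2
  lambda0 <- min(max(tstar - ystar / mu0, 0), max(x))
  start <- c(A = max(y), mu = mu0, lambda = lambda0, nu = 1)[params]
  if (start[["A"]] <= 0) start[["A"]] <- 1e-6
  start
}

# ---- least-squares engine ----------------------------------------------

# Levenberg-Marquardt with box bounds; 200 iterations, relative tolerance
# 1e-8. Returns the last iterate even on non-convergence, with a flag.
fit_ls <- function(x, y, pred_fn, start, lower = NULL, upper = NULL) {
  par0 <- as.list(start)
  resid_fn <- function(par) {
    r <- y - pred_fn(x, as.list(par))
    r[!is.finite(r)] <- 1e6
    r
  }
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, fn = resid_fn,
      lower = if (is.null(lower)) rep(-Inf, length(start)) else lower,
      upper = if (is.null(upper)) rep(Inf, length(start)) else upper,
      control = minpack.lm::nls.lm.control(maxiter = 200L,
                                           ftol = 1e-8, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(res)) {
    return(list(par = unlist(par0), converged = FALSE, fin_tol = NA_real_,
                deviance = sum(resid_fn(par0)^2), niter = 0L))
  }
  trace <- res$rsstrace
  fin_tol <- if (length(trace) >= 2L) {
    abs(diff(utils::tail(trace, 2L))) / max(utils::tail(trace, 1L), 1e-300)
  } else 0
  list(par = unlist(res$par), converged = res$info %in% 1:4,
       fin_tol = fin_tol, deviance = res$deviance, niter = res$niter)
}

# ---- fit result container ----------------------------------------------

new_gc_fit <- function(method, coefficients, predict, derivative, x, y,
                       converged, quality) {
  structure(
    list(method = method, coefficients = coefficients, predict = predict,
         derivative = derivative, n_points = length(x), converged = converged,
         domain = range(x), quality = quality, data = list(x = x, y = y)),
    class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat("<growth-curve fit:", x$method, "|", x$n_points, "points | converged:",
      x$converged, ">\n")
  if (length(x$coefficients)) {
    print(round(x$coefficients, 6))
  }
  invisible(x)
}

#' Predict from a growth-curve fit
#'
#' @param object A `gc_fit`.
#' @param t Times at which to evaluate (defaults to the observed times).
#' @param deriv 0 for the fitted curve, 1 for its first derivative.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.gc_fit <- function(object, t = object$data$x, deriv = 0, ...) {
  if (deriv == 0) object$predict(t) else object$derivative(t)
}

#' Residual sum of squares of a fit
#' @param object A `gc_fit`.
#' @param ... Unused.
#' @export
deviance.gc_fit <- function(object, ...) {
  sum((object$data$y - object$predict(object$data$x))^2)
}

# ---- quality statistics -------------------------------------------------

#' Fit-quality statistics
#'
#' Gaussian residual-sum-of-squares statistics for a parametric fit:
#' `logLik = -n/2 * (log(2*pi) + log(RSS/n) + 1)`; `AIC = 2(p+1) - 2 logLik`
#' and `BIC = log(n)(p+1) - 2 logLik` (the error variance counts as one
#' parameter); `deviance = RSS`; `df.residual = n - p`;
#' `sigma = sqrt(RSS / (n - p))`. RSS is floored at 1e-300 so a perfect fit
#' reports a large finite log-likelihood instead of overflowing. For spline
#' fits the smoothing-specific statistics (spar, df, crit, penalized RSS,
#' cross-validation score) are reported instead.
#'
#' @param fit A `gc_fit`.
#' @param x,y Data to score against (default: the data the fit was built on).
#' @return A one-row tibble of quality statistics.
#' @export
quality_stats <- function(fit, x = fit$data$x, y = fit$data$y) {
  if (fit$method == "spline") return(fit$quality)
  n <- length(y)
  p <- length(fit$coefficients)
  rss <- max(sum((y - fit$predict(x))^2), 1e-300)
  if (n <= p) {
    warning("n <= number of parameters; quality statistics unavailable",
            call. = FALSE)
    return(tibble::tibble(sigma = NA_real_, isConv = fit$converged,
                          finTol = fit$quality$finTol, logLik = NA_real_,
                          AIC = NA_real_, BIC = NA_real_, deviance = rss,
                          df.residual = n - p))
  }
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  tibble::tibble(
    sigma = sqrt(rss / (n - p)),
    isConv = fit$converged,
    finTol = fit$quality$finTol,
    logLik = ll,
    AIC = 2 * (p + 1) - 2 * ll,
    BIC = log(n) * (p + 1) - 2 * ll,
    deviance = rss,
    df.residual = n - p)
}

# ---- fitting front ends -------------------------------------------------

#' Fit a cubic smoothing spline to one well
#'
#' Model-free fit via [stats::smooth.spline()]. When `spar` is not supplied
#' the smoothing parameter is chosen by generalized cross-validation. The
#' derivative is the spline's analytic derivative. Duplicate time points
#' (e.g. after unit conversion) are averaged with a warning.
#'
#' @param x Strictly increasing numeric time vector (>= 5 points).
#' @param y Numeric measures.
#' @param spar Optional smoothing parameter in [0, 1].
#' @return A `gc_fit` with quality columns `spar`, `df`, `crit`,
#'   `penalized_rss` and `cv.crit` (the GCV score).
#' @export
fit_spline <- function(x, y, spar = NULL) {
  if (anyDuplicated(x)) {
    warning("duplicate time points averaged before spline fit", call. = FALSE)
    agg <- tapply(y, x, mean)
    x <- as.numeric(names(agg))
    y <- as.numeric(agg)
  }
  if (length(x) < 5L) stop("spline fit needs >= 5 points", call. = FALSE)
  sf <- if (is.null(spar)) {
    stats::smooth.spline(x, y, cv = FALSE, keep.data = FALSE)
  } else {
    stats::smooth.spline(x, y, spar = spar, cv = FALSE, keep.data = FALSE)
  }
  quality <- tibble::tibble(
    spar = sf$spar,
    df = sf$df,
    crit = sf$crit,
    penalized_rss = sf$pen.crit,
    cv.crit = sf$cv.crit)
  new_gc_fit(
    method = "spline",
    coefficients = numeric(0),
    predict = function(t) stats::predict(sf, t)$y,
    derivative = function(t) stats::predict(sf, t, deriv = 1L)$y,
    x = x, y = y, converged = TRUE, quality = quality)
}

#' Fit a named sigmoid growth model to one well
#'
#' Fits the Gompertz, logistic or Richards model (see [growth_model()]) by
#' bounded Levenberg-Marquardt least squares with self-starting initial
#' values: `A0 = max(y)`, `mu0` the largest finite-difference slope,
#' `lambda0` the tangent x-intercept at the max-slope point clamped to
#' `[0, max(x)]`, `nu0 = 1`. Bounds: A > 0, mu > 0, lambda >= 0 (nu > 0).
#' Non-convergence is not fatal: the last iterate is returned with
#' `converged = FALSE`.
#'
#' @param x,y Numeric time and measure vectors.
#' @param model `"gompertz"`, `"logistic"` or `"richards"`.
#' @param start Optional named vector overriding the self-starts.
#' @return A `gc_fit` with coefficients `A`, `mu`, `lambda` (and `nu`).
#' @examples
#' t <- seq(0, 400, length.out = 50)
#' y <- growth_model(t, "gompertz", A = 1, mu = 0.01, lambda = 100)
#' fit_named_model(t, y, "gompertz")
#' @export
fit_named_model <- function(x, y, model = c("gompertz", "logistic", "richards"),
                            start = NULL) {
  model <- match.arg(model)
  m <- named_models[[model]]
  if (length(x) < length(m$params) + 2L) {
    stop("need at least ", length(m$params) + 2L, " points to fit ", model,
         call. = FALSE)
  }
  st <- self_start(x, y, m$params)
  if (!is.null(start)) st[names(start)] <- start
  lower <- c(A = 1e-12, mu = 1e-12, lambda = 0, nu = 1e-6)[m$params]
  res <- fit_ls(x, y, m$fn, st, lower = lower)
  par <- res$par[m$params]
  plist <- as.list(par)
  if (!res$converged) {
    warning(model, " fit did not converge; returning last iterate",
            call. = FALSE)
  }
  fit <- new_gc_fit(
    method = model,
    coefficients = par,
    predict = function(t) m$fn(t, plist),
    derivative = function(t) m$grad(t, plist),
    x = x, y = y, converged = res$converged,
    quality = tibble::tibble(finTol = res$fin_tol))
  fit$quality <- quality_stats(fit)
  fit
}

#' Fit a user-specified model from the formula mini-language
#'
#' Least-squares fit of `y ~ f(x; parameters)` where `f` is a model-mode
#' formula (see [parse_formula()]). Starting values must cover every
#' parameter; they can be given as a named vector or as the comma-separated
#' text form accepted by [parse_start_values()]. The curve derivative is
#' obtained by symbolic differentiation of the model expression with respect
#' to `x` when the expression is smooth and closed-form; otherwise central
#' finite differences with step `1e-6 * diff(range(x))` are used.
#'
#' @param x,y Numeric time and measure vectors.
#' @param model A model formula string or `gc_formula`.
#' @param start Named numeric vector, or a string like `"a = 1, k = 3e-5"`.
#' @return A `gc_fit` with the user-named coefficients.
#' @examples
#' t <- seq(0, 1e5, length.out = 50)
#' y <- 1 - (1 - 0.5) * exp(-3e-5 * t)
#' fit_manual(t, y, "y ~ a - (a - w0) * exp(-k * x)",
#'            start = c(a = 2, w0 = 1, k = 6e-5))
#' @export
fit_manual <- function(x, y, model, start) {
  if (is.character(model)) model <- parse_formula(model, "model")
  stopifnot(inherits(model, "gc_formula"), model$mode == "model")
  if (is.character(start)) start <- parse_start_values(start, model$params)
  miss <- setdiff(model$params, names(start))
  if (length(miss)) {
    stop("missing start value(s) for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  start <- start[model$params]
  pred_fn <- function(t, p) eval_model_formula(model, t, p)
  res <- fit_ls(x, y, pred_fn, start)
  par <- res$par[model$params]
  plist <- as.list(par)
  if (!res$converged) {
    warning("manual model fit did not converge; returning last iterate",
            call. = FALSE)
  }
  predict_fn <- function(t) pred_fn(t, plist)
  derivative_fn <- if (ast_differentiable(model$ast)) {
    dlang <- stats::D(ast_to_lang(model$ast), "x")
    function(t) {
      env <- list2env(plist)
      env$x <- t
      rep_len(eval(dlang, env), length(t))
    }
  } else {
    h <- 1e-6 * diff(range(x))
    function(t) (predict_fn(t + h) - predict_fn(t - h)) / (2 * h)
  }
  fit <- new_gc_fit(
    method = "manual",
    coefficients = par,
    predict = predict_fn,
    derivative = derivative_fn,
    x = x, y = y, converged = res$converged,
    quality = tibble::tibble(finTol = res$fin_tol))
  fit$quality <- quality_stats(fit)
  fit
}

#' Fit every well of a (preprocessed) measures table
#'
#' Applies one of the five estimation methods to each well and returns a
#' nested tibble with one row per well and the `gc_fit` objects in a `fit`
#' list-column. Uses `measure_preprocessed` when present, raw `measure`
#' otherwise. Wells flagged by [preprocess_measures()] or with fewer than 5
#' usable points are skipped with a warning.
#'
#' @param table Tidy measures tibble.
#' @param method `"spline"`, `"gompertz"`, `"logistic"`, `"richards"` or
#'   `"manual"`.
#' @param model,start Manual-mode model formula and start values.
#' @param spar Optional spline smoothing parameter.
#' @return Tibble: run, plate, well, method, fit (list-column).
#' @export
fit_growth_curves <- function(table, method = c("spline", "gompertz",
                                                "logistic", "richards",
                                                "manual"),
                              model = NULL, start = NULL, spar = NULL) {
  method <- match.arg(method)
  if (method == "manual") {
    if (is.null(model) || is.null(start)) {
      stop("manual method requires `model` and `start`", call. = FALSE)
    }
    if (is.character(model)) model <- parse_formula(model, "model")
    if (is.character(start)) start <- parse_start_values(start, model$params)
  }
  ycol <- if ("measure_preprocessed" %in% names(table)) "measure_preprocessed"
          else "measure"
  excluded <- attr(table, "excluded_wells") %||% character(0)
  table |>
    dplyr::group_by(.data$run, .data$plate, .data$well) |>
    dplyr::group_modify(function(df, key) {
      label <- paste(key$run, key$plate, key$well, sep = "/")
      keep <- is.finite(df[[ycol]]) & is.finite(df$runtime)
      if (label %in% excluded || sum(keep) < 5L) {
        warning("skipping well ", label, " (too few usable points)",
                call. = FALSE)
        return(tibble::tibble(method = method, fit = list(NULL)))
      }
      x <- df$runtime[keep]
      y <- df[[ycol]][keep]
      fit <- tryCatch(
        switch(method,
          spline = fit_spline(x, y, spar = spar),
          manual = fit_manual(x, y, model, start),
          fit_named_model(x, y, method)),
        error = function(e) {
          warning("well ", label, " fit failed: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
      tibble::tibble(method = method, fit = list(fit))
    }) |>
    dplyr::ungroup()
}
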