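test_that("smoothing spline reproduces simple curves and their slopes", {
  x <- seq(0, 50, length.out = 60)
  fit <- fit_spline(x, 0.2 * x)
  expect_lt(max(abs(fit$predict(x) - 0.2 * x)), 1e-6)
  expect_named(fit$quality, c("spar", "df", "crit", "penalized_rss", "cv.crit"))
  # heavier smoothing -> fewer equivalent degrees of freedom
  t <- seq(0, 400, length.out = 100)
  y <- growth_model(t, "gompertz", A = 1, mu = 0.01, lambda = 100) +
    stats::rnorm(100, 0, 0.005)
  df_light <- fit_spline(t, y, spar = 0.2)$quality$df
  df_heavy <- fit_spline(t, y, spar = 1.0)$quality$df
  expect_lt(df_heavy, df_light)
  # spline max slope approximates the generating model's mu within 2%
  t <- seq(0, 400, length.out = 200)
  sf <- fit_spline(t, growth_model(t, "gompertz", A = 1, mu = 0.01,
                                   lambda = 100))
  grid <- seq(0, 400, length.out = 1000)
  expect_lt(abs(max(sf$derivative(grid)) - 0.01) / 0.01, 0.02)
  expect_warning(fit_spline(c(1, 1, 2, 3, 4, 5), c(1, 2, 3, 4, 5, 6)),
                 "duplicate")
})

test_that("named sigmoid fits recover their own noiseless parameters", {
  t <- seq(0, 400, length.out = 100)
  truth <- c(A = 1, mu = 0.01, lambda = 100)
  for (model in c("gompertz", "logistic", "richards")) {
    y <- growth_model(t, model, A = 1, mu = 0.01, lambda = 100, nu = 1.3)
    fit <- fit_named_model(t, y, model)
    expect_true(fit$converged)
    expect_lt(deviance(fit), 1e-8)
    got <- fit$coefficients[names(truth)]
    want <- truth
    if (model == "richards") want <- c(truth, nu = 1.3)[names(fit$coefficients)]
    expect_lt(max(abs(fit$coefficients[names(want)] - want) / want), 1e-4)
  }
  # logistic self-fit is numerically exact
  y <- growth_model(t, "logistic", A = 1.2, mu = 0.02, lambda = 50)
  expect_lt(deviance(fit_named_model(t, y, "logistic")), 1e-10)
})

test_that("Richards with nu = 1 collapses to the logistic", {
  t <- seq(0, 400, length.out = 120)
  y <- growth_model(t, "logistic", A = 1, mu = 0.01, lambda = 100)
  expect_equal(growth_model(t, "richards", A = 1, mu = 0.01, lambda = 100,
                            nu = 1), y, tolerance = 1e-12)
  fl <- fit_named_model(t, y, "logistic")
  fr <- fit_named_model(t, y, "richards")
  for (p in c("A", "mu", "lambda")) {
    expect_lt(abs(fr$coefficients[[p]] - fl$coefficients[[p]]) /
                abs(fl$coefficients[[p]]), 1e-3)
  }
})

test_that("manual models fit through the formula engine", {
  # constant and linear closed forms
  cf <- fit_manual(c(0, 1, 2), c(2, 2, 2), "y ~ c", start = c(c = 5))
  expect_equal(unname(cf$coefficients[["c"]]), 2, tolerance = 1e-9)
  lf <- fit_manual(0:10, 2 * (0:10), "y ~ a*x", start = c(a = 9))
  expect_equal(unname(lf$coefficients[["a"]]), 2, tolerance = 1e-9)
  expect_lt(deviance(lf), 1e-18)
  # Brody recovery from perturbed starts
  t <- seq(0, 1e5, length.out = 200)
  y <- 1 - (1 - 0.5) * exp(-3e-5 * t)
  fit <- fit_manual(t, y, "y ~ a - (a - w0) * exp(-k * x)",
                    start = "a = 2, w0 = 1, k = 0.00006")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), c(1, 0.5, 3e-5), tolerance = 1e-6)
  expect_error(fit_manual(t, y, "y ~ a - (a - w0) * exp(-k * x)",
                          start = c(a = 2)), "missing start value")
})

test_that("quality statistics follow the Gaussian RSS formulas", {
  set.seed(21)
  t <- seq(0, 400, length.out = 50)
  y <- growth_model(t, "gompertz", A = 1, mu = 0.01, lambda = 100) +
    stats::rnorm(50, 0, 0.02)
  fit <- fit_named_model(t, y, "gompertz")
  q <- quality_stats(fit)
  n <- 50; p <- 3
  rss <- q$deviance
  expect_equal(q$sigma, sqrt(rss / (n - p)))
  expect_equal(q$df.residual, n - p)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  expect_equal(q$logLik, ll)
  expect_equal(q$AIC, 2 * (p + 1) - 2 * ll)
  expect_equal(q$BIC, log(n) * (p + 1) - 2 * ll)
  expect_true(q$isConv)
  expect_true(is.finite(q$finTol))
  # a perfect fit reports large finite statistics, not Inf (RSS floored)
  perfect <- fit_manual(0:9, 2 * (0:9), "y ~ a*x", start = c(a = 2))
  expect_true(is.finite(quality_stats(perfect)$logLik))
  # a useless extra parameter raises BIC on a well-fit curve
  y2 <- growth_model(t, "logistic", A = 1, mu = 0.01, lambda = 100) +
    stats::rnorm(50, 0, 0.01)
  expect_gt(quality_stats(fit_named_model(t, y2, "richards"))$BIC,
            quality_stats(fit_named_model(t, y2, "logistic"))$BIC)
})

test_that("analytic derivatives agree with central finite differences", {
  t <- seq(0, 400, length.out = 80)
  grid <- seq(5, 395, length.out = 100)
  h <- 1e-3
  check_deriv <- function(fit) {
    fd <- (fit$predict(grid + h) - fit$predict(grid - h)) / (2 * h)
    an <- fit$derivative(grid)
    expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-4)
  }
  for (model in c("gompertz", "logistic", "richards")) {
    y <- growth_model(t, model, A = 1, mu = 0.01, lambda = 100, nu = 1.2)
    check_deriv(fit_named_model(t, y, model))
  }
  y <- growth_model(t, "gompertz", A = 1, mu = 0.01, lambda = 100)
  check_deriv(fit_spline(t, y))
  tb <- seq(0, 1e5, length.out = 100)
  yb <- 1 - 0.5 * exp(-3e-5 * tb)
  gridb <- seq(1e3, 9e4, length.out = 100)
  fitb <- fit_manual(tb, yb, "y ~ a - (a - w0) * exp(-k * x)",
                     start = c(a = 1.2, w0 = 0.4, k = 2e-5))
  fdb <- (fitb$predict(gridb + 1) - fitb$predict(gridb - 1)) / 2
  expect_lt(max(abs(fitb$derivative(gridb) - fdb)) / max(abs(fdb)), 1e-4)
})

test_that("parameter recovery holds across 100 noisy synthetic wells", {
  sim <- simulate_experiment(sim_config(
    seed = 31, shape = plate_shape(8, 12), n_cycles = 94, baseline = 0,
    noise_sd = 0.01, spike_prob = 0, A_range = c(0.9, 1.3),
    mu_range = c(0.2, 0.4), lambda_range = c(3, 6), design = NULL))
  wells <- unique(sim$measures$well)
  rel_err <- purrr::map_dfr(wells, function(w) {
    d <- sim$measures[sim$measures$well == w, ]
    tr <- sim$truth[sim$truth$well == w, ]
    fit <- fit_named_model(d$runtime, d$measure, "gompertz")
    tibble::tibble(
      A = abs(fit$coefficients[["A"]] - tr$A) / tr$A,
      mu = abs(fit$coefficients[["mu"]] - tr$mu) / tr$mu,
      lambda = abs(fit$coefficients[["lambda"]] - tr$lambda) / tr$lambda)
  })
  expect_gte(nrow(rel_err), 96)
  expect_lt(stats::median(rel_err$A), 0.05)
  expect_lt(stats::median(rel_err$mu), 0.05)
  expect_lt(stats::median(rel_err$lambda), 0.05)
})

test_that("the well-level driver fits, skips and nests per well", {
  sim <- tiny_sim(seed = 5)
  fits <- fit_growth_curves(sim$measures, method = "gompertz")
  expect_equal(nrow(fits), 6L)
  expect_s3_class(fits$fit[[1]], "gc_fit")
  expect_equal(fits$method, rep("gompertz", 6))
  td <- tidy(fits$fit[[1]])
  expect_equal(td$term, c("A", "mu", "lambda"))
  gl <- glance(fits$fit[[1]])
  expect_true(all(c("sigma", "isConv", "logLik", "AIC", "BIC", "deviance",
                    "df.residual") %in% names(gl)))
  short <- as_tidy_measures(tibble::tibble(
    well = "A01", runtime = as.numeric(0:3), measure = c(1, 2, 3, 4)))
  expect_warning(f2 <- fit_growth_curves(short, method = "spline"),
                 "too few")
  expect_null(f2$fit[[1]])
  expect_error(fit_growth_curves(sim$measures, method = "manual"),
               "requires")
})
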