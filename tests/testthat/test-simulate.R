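test_that("simulation is a deterministic function of its config", {
  a <- simulate_experiment(sim_config(seed = 4, shape = plate_shape(2, 3),
                                      n_cycles = 15))
  b <- simulate_experiment(sim_config(seed = 4, shape = plate_shape(2, 3),
                                      n_cycles = 15))
  expect_identical(a$measures$measure, b$measures$measure)
  expect_identical(a$truth, b$truth)
  c <- simulate_experiment(sim_config(seed = 5, shape = plate_shape(2, 3),
                                      n_cycles = 15))
  expect_false(identical(a$measures$measure, c$measures$measure))
})

test_that("per-well substreams do not depend on plate shape or well order", {
  small <- simulate_experiment(sim_config(seed = 6, shape = plate_shape(2, 3),
                                          n_cycles = 10))
  large <- simulate_experiment(sim_config(seed = 6, shape = plate_shape(8, 12),
                                          n_cycles = 10))
  for (w in c("A01", "B03")) {
    expect_identical(small$truth[small$truth$well == w, c("A", "mu", "lambda")],
                     large$truth[large$truth$well == w, c("A", "mu", "lambda")])
  }
})

test_that("the noiseless limit reproduces the truth model exactly", {
  sim <- tiny_sim(seed = 7)
  d <- sim$measures[sim$measures$well == "A01", ]
  tr <- sim$truth[sim$truth$well == "A01", ]
  want <- growth_model(d$runtime, "gompertz", A = tr$A, mu = tr$mu,
                       lambda = tr$lambda)
  expect_equal(d$measure, want, tolerance = 1e-6)  # 6-decimal quantization
  # default-size experiment: 96 wells x 94 cycles = 9024 records
  full <- simulate_experiment(sim_config(seed = 8))
  expect_equal(nrow(full$measures), 9024L)
  expect_equal(nrow(full$truth), 96L)
  # case-study-like defaults carry the factorial design
  expect_setequal(unique(full$measures$strain), c("BY4743", "opi3", "swd3"))
  expect_equal(sort(unique(as.numeric(full$measures$dose_uM))),
               sort(c(50 / 2^(0:6), 0)))
})

test_that("spikes and baseline enter the simulated signal as configured", {
  base <- simulate_experiment(sim_config(seed = 9, shape = plate_shape(1, 3),
                                         n_cycles = 40, noise_sd = 0,
                                         spike_prob = 0, baseline = 0.25))
  tr <- base$truth[1, ]
  d <- base$measures[base$measures$well == "A01", ]
  expect_equal(d$measure,
               0.25 + growth_model(d$runtime, "gompertz", A = tr$A,
                                   mu = tr$mu, lambda = tr$lambda),
               tolerance = 1e-6)
  spiky <- simulate_experiment(sim_config(seed = 9, shape = plate_shape(1, 3),
                                          n_cycles = 40, noise_sd = 0,
                                          spike_prob = 0.5,
                                          spike_height = 10, baseline = 0.25))
  expect_gt(sum(spiky$measures$measure > 5), 0)
})

test_that("emitted fixture files are byte-identical across reruns", {
  cfg <- sim_config(seed = 10, shape = plate_shape(3, 4), n_cycles = 12)
  sim <- simulate_experiment(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  emit_fixture_files(sim, "long_csv", d1, cfg)
  emit_fixture_files(sim, "long_csv", d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # two runs emit run1/run2 measures + matching _design files
  cfg2 <- sim_config(seed = 11, n_runs = 2, shape = plate_shape(3, 4),
                     n_cycles = 12)
  d3 <- tempfile()
  emit_fixture_files(simulate_experiment(cfg2), "long_csv", d3, cfg2)
  expect_setequal(list.files(d3), c("run1.csv", "run1_design.csv",
                                    "run2.csv", "run2_design.csv"))
  # bioscreen dialect: Time column in hh:mm:ss with numeric headers
  cfgn <- sim_config(seed = 12, shape = plate_shape(n_wells = 8),
                     n_cycles = 10)
  d4 <- tempfile()
  emit_fixture_files(simulate_experiment(cfgn), "bioscreen", d4, cfgn)
  top <- readLines(file.path(d4, "run1.csv"), n = 2)
  expect_match(top[1], "^Time(,[0-9]+)+$")
  expect_match(top[2], "^[0-9]{2}:[0-9]{2}:[0-9]{2},")
})

test_that("noiseless fits recover simulated truth to 1e-4 relative", {
  sim <- simulate_experiment(sim_config(seed = 13, shape = plate_shape(2, 3),
                                        n_cycles = 60, noise_sd = 0,
                                        spike_prob = 0, baseline = 0,
                                        truth_model = "logistic"))
  fits <- fit_growth_curves(sim$measures, method = "logistic")
  s <- summarize_growth_curves(fits)
  joined <- dplyr::inner_join(s, sim$truth, by = c("run", "plate", "well"),
                              suffix = c("", ".t"))
  expect_lt(max(abs(joined$A - joined$A.t) / joined$A.t), 1e-4)
  expect_lt(max(abs(joined$mu - joined$mu.t) / joined$mu.t), 1e-4)
  expect_lt(max(abs(joined$lambda - joined$lambda.t) / joined$lambda.t), 1e-4)
})
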