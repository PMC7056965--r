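# Shared fixtures: all inputs are generated in code at test time.

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force running filter with symmetric shrinking windows: the
# independent oracle for running_median()/running_mean().
brute_running <- function(y, k, fun) {
  n <- length(y)
  h <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    hw <- min(h, i - 1, n - i)
    fun(y[(i - hw):(i + hw)])
  }, numeric(1))
}

# Random well-mode formula strings over the engine's vocabulary, with slice
# bounds kept inside 1..n so only semantics (not error paths) are compared.
random_formula <- function(n, depth = 3) {
  leaf <- function() {
    switch(sample(4, 1),
      "y", "x",
      sprintf("%.3f", stats::runif(1, 0.1, 3)),
      {
        a <- sample(n, 1)
        b <- a + sample.int(n - a + 1, 1) - 1
        sprintf("y[%d:%d]", a, b)
      })
  }
  build <- function(d) {
    if (d <= 0 || stats::runif(1) < 0.3) return(leaf())
    switch(sample(3, 1),
      sprintf("(%s %s %s)", build(d - 1),
              sample(c("+", "-", "*", "/"), 1), build(d - 1)),
      sprintf("%s(%s)", sample(c("min", "max", "mean", "median", "log",
                                 "exp", "sqrt", "abs"), 1),
              build(d - 1)),
      sprintf("-(%s)", build(d - 1)))
  }
  build(depth)
}

# Independent oracle: base R evaluation of the same expression text in a
# sealed environment holding only the vocabulary (R shares the 1-based
# inclusive slice semantics).
oracle_eval <- function(text, y, x) {
  env <- list2env(list(y = y, x = x, median = stats::median),
                  parent = baseenv())
  out <- suppressWarnings(eval(parse(text = text)[[1]], env))
  out[is.nan(out)] <- NA_real_
  rep_len(as.numeric(out), length(y))
}

# Drop bookkeeping attributes before cross-dialect table comparisons.
strip_attrs <- function(tbl) {
  attr(tbl, "log") <- NULL
  attr(tbl, "units") <- NULL
  tbl
}

# Noiseless single-plate simulation used across tests.
tiny_sim <- function(seed = 1, ...) {
  simulate_experiment(sim_config(
    seed = seed, shape = plate_shape(2, 3), n_cycles = 30, noise_sd = 0,
    spike_prob = 0, baseline = 0, ...))
}
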