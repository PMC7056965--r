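test_that("formats are detected from content, with a unique claimant", {
  long <- write_lines_tmp(c("well,runtime,measure", "A1,0,0.1"))
  wide <- write_lines_tmp(c("time,A01,A02", "0,0.1,0.2"))
  bios <- write_lines_tmp(c("Time,1,2,3", "00:15:00,0.1,0.2,0.3"))
  plater <- write_lines_tmp(c("strain,1,2,3", "A,s1,s2,s3", "B,s4,s5,s6"))
  design <- write_lines_tmp(c("plate,well,strain", "1,A01,s1"))
  expect_equal(detect_format(long), "long_csv")
  expect_equal(detect_format(wide), "wide_csv")
  expect_equal(detect_format(bios), "bioscreen")
  expect_equal(detect_format(plater), "plater_design")
  expect_equal(detect_format(design), "generic_design_csv")
  junk <- write_lines_tmp(c(">seq1", "ACGT"))
  expect_error(detect_format(junk), "unrecognized format")
  # detection never looks at the filename
  odd_name <- file.path(tempdir(), "something_design.csv")
  file.copy(long, odd_name, overwrite = TRUE)
  expect_equal(detect_format(odd_name), "long_csv")
})

test_that("long reader fills defaults and enforces uniqueness", {
  path <- write_lines_tmp(c("well,runtime,measure",
                            "a1,10,0.2", "A1,0,0.1", "B1,0,0.3",
                            "B1,10,0.4", "B1,20,0.5", "A1,20,0.3"))
  tbl <- read_measures_long_csv(path, units = "seconds")
  expect_equal(nrow(tbl), 6L)
  expect_equal(unique(tbl$plate), "1")
  expect_equal(unique(tbl$run), tools::file_path_sans_ext(basename(path)))
  expect_equal(tbl$well[1:2], c("A01", "A01"))       # normalized + sorted
  expect_equal(tbl$runtime[tbl$well == "A01"], c(0, 10, 20))
  typed <- write_lines_tmp(c("well,runtime,measure,measure_type",
                             "A1,0,0.1,OD595", "A1,0,55,lum"))
  expect_equal(nrow(read_measures_long_csv(typed)), 2L)
  dup <- write_lines_tmp(c("well,runtime,measure", "A1,0,0.1", "A01,0,0.2"))
  expect_error(read_measures_long_csv(dup), "duplicate measure key")
  bad <- write_lines_tmp(c("well,runtime,measure", "A1,abc,0.1"))
  expect_error(read_measures_long_csv(bad), "non-numeric runtime.*row 1")
})

test_that("wide reader melts, drops blanks and parses hh:mm:ss", {
  path <- write_lines_tmp(c("time,A01,A02", "0,0.1,0.4", "1,0.2,", "2,0.3,0.6"))
  tbl <- read_measures_wide_csv(path, units = "hours")
  expect_equal(nrow(tbl), 5L)                    # blank A02@t=1 dropped
  expect_false(any(tbl$well == "A02" & tbl$runtime == 1))
  expect_equal(attr(tbl, "units"), "hours")
  hms <- write_lines_tmp(c("time,A01", "00:15:00,0.1", "00:30:00,0.2"))
  expect_equal(read_measures_wide_csv(hms, units = "minutes")$runtime,
               c(15, 30))
  expect_equal(read_measures_wide_csv(hms, units = "seconds")$runtime,
               c(900, 1800))
  dup <- write_lines_tmp(c("time,A01,A01", "0,0.1,0.2"))
  expect_error(read_measures_wide_csv(dup), "repeated well header")
})

test_that("bioscreen wells split into two 100-well plates", {
  mk <- function(ids) {
    write_lines_tmp(c(paste(c("Time", ids), collapse = ","),
                      paste(c("00:15:00", sprintf("%.3f", seq_along(ids) / 100)),
                            collapse = ","),
                      paste(c("00:30:00", sprintf("%.3f", seq_along(ids) / 50)),
                            collapse = ",")))
  }
  one <- read_measures_bioscreen(mk(1:100), units = "minutes")
  expect_equal(nrow(one), 200L)
  expect_equal(unique(one$plate), "1")
  expect_equal(sort(unique(one$runtime)), c(15, 30))
  two <- read_measures_bioscreen(mk(1:200), units = "minutes")
  expect_equal(sort(unique(two$plate)), c("1", "2"))
  expect_equal(sum(two$plate == "2"), 200L)
  # well 150 renumbers to 50 on plate 2
  expect_true(any(two$plate == "2" & two$well == "50"))
  expect_error(read_measures_bioscreen(mk(c(1, 201))), "out of range")
})

test_that("plater designs parse block per variable with shared shape", {
  rows <- function(v) {
    c(paste(c(v, 1:12), collapse = ","),
      vapply(LETTERS[1:8], function(r) {
        paste(c(r, rep(paste0(v, "_val"), 12)), collapse = ",")
      }, character(1)))
  }
  one <- write_lines_tmp(rows("strain"))
  d <- read_design_plater(one)
  expect_equal(nrow(d), 96L)
  expect_equal(names(d), c("plate", "well", "strain"))
  two <- write_lines_tmp(c(rows("drug"), "", rows("dose_uM")))
  d2 <- read_design_plater(two)
  expect_equal(names(d2), c("plate", "well", "drug", "dose_uM"))
  expect_equal(nrow(d2), 96L)
  # 7 data rows under a 12-column header is not a standard plate block
  ragged <- write_lines_tmp(rows("strain")[1:8])
  expect_error(read_design_plater(ragged), "ragged or partial")
  small <- function(v) {
    c(paste(c(v, 1:4), collapse = ","),
      vapply(LETTERS[1:3], function(r) {
        paste(c(r, rep(paste0(v, "_v"), 4)), collapse = ",")
      }, character(1)))
  }
  mismatch <- write_lines_tmp(c(rows("strain"), "", small("drug")))
  expect_error(read_design_plater(mismatch), "shape")
  dupvar <- write_lines_tmp(c(rows("strain"), "", rows("strain")))
  expect_error(read_design_plater(dupvar), "duplicate")
  # empty grid cells become missing values
  sparse <- write_lines_tmp(c("strain,1,2,3,4", "A,s1,,s3,s4",
                              "B,,s2,s3,s4", "C,s1,s2,s3,s4"))
  ds <- read_design_plater(sparse)
  expect_equal(ds$strain[ds$well == "A02"], NA_character_)
  expect_equal(nrow(ds), 12L)
})

test_that("multi-file join heuristics follow the file-count rules", {
  sim <- tiny_sim(seed = 20)
  cfg <- sim_config(seed = 20, shape = plate_shape(2, 3), n_cycles = 30,
                    noise_sd = 0, spike_prob = 0, baseline = 0)
  d <- tempfile()
  emit_fixture_files(sim, "long_csv", d, cfg)
  m1 <- file.path(d, "run1.csv")
  des <- file.path(d, "run1_design.csv")

  # (a) one measures + one design -> a single run with design columns
  a <- join_experiment(c(m1, des), units = "hours")
  expect_equal(unique(a$run), "run1")
  expect_true(all(c("strain", "drug", "dose_uM") %in% names(a)))
  expect_equal(nrow(a), 6L * 30L)   # joining never changes the record count

  # (b) two measures + one design -> design joined onto each run
  m2 <- file.path(d, "second.csv")
  file.copy(m1, m2)
  b <- join_experiment(c(m1, m2, des), units = "hours")
  expect_setequal(unique(b$run), c("run1", "second"))
  expect_equal(nrow(b), 2L * 6L * 30L)
  expect_true(all(!is.na(b$strain)))

  # (c) multiple designs match measures by stem prefix after '_design'
  sim2 <- simulate_experiment(sim_config(seed = 21, n_runs = 2,
                                         shape = plate_shape(2, 3),
                                         n_cycles = 30, noise_sd = 0,
                                         spike_prob = 0, baseline = 0))
  d2 <- tempfile()
  emit_fixture_files(sim2, "long_csv", d2, cfg)
  files <- file.path(d2, c("run1.csv", "run1_design.csv",
                           "run2.csv", "run2_design.csv"))
  cc <- join_experiment(files, units = "hours")
  expect_setequal(unique(cc$run), c("run1", "run2"))
  expect_true(all(!is.na(cc$strain)))
  expect_match(paste(attr(cc, "log"), collapse = "\n"),
               "matched design 'run1_design.csv' to run 'run1'")

  # unmatched design warns; ambiguous match errors
  stray <- file.path(d2, "zzz_design.csv")
  file.copy(files[2], stray)
  expect_warning(join_experiment(c(files[1], files[3], files[2], stray),
                                 units = "hours"),
                 "matched no measures file")
  dupm <- file.path(d2, "run1b.csv")
  file.copy(files[1], dupm)
  expect_error(join_experiment(c(files[1], dupm, files[3], files[2],
                                 files[4]), units = "hours"),
               "equally well")
  expect_error(join_experiment(des), "no measures file")
})

test_that("every dialect parses back to the same canonical table", {
  cfg_grid <- sim_config(seed = 22, shape = plate_shape(2, 3), n_cycles = 25)
  sim <- simulate_experiment(cfg_grid)
  key_cols <- c("run", "plate", "well", "runtime", "measure")
  parsed <- lapply(c("long_csv", "wide_csv"), function(dia) {
    dir <- tempfile()
    emit_fixture_files(sim, dia, dir, cfg_grid)
    out <- join_experiment(list.files(dir, full.names = TRUE), units = "hours")
    out <- out[order(out$well, out$runtime), ]
    strip_attrs(tibble::as_tibble(out[key_cols]))
  })
  expect_equal(parsed[[1]], parsed[[2]])
  # numbered-well sim: bioscreen vs long
  cfg_num <- sim_config(seed = 23, shape = plate_shape(n_wells = 12),
                        n_cycles = 25)
  simn <- simulate_experiment(cfg_num)
  parsedn <- lapply(c("long_csv", "bioscreen"), function(dia) {
    dir <- tempfile()
    emit_fixture_files(simn, dia, dir, cfg_num)
    out <- join_experiment(list.files(dir, full.names = TRUE), units = "hours")
    out <- out[order(as.integer(out$well), out$runtime), ]
    strip_attrs(tibble::as_tibble(out[key_cols]))
  })
  expect_equal(parsedn[[1]], parsedn[[2]])
})
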