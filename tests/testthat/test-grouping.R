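test_that("the worked shorthand example selects 96 targets from one reference", {
  specs <- parse_group_shorthand("1!A01->A01:H12", plate_shape(8, 12),
                                 plates = "1")
  expect_length(specs, 1L)
  spec <- specs[[1]]
  expect_equal(spec$plate, "1")
  expect_equal(spec$ref_wells, "A01")
  expect_length(spec$target_wells, 96L)
  expect_setequal(spec$target_wells, plate_wells(plate_shape(8, 12)))
})

test_that("omitting the plate prefix instantiates the spec on every plate", {
  specs <- parse_group_shorthand("A01->A01:H12", plate_shape(8, 12),
                                 plates = c("1", "2"))
  expect_length(specs, 2L)
  expect_equal(vapply(specs, `[[`, "", "plate"), c("1", "2"))
  expect_equal(vapply(specs, `[[`, "", "name"), c("g1", "g1"))
})

test_that("rectangles expand inclusively in row-major order, any corner order", {
  specs <- parse_group_shorthand("B02:C03->D04", plate_shape(8, 12))
  expect_equal(specs[[1]]$ref_wells, c("B02", "B03", "C02", "C03"))
  expect_equal(specs[[1]]$target_wells, "D04")
  flipped <- parse_group_shorthand("C03:B02->D04", plate_shape(8, 12))
  expect_equal(flipped[[1]]$ref_wells, specs[[1]]$ref_wells)
  # numbered plates use integer ranges
  nspec <- parse_group_shorthand("1->5:8", plate_shape(n_wells = 10))
  expect_equal(nspec[[1]]$target_wells, c("5", "6", "7", "8"))
})

test_that("rectangle expansion matches a brute-force enumerator", {
  set.seed(14)
  shape <- plate_shape(8, 12)
  for (i in 1:25) {
    r <- sort(sample(8, 2, replace = TRUE))
    cl <- sort(sample(12, 2, replace = TRUE))
    a <- paste0(LETTERS[r[1]], cl[1])
    b <- paste0(LETTERS[r[2]], cl[2])
    spec <- parse_group_shorthand(paste0("A01->", a, ":", b), shape)[[1]]
    brute <- as.vector(t(outer(LETTERS[r[1]:r[2]],
                               sprintf("%02d", cl[1]:cl[2]), paste0)))
    expect_equal(spec$target_wells, brute)
    expect_length(spec$target_wells, diff(r + c(0, 1)) * diff(cl + c(0, 1)))
  }
})

test_that("specs round-trip through their rendered shorthand", {
  set.seed(15)
  for (i in 1:20) {
    shape <- plate_shape(sample(3:8, 1), sample(3:12, 1))
    wells <- plate_wells(shape)
    spec <- structure(list(
      name = "g1", plate = "1",
      ref_wells = sample(wells, sample(3, 1)),
      target_wells = sample(wells, sample(6, 1))), class = "group_spec")
    back <- parse_group_shorthand(format_group_spec(spec), shape,
                                  plates = "1")[[1]]
    expect_equal(back$ref_wells, spec$ref_wells)
    expect_equal(back$target_wells, spec$target_wells)
    expect_equal(back$plate, spec$plate)
  }
})

test_that("malformed specs fail with line-addressed errors", {
  shape <- plate_shape(8, 12)
  expect_error(parse_group_shorthand("A01,A02", shape), "missing '->'")
  expect_error(parse_group_shorthand("->A01", shape), "empty reference")
  expect_error(parse_group_shorthand("A01->", shape), "empty target")
  expect_error(parse_group_shorthand("A01->A0x", shape), "malformed")
  expect_error(parse_group_shorthand("A01->A01:J13", shape), "outside")
  expect_error(parse_group_shorthand("3!A01->A02", shape, plates = c("1", "2")),
               "unknown plate")
  expect_error(parse_group_shorthand("A01->A02\nB01->", shape), "line 2")
})

test_that("apply_groups marks references, duplicates multi-group wells", {
  tbl <- tibble::tibble(run = "1", plate = "1",
                        well = c("A01", "A02", "A03"), v = 1:3)
  specs <- parse_group_shorthand("A01->A01,A02", plate_shape(1, 3))
  out <- apply_groups(tbl, specs)
  # reference status wins for a well on both sides
  expect_equal(sum(out$well == "A01"), 1L)
  expect_true(out$is_ref[out$well == "A01"])
  expect_false(out$is_ref[out$well == "A02"])
  expect_false("A03" %in% out$well)   # ungrouped rows dropped from the view
  # grouped row count = sum over specs of matched well rows
  specs2 <- parse_group_shorthand("A01->A02\nA02->A03,A01", plate_shape(1, 3))
  out2 <- apply_groups(tbl, specs2)
  expect_equal(nrow(out2), 2L + 3L)
  expect_setequal(unique(out2$group), c("g1", "g2"))
  expect_warning(apply_groups(tbl, parse_group_shorthand("A01->B03",
                                                         plate_shape(2, 3))),
                 "not in data")
  # an empty table warns both about the missing wells and the empty view
  expect_warning(
    expect_warning(empty <- apply_groups(tbl[0, ], specs), "not in data"),
    "no wells matched")
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("group", "is_ref") %in% names(empty)))
})
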