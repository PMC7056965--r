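#' Normalize a well label to canonical form
#'
#' Alphanumeric labels ("a1", "H12") are canonicalized to an uppercase row
#' letter followed by a two-digit, zero-padded column ("A01", "H12"). Purely
#' numeric labels (instruments that number wells 1, 2, ...) are kept as the
#' plain number without padding. Two labels refer to the same well if and only
#' if their canonical renderings are equal.
#'
#' @param text Character vector of well labels ("A1", "a01", "13", ...).
#' @return Character vector of canonical labels.
#' @examples
#' normalize_well_label(c("a1", "H12", "13"))
#' @export
normalize_well_label <- function(text) {
  text <- as.character(text)
  out <- character(length(text))
  alnum <- grepl("^[A-Pa-p][0-9]{1,2}$", text)
  num <- grepl("^[0-9]+$", text)
  bad <- !alnum & !num
  if (any(bad)) {
    stop("malformed well label(s): ",
         paste(utils::head(unique(text[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  out[alnum] <- paste0(
    toupper(substr(text[alnum], 1L, 1L)),
    sprintf("%02d", as.integer(substring(text[alnum], 2L)))
  )
  out[num] <- as.character(as.integer(text[num]))
  out
}

#' @keywords internal
well_row <- function(well) {
  ifelse(grepl("^[A-P]", well), match(substr(well, 1L, 1L), LETTERS), NA_integer_)
}

#' @keywords internal
well_col <- function(well) {
  ifelse(grepl("^[A-P]", well), as.integer(substring(well, 2L)), NA_integer_)
}

#' Plate shapes
#'
#' A plate shape is either a rectangular grid (`n_rows` x `n_cols`) for
#' letter-number labelled plates, or a numeric well count for instruments
#' that number their wells. `plate_shape()` constructs one explicitly;
#' `infer_plate_shape()` picks the smallest standard plate (12 = 3x4,
#' 24 = 4x6, 48 = 6x8, 96 = 8x12, 384 = 16x24; or the observed numeric
#' count) covering all observed labels.
#'
#' @param n_rows,n_cols Grid dimensions for a rectangular plate.
#' @param n_wells Well count for a numerically labelled plate.
#' @return A `plate_shape` list with fields `n_rows`/`n_cols` or `n_wells`.
#' @examples
#' infer_plate_shape(c("A01", "H12"))
#' infer_plate_shape(c("1", "100"))
#' @export
plate_shape <- function(n_rows = NULL, n_cols = NULL, n_wells = NULL) {
  if (!is.null(n_wells)) {
    structure(list(n_wells = as.integer(n_wells)), class = "plate_shape")
  } else {
    structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
              class = "plate_shape")
  }
}

standard_shapes <- list(
  c(3L, 4L), c(4L, 6L), c(6L, 8L), c(8L, 12L), c(16L, 24L)
)

#' @rdname plate_shape
#' @param wells Character vector of canonical well labels.
#' @export
infer_plate_shape <- function(wells) {
  wells <- normalize_well_label(wells)
  if (all(grepl("^[0-9]+$", wells))) {
    return(plate_shape(n_wells = max(as.integer(wells))))
  }
  rmax <- max(well_row(wells), na.rm = TRUE)
  cmax <- max(well_col(wells), na.rm = TRUE)
  for (s in standard_shapes) {
    if (rmax <= s[1] && cmax <= s[2]) return(plate_shape(s[1], s[2]))
  }
  plate_shape(rmax, cmax)
}

#' @export
print.plate_shape <- function(x, ...) {
  if (!is.null(x$n_wells)) {
    cat("<plate shape:", x$n_wells, "numbered wells>\n")
  } else {
    cat("<plate shape:", x$n_rows, "x", x$n_cols, ">\n")
  }
  invisible(x)
}

#' All well labels of a plate shape, row-major
#' @param shape A [plate_shape()].
#' @return Character vector of canonical labels.
#' @export
plate_wells <- function(shape) {
  if (!is.null(shape$n_wells)) return(as.character(seq_len(shape$n_wells)))
  as.vector(t(outer(LETTERS[seq_len(shape$n_rows)],
                    sprintf("%02d", seq_len(shape$n_cols)), paste0)))
}

runtime_unit_factors <- c(seconds = 1, minutes = 60, hours = 3600)

#' @keywords internal
check_runtime_unit <- function(unit) {
  if (!unit %in% names(runtime_unit_factors)) {
    stop("unknown runtime unit '", unit, "'; allowed: ",
         paste(names(runtime_unit_factors), collapse = ", "), call. = FALSE)
  }
  unit
}

#' Convert the runtime unit of a tidy measures table
#'
#' Rescales the `runtime` column between seconds, minutes and hours and
#' updates the table's `units` attribute. All other columns are untouched.
#'
#' @param table Tidy measures tibble with a `runtime` column and a `units`
#'   attribute (as produced by the readers or [as_tidy_measures()]).
#' @param to Target unit: "seconds", "minutes" or "hours".
#' @param from Source unit; defaults to the table's `units` attribute.
#' @return The table with rescaled `runtime`.
#' @export
convert_runtime_units <- function(table, to, from = attr(table, "units")) {
  check_runtime_unit(to)
  if (is.null(from)) stop("source runtime unit unknown; supply `from`", call. = FALSE)
  check_runtime_unit(from)
  table$runtime <- table$runtime * runtime_unit_factors[[from]] / runtime_unit_factors[[to]]
  attr(table, "units") <- to
  table
}

#' Validate and canonicalize a tidy measures table
#'
#' The canonical table has one row per (run, plate, well, runtime) observation
#' with a numeric `measure` column, optional `measure_type` and `datetime`
#' columns, and zero or more design columns. Duplicate keys fail loudly;
#' rows are sorted by runtime within each well.
#'
#' @param table A data frame with at least `well`, `runtime`, `measure`.
#' @param units Runtime unit to record in the `units` attribute.
#' @return A tibble with canonical well labels, sorted within wells.
#' @export
as_tidy_measures <- function(table, units = attr(table, "units") %||% "seconds") {
  table <- tibble::as_tibble(table)
  need <- c("well", "runtime", "measure")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"run" %in% names(table)) table$run <- "1"
  if (!"plate" %in% names(table)) table$plate <- "1"
  table$run <- as.character(table$run)
  table$plate <- as.character(table$plate)
  table$well <- normalize_well_label(table$well)
  if (!is.numeric(table$runtime)) stop("runtime must be numeric", call. = FALSE)
  if (any(table$runtime < 0, na.rm = TRUE)) stop("runtime must be >= 0", call. = FALSE)
  keycols <- intersect(c("run", "plate", "well", "runtime", "measure_type"), names(table))
  key <- do.call(paste, c(table[keycols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- table[duplicated(key), keycols, drop = FALSE][1L, ]
    stop("duplicate measure key: ", paste(unlist(dup), collapse = "/"), call. = FALSE)
  }
  lead <- intersect(c("run", "plate", "well", "runtime", "datetime", "measure_type", "measure"),
                    names(table))
  table <- table[c(lead, setdiff(names(table), lead))]
  table <- dplyr::arrange(table, .data$run, .data$plate, .data$well, .data$runtime)
  attr(table, "units") <- check_runtime_unit(units)
  table
}

#' Per-run experiment summary
#'
#' Counts, for each run, the number of plates (`n_plates`), distinct wells
#' (`n_wells`) and measure records (`n_measures`).
#'
#' @param table Tidy measures tibble.
#' @return A tibble with one row per run.
#' @export
experiment_summary <- function(table) {
  if (nrow(table) == 0L) stop("empty measures table", call. = FALSE)
  table |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      n_plates = dplyr::n_distinct(.data$plate),
      n_wells = dplyr::n_distinct(paste(.data$plate, .data$well)),
      n_measures = dplyr::n(),
      .groups = "drop"
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
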