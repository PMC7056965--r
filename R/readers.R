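# File-format detection and parsing of measures/design files into the
# canonical tidy table. The registry is ordered but detection requires a
# unique claimant, so adding a dialect cannot silently shadow another.

read_text_lines <- function(path, n = -1L) {
  lines <- readLines(path, n = n, warn = FALSE, encoding = "UTF-8")
  if (length(lines)) lines[1L] <- sub("^﻿", "", lines[1L])
  lines
}

sniff_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))) >
      lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))) ";" else ","
}

split_fields <- function(line, delim) {
  trimws(strsplit(line, delim, fixed = TRUE)[[1L]])
}

is_well_header <- function(x) grepl("^[A-Pa-p][0-9]{1,2}$", x)
is_int_header <- function(x) grepl("^[0-9]+$", x)
is_time_header <- function(x) tolower(x) %in% c("time", "runtime", "t")

# hh:mm:ss (hours may exceed 24) -> seconds
parse_hms <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3L || anyNA(suppressWarnings(as.numeric(p)))) {
      stop("malformed hh:mm:ss time '", paste(p, collapse = ":"), "'",
           call. = FALSE)
    }
    p <- as.numeric(p)
    p[1L] * 3600 + p[2L] * 60 + p[3L]
  }, numeric(1))
}

is_hms <- function(x) grepl("^\\s*[0-9]+:[0-9]{1,2}:[0-9]{1,2}(\\.[0-9]+)?\\s*$", x)

file_stem <- function(path) tools::file_path_sans_ext(basename(path))

# ---- format registry ----------------------------------------------------

# Each entry: sniff over the first 50 lines -> logical claim.
reader_registry <- list(
  long_csv = function(lines) {
    delim <- sniff_delim(lines[1L])
    f <- tolower(split_fields(lines[1L], delim))
    all(c("well", "runtime", "measure") %in% f)
  },
  wide_csv = function(lines) {
    delim <- sniff_delim(lines[1L])
    f <- split_fields(lines[1L], delim)
    length(f) >= 2L && is_time_header(f[1L]) && all(is_well_header(f[-1L]))
  },
  bioscreen = function(lines) {
    delim <- sniff_delim(lines[1L])
    f <- split_fields(lines[1L], delim)
    length(f) >= 2L && tolower(f[1L]) == "time" && all(is_int_header(f[-1L]))
  },
  plater_design = function(lines) {
    delim <- sniff_delim(lines[1L])
    f <- split_fields(lines[1L], delim)
    if (length(f) < 2L || !nzchar(f[1L]) || !all(is_int_header(f[-1L])) ||
        tolower(f[1L]) == "time" || length(lines) < 2L) {
      return(FALSE)
    }
    body <- split_fields(lines[2L], delim)
    grepl("^[A-Pa-p]$", body[1L])
  },
  generic_design_csv = function(lines) {
    delim <- sniff_delim(lines[1L])
    f <- tolower(split_fields(lines[1L], delim))
    "well" %in% f && !any(c("runtime", "measure") %in% f) && length(f) >= 2L
  }
)

#' Detect the format of an input file
#'
#' Checks the first 50 lines against each registered format signature and
#' returns the unique claimant among `long_csv`, `wide_csv`, `bioscreen`,
#' `plater_design` and `generic_design_csv`. Detection looks only at file
#' content, never at the filename.
#'
#' @param path Path to a plain-text file.
#' @return The format name (character scalar).
#' @export
detect_format <- function(path) {
  lines <- read_text_lines(path, n = 50L)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  claims <- names(reader_registry)[vapply(reader_registry, function(f) {
    isTRUE(tryCatch(f(lines), error = function(e) FALSE))
  }, logical(1))]
  if (length(claims) == 0L) {
    stop("unrecognized format for '", basename(path), "'; first line: ",
         lines[1L], call. = FALSE)
  }
  if (length(claims) > 1L) {
    stop("ambiguous format for '", basename(path), "': ",
         paste(claims, collapse = ", "), call. = FALSE)
  }
  claims
}

# ---- measures readers ---------------------------------------------------

read_delim_tbl <- function(path) {
  first <- read_text_lines(path, n = 1L)
  readr::read_delim(path, delim = sniff_delim(first), show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    locale = readr::locale(encoding = "UTF-8"),
                    col_types = readr::cols(.default = readr::col_character()))
}

check_numeric_column <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop("non-numeric ", what, " in '", basename(path), "' at data row ",
         bad[1L], ": '", x[bad[1L]], "'", call. = FALSE)
  }
  out
}

#' Read a long-format measures CSV
#'
#' Requires columns `well`, `runtime`, `measure`; optional `run`, `plate`,
#' `measure_type`, `datetime`. A missing `run` defaults to the file stem and
#' a missing `plate` to `"1"`. Both `,` and `;` delimiters are sniffed.
#'
#' @param path File path.
#' @param units Runtime unit the file reports ("seconds", "minutes",
#'   "hours"); recorded on the result.
#' @return A tidy measures tibble (see [as_tidy_measures()]).
#' @export
canonicalize_key_names <- function(tbl, keys) {
  lower <- tolower(names(tbl))
  for (key in keys) {
    names(tbl)[lower == key] <- key
  }
  tbl
}

read_measures_long_csv <- function(path, units = "seconds") {
  tbl <- read_delim_tbl(path)
  tbl <- canonicalize_key_names(tbl, c("run", "plate", "well", "runtime",
                                       "measure", "measure_type", "datetime"))
  miss <- setdiff(c("well", "runtime", "measure"), names(tbl))
  if (length(miss)) {
    stop("'", basename(path), "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"run" %in% names(tbl)) tbl$run <- file_stem(path)
  if (!"plate" %in% names(tbl)) tbl$plate <- "1"
  tbl$runtime <- check_numeric_column(tbl$runtime, "runtime", path)
  tbl$measure <- check_numeric_column(tbl$measure, "measure", path)
  as_tidy_measures(tbl, units = units)
}

# Shared by wide_csv and bioscreen: first column = time, remaining columns
# one per well. Blank cells are dropped, not imputed.
melt_wide <- function(tbl, path, units, run) {
  time_raw <- tbl[[1L]]
  if (all(is_hms(time_raw))) {
    runtime <- parse_hms(time_raw) / runtime_unit_factors[[check_runtime_unit(units)]]
  } else {
    runtime <- check_numeric_column(time_raw, "time", path)
  }
  long <- tbl[-1L]
  long$runtime <- runtime
  out <- tidyr::pivot_longer(long, cols = -"runtime", names_to = "well",
                             values_to = "measure")
  out <- out[!is.na(out$measure) & nzchar(out$measure), ]
  out$measure <- check_numeric_column(out$measure, "measure", path)
  out$run <- run
  out
}

#' Read a wide (time x well) measures CSV
#'
#' First column is time (numeric in `units`, or `hh:mm:ss`, which is
#' converted to seconds and then to `units`); every remaining header is a
#' well label. Blank cells yield no record.
#'
#' @inheritParams read_measures_long_csv
#' @return A tidy measures tibble.
#' @export
read_measures_wide_csv <- function(path, units = "seconds") {
  first <- read_text_lines(path, n = 1L)
  header <- split_fields(first, sniff_delim(first))
  if (anyDuplicated(header[-1L])) {
    stop("repeated well header in '", basename(path), "': ",
         paste(unique(header[-1L][duplicated(header[-1L])]), collapse = ", "),
         call. = FALSE)
  }
  tbl <- read_delim_tbl(path)
  out <- melt_wide(tbl, path, units, run = file_stem(path))
  out$plate <- "1"
  as_tidy_measures(out, units = units)
}

#' Read a Bioscreen-style wide measures file
#'
#' First column `Time` in `hh:mm:ss`; remaining headers are the instrument's
#' numbered wells 1-200. Wells 1-100 are assigned plate "1" and wells
#' 101-200 plate "2" (renumbered 1-100 within the plate), mirroring the
#' instrument's two-cassette layout.
#'
#' @inheritParams read_measures_long_csv
#' @return A tidy measures tibble.
#' @export
read_measures_bioscreen <- function(path, units = "seconds") {
  tbl <- read_delim_tbl(path)
  ids <- suppressWarnings(as.integer(names(tbl)[-1L]))
  if (anyNA(ids)) {
    stop("non-numeric well header in '", basename(path), "'", call. = FALSE)
  }
  if (any(ids > 200L | ids < 1L)) {
    stop("Bioscreen well id out of range 1-200 in '", basename(path), "'",
         call. = FALSE)
  }
  out <- melt_wide(tbl, path, units, run = file_stem(path))
  id <- as.integer(out$well)
  out$plate <- ifelse(id <= 100L, "1", "2")
  out$well <- as.character(ifelse(id <= 100L, id, id - 100L))
  as_tidy_measures(out, units = units)
}

# ---- design readers -----------------------------------------------------

#' Read a plate-shaped ('plater'-style) design file
#'
#' One or more plate-shaped blocks separated by a blank line. In each block
#' the top-left cell is the variable name, the first row holds the column
#' numbers, the first column the row letters, and the grid the values.
#' Every block must share the same plate shape; empty grid cells become
#' missing values.
#'
#' @param path File path.
#' @return A design tibble: `plate`, `well`, one column per variable.
#' @export
read_design_plater <- function(path) {
  lines <- read_text_lines(path)
  delim <- sniff_delim(lines[1L])
  blank <- !nzchar(trimws(gsub(delim, "", lines, fixed = TRUE)))
  blocks <- split(lines[!blank], cumsum(blank)[!blank])
  out <- NULL
  shape_dims <- NULL
  seen <- character(0)
  for (block in blocks) {
    header <- split_fields(block[1L], delim)
    var <- header[1L]
    cols <- header[-1L]
    if (!nzchar(var)) stop("plater block with empty variable name", call. = FALSE)
    if (var %in% seen) {
      stop("duplicate plater variable '", var, "'", call. = FALSE)
    }
    if (!all(is_int_header(cols))) {
      stop("plater block '", var, "': non-numeric column header", call. = FALSE)
    }
    seen <- c(seen, var)
    body <- lapply(block[-1L], split_fields, delim = delim)
    dims <- c(length(body), length(cols))
    if (!any(vapply(standard_shapes, identical, logical(1), as.integer(dims)))) {
      stop("plater block '", var, "' is ragged or partial: ", dims[1L],
           " data rows x ", dims[2L], " columns is not a standard plate shape",
           call. = FALSE)
    }
    if (is.null(shape_dims)) {
      shape_dims <- dims
    } else if (!identical(shape_dims, dims)) {
      stop("plater block '", var, "' has shape ", dims[1L], "x", dims[2L],
           " but earlier blocks are ", shape_dims[1L], "x", shape_dims[2L],
           call. = FALSE)
    }
    rows <- lapply(seq_along(body), function(i) {
      fields <- body[[i]]
      if (!grepl("^[A-Pa-p]$", fields[1L])) {
        stop("plater block '", var, "': row ", i,
             " does not start with a row letter", call. = FALSE)
      }
      # allow trailing empty cells dropped by the splitter
      vals <- fields[-1L]
      if (length(vals) > length(cols)) {
        stop("plater block '", var, "': row ", fields[1L],
             " has more cells than the header", call. = FALSE)
      }
      vals <- c(vals, rep("", length(cols) - length(vals)))
      tibble::tibble(
        well = normalize_well_label(paste0(toupper(fields[1L]), cols)),
        value = ifelse(nzchar(vals), vals, NA_character_))
    })
    piece <- dplyr::bind_rows(rows)
    names(piece)[2L] <- var
    out <- if (is.null(out)) piece else dplyr::full_join(out, piece, by = "well")
  }
  out$plate <- "1"
  out[c("plate", "well", setdiff(names(out), c("plate", "well")))]
}

#' Read a generic CSV design file
#'
#' Columns: `well` (required), optional `plate` and `run`, plus one column
#' per design variable. (plate, well) must be unique.
#'
#' @param path File path.
#' @return A design tibble.
#' @export
read_design_csv <- function(path) {
  tbl <- read_delim_tbl(path)
  tbl <- canonicalize_key_names(tbl, c("run", "plate", "well"))
  if (!"well" %in% names(tbl)) {
    stop("design file '", basename(path), "' lacks a well column", call. = FALSE)
  }
  if (!"plate" %in% names(tbl)) tbl$plate <- "1"
  tbl$plate <- as.character(tbl$plate)
  tbl$well <- normalize_well_label(tbl$well)
  key <- paste(tbl$plate, tbl$well)
  if (anyDuplicated(key)) {
    stop("design file '", basename(path), "' has duplicate (plate, well): ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  tbl[c("plate", "well", setdiff(names(tbl), c("plate", "well")))]
}

# ---- multi-file joining -------------------------------------------------

read_measures_file <- function(path, units) {
  switch(detect_format(path),
    long_csv = read_measures_long_csv(path, units),
    wide_csv = read_measures_wide_csv(path, units),
    bioscreen = read_measures_bioscreen(path, units),
    stop("'", basename(path), "' is a design file, not a measures file",
         call. = FALSE))
}

read_design_file <- function(path) {
  switch(detect_format(path),
    plater_design = read_design_plater(path),
    generic_design_csv = read_design_csv(path),
    stop("'", basename(path), "' is a measures file, not a design file",
         call. = FALSE))
}

strip_design_token <- function(stem) sub("[_-]design$", "", stem)

lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L)) {
    i <- i + 1L
  }
  i
}

join_design <- function(measures, design, log, dname) {
  dd <- design
  dd$run <- NULL
  mkeys <- unique(paste(measures$plate, measures$well))
  dkeys <- paste(dd$plate, dd$well)
  dropped <- dd[!dkeys %in% mkeys, c("plate", "well")]
  if (nrow(dropped)) {
    warning("design wells absent from measures (dropped): ",
            paste(paste0(dropped$plate, "/", dropped$well), collapse = ", "),
            call. = FALSE)
  }
  out <- dplyr::left_join(measures, dd, by = c("plate", "well"))
  attr(out, "units") <- attr(measures, "units")
  c(log, paste0("joined design '", dname, "' onto run(s) ",
                paste(unique(measures$run), collapse = ", ")))
  out
}

#' Join measures and design files into one experiment
#'
#' Classifies each file by content, parses it, and joins designs onto
#' measures with the multi-file heuristic: one measures + one design file
#' form a single run; several measures files + one design share that design,
#' one run per measures file; with several designs, each design is matched
#' to the measures file sharing the longest filename-stem prefix after a
#' trailing `_design`/`-design` token is stripped (so `run1_design.csv`
#' matches `run1.txt`). Ties are an error; unmatched designs a warning. The
#' run id is the measures file stem. Parsing and joining actions are
#' recorded in the result's `log` attribute.
#'
#' @param files Character vector of file paths (>= 1 measures file).
#' @param units Runtime unit for the measures readers.
#' @return A tidy measures tibble covering all runs, with design columns
#'   where available.
#' @export
join_experiment <- function(files, units = "seconds") {
  kinds <- vapply(files, detect_format, character(1))
  is_design <- kinds %in% c("plater_design", "generic_design_csv")
  mfiles <- files[!is_design]
  dfiles <- files[is_design]
  if (!length(mfiles)) stop("no measures file among inputs", call. = FALSE)
  log <- paste0("parsed '", basename(files), "' as ", kinds)

  measures <- lapply(mfiles, function(p) {
    m <- read_measures_file(p, units)
    m$run <- file_stem(p)
    m
  })
  names(measures) <- vapply(mfiles, file_stem, character(1))
  designs <- lapply(dfiles, read_design_file)

  if (length(dfiles) == 1L) {
    # one design joins onto every measures file
    measures <- lapply(measures, join_design, design = designs[[1L]],
                       log = log, dname = basename(dfiles[1L]))
    log <- c(log, paste0("joined design '", basename(dfiles[1L]),
                         "' onto every run"))
  } else if (length(dfiles) > 1L) {
    mstems <- names(measures)
    for (i in seq_along(dfiles)) {
      base <- strip_design_token(file_stem(dfiles[i]))
      lens <- vapply(mstems, lcp_len, integer(1), a = base)
      best <- max(lens)
      if (best == 0L) {
        warning("design file '", basename(dfiles[i]),
                "' matched no measures file; skipped", call. = FALSE)
        next
      }
      hits <- which(lens == best)
      if (length(hits) > 1L) {
        stop("design file '", basename(dfiles[i]),
             "' matches several measures files equally well: ",
             paste(mstems[hits], collapse = ", "), call. = FALSE)
      }
      measures[[hits]] <- join_design(measures[[hits]], designs[[i]], log,
                                      basename(dfiles[i]))
      log <- c(log, paste0("matched design '", basename(dfiles[i]),
                           "' to run '", mstems[hits], "'"))
    }
  }
  out <- dplyr::bind_rows(measures)
  out <- as_tidy_measures(out, units = units)
  attr(out, "log") <- log
  out
}
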