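# Reference/target grouping shorthand:
#   [plate!]refs->targets
# where each side is a comma list of wells and rectangular ranges
# (A01:H12 expands row-major to every well inside the rectangle; numbered
# plates use integer ranges n1:n2). One spec per line; omitting the plate
# prefix instantiates the spec on every plate of the run.

#' Parse reference/target group shorthand
#'
#' Each nonblank line has the form `[plate!]refs->targets`. Both sides are
#' comma-separated lists of well labels or ranges: `B02:C03` expands to the
#' inclusive rectangle between the two corners (row-major), and on numbered
#' plates `5:8` expands to an integer range. Lines without a plate prefix
#' are instantiated once per plate in `plates`. Groups are named `g1`,
#' `g2`, ... by line order (`plate!g<k>` when plate-scoped).
#'
#' @param text Multiline shorthand string (or character vector of lines).
#' @param shape The [plate_shape()] the wells must fall inside.
#' @param plates Character vector of plate ids in the run.
#' @return A list of `group_spec` objects with fields `name`, `plate`,
#'   `ref_wells` and `target_wells`.
#' @examples
#' parse_group_shorthand("1!A01->A01:H12", plate_shape(8, 12), plates = "1")
#' @export
parse_group_shorthand <- function(text, shape, plates = "1") {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  specs <- list()
  k <- 0L
  for (li in seq_along(lines)) {
    line <- trimws(lines[[li]])
    k <- k + 1L
    err <- function(msg) {
      stop("group spec line ", li, " ('", line, "'): ", msg, call. = FALSE)
    }
    plate <- NULL
    body <- line
    if (grepl("!", line, fixed = TRUE)) {
      parts <- strsplit(line, "!", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) err("expected a single '!' plate prefix")
      plate <- trimws(parts[1L])
      body <- parts[2L]
      if (!plate %in% plates) {
        err(paste0("unknown plate '", plate, "'; plates in run: ",
                   paste(plates, collapse = ", ")))
      }
    }
    arrow <- regexpr("->", body, fixed = TRUE)
    if (arrow == -1L) err("missing '->' arrow")
    ref_txt <- substr(body, 1L, arrow - 1L)
    tgt_txt <- substring(body, arrow + 2L)
    refs <- tryCatch(expand_well_set(ref_txt, shape),
                     error = function(e) err(conditionMessage(e)))
    tgts <- tryCatch(expand_well_set(tgt_txt, shape),
                     error = function(e) err(conditionMessage(e)))
    if (!length(refs)) err("empty reference side")
    if (!length(tgts)) err("empty target side")
    for (pl in (if (is.null(plate)) plates else plate)) {
      specs[[length(specs) + 1L]] <- structure(
        list(name = if (is.null(plate)) paste0("g", k)
             else paste0(plate, "!g", k),
             plate = pl, ref_wells = refs, target_wells = tgts),
        class = "group_spec")
    }
  }
  specs
}

# Expand one comma-separated side of a spec into canonical well labels.
expand_well_set <- function(text, shape) {
  items <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  items <- items[nzchar(items)]
  wells <- character(0)
  for (item in items) {
    if (grepl(":", item, fixed = TRUE)) {
      corners <- trimws(strsplit(item, ":", fixed = TRUE)[[1L]])
      if (length(corners) != 2L) stop("malformed range '", item, "'", call. = FALSE)
      wells <- c(wells, expand_rectangle(corners[1L], corners[2L], shape))
    } else {
      w <- normalize_well_label(item)
      check_in_shape(w, shape)
      wells <- c(wells, w)
    }
  }
  unique(wells)
}

check_in_shape <- function(wells, shape) {
  if (!is.null(shape$n_wells)) {
    if (any(grepl("^[A-P]", wells))) {
      stop("alphanumeric well on a numbered plate: ",
           paste(wells[grepl("^[A-P]", wells)], collapse = ", "), call. = FALSE)
    }
    ids <- as.integer(wells)
    if (any(ids < 1L | ids > shape$n_wells)) {
      stop("well(s) outside the ", shape$n_wells, "-well plate: ",
           paste(wells[ids < 1L | ids > shape$n_wells], collapse = ", "),
           call. = FALSE)
    }
  } else {
    if (any(grepl("^[0-9]", wells))) {
      stop("numeric well on a gridded plate: ",
           paste(wells[grepl("^[0-9]", wells)], collapse = ", "), call. = FALSE)
    }
    r <- well_row(wells)
    cl <- well_col(wells)
    bad <- r > shape$n_rows | cl > shape$n_cols | cl < 1L
    if (any(bad)) {
      stop("well(s) outside the ", shape$n_rows, "x", shape$n_cols,
           " plate: ", paste(wells[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(wells)
}

# Inclusive rectangle between two corners (any order), row-major; on
# numbered plates an integer range.
expand_rectangle <- function(a, b, shape) {
  a <- normalize_well_label(a)
  b <- normalize_well_label(b)
  check_in_shape(c(a, b), shape)
  if (!is.null(shape$n_wells)) {
    ia <- as.integer(a)
    ib <- as.integer(b)
    return(as.character(seq(min(ia, ib), max(ia, ib))))
  }
  r <- sort(c(well_row(a), well_row(b)))
  cl <- sort(c(well_col(a), well_col(b)))
  as.vector(t(outer(LETTERS[r[1L]:r[2L]],
                    sprintf("%02d", cl[1L]:cl[2L]), paste0)))
}

#' Render a group spec back to shorthand
#'
#' Inverse of [parse_group_shorthand()] up to range compression: wells are
#' written as explicit comma lists, which parse back to the same spec.
#'
#' @param spec A `group_spec`.
#' @return A single shorthand line.
#' @export
format_group_spec <- function(spec) {
  paste0(spec$plate, "!", paste(spec$ref_wells, collapse = ","), "->",
         paste(spec$target_wells, collapse = ","))
}

#' @export
print.group_spec <- function(x, ...) {
  cat("<group", x$name, "| plate", x$plate, "|", length(x$ref_wells),
      "ref,", length(x$target_wells), "target wells>\n")
  invisible(x)
}

#' Attach group membership to a table
#'
#' Produces one output row per (input row x matching group), adding `group`
#' and `is_ref` columns. A well on both sides of one spec is marked
#' `is_ref = TRUE` (reference status wins within a group). Rows matching no
#' group are dropped from the grouped view (keep the ungrouped table for
#' complete outputs); wells named in a spec but absent from the data trigger
#' a warning.
#'
#' @param table Tibble keyed by (plate, well) (e.g. measures or summary).
#' @param specs List of `group_spec` from [parse_group_shorthand()].
#' @return The grouped view with `group` and `is_ref` columns.
#' @export
apply_groups <- function(table, specs) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  pieces <- list()
  for (spec in specs) {
    members <- unique(c(spec$ref_wells, spec$target_wells))
    hit <- table$plate == spec$plate & table$well %in% members
    present <- unique(table$well[table$plate == spec$plate])
    absent <- setdiff(members, present)
    if (length(absent)) {
      warning("group ", spec$name, ": well(s) not in data: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    if (!any(hit)) next
    piece <- table[hit, , drop = FALSE]
    piece$group <- spec$name
    piece$is_ref <- piece$well %in% spec$ref_wells
    pieces[[length(pieces) + 1L]] <- piece
  }
  if (!length(pieces)) {
    warning("no wells matched any group", call. = FALSE)
    out <- table[0, , drop = FALSE]
    out$group <- character(0)
    out$is_ref <- logical(0)
    return(out)
  }
  dplyr::bind_rows(pieces)
}
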