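# Plate-view graphics: one rectangle per well in the plate's physical
# geometry, filled by a metric or design variable; optional per-well curve
# panels with translucent reference-curve overlays.

well_geometry <- function(data) {
  if (all(grepl("^[0-9]+$", data$well))) {
    # numbered wells laid out in rows of 10
    id <- as.integer(data$well)
    data$.row <- (id - 1L) %/% 10L + 1L
    data$.col <- (id - 1L) %% 10L + 1L
  } else {
    data$.row <- well_row(data$well)
    data$.col <- well_col(data$well)
  }
  data
}

#' Plate-view plot of one value per well
#'
#' Draws each well of each plate as a rectangle in plate geometry, filled by
#' the chosen summary metric or design variable. Numeric fills use the
#' perceptually uniform viridis scale (equal steps in data read as equal
#' steps in color); categorical fills use a discrete palette.
#'
#' @param data Tibble with one row per (run, plate, well) and the fill
#'   column (e.g. a summary table).
#' @param fill Name of the column to map to fill.
#' @return A ggplot object, faceted by run and plate.
#' @export
plot_plate <- function(data, fill) {
  if (!fill %in% names(data)) {
    stop("unknown metric '", fill, "'; available: ",
         paste(setdiff(names(data), c("run", "plate", "well")),
               collapse = ", "), call. = FALSE)
  }
  data <- well_geometry(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$.col, y = .data$.row,
                                          fill = .data[[fill]])) +
    ggplot2::geom_tile(color = "grey30", linewidth = 0.2) +
    ggplot2::scale_y_reverse(breaks = sort(unique(data$.row)),
                             labels = function(b) {
                               if (all(grepl("^[0-9]+$", data$well))) b
                               else LETTERS[b]
                             }) +
    ggplot2::scale_x_continuous(breaks = sort(unique(data$.col)),
                                position = "top") +
    ggplot2::facet_grid(run ~ plate, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = NULL, fill = fill) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (is.numeric(data[[fill]])) p + ggplot2::scale_fill_viridis_c()
  else p + ggplot2::scale_fill_viridis_d()
}

#' Per-well growth-curve panels in plate layout
#'
#' Line plot of each well's measures, faceted in the plate's row/column
#' geometry. When `groups` (from [parse_group_shorthand()]) are supplied,
#' each group's reference curves are replicated into its target wells and
#' drawn in light, semi-transparent grey beneath the target curves.
#'
#' @param measures Tidy measures tibble (single run/plate recommended).
#' @param groups Optional list of `group_spec`s for reference overlays.
#' @param y Measure column to plot.
#' @return A ggplot object.
#' @export
plot_well_curves <- function(measures, groups = NULL, y = "measure") {
  data <- well_geometry(measures)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$runtime,
                                          y = .data[[y]]))
  if (!is.null(groups)) {
    overlays <- lapply(groups, function(spec) {
      refs <- measures[measures$plate == spec$plate &
                         measures$well %in% spec$ref_wells, ]
      if (!nrow(refs)) return(NULL)
      targets <- intersect(spec$target_wells,
                           measures$well[measures$plate == spec$plate])
      purrr::map_dfr(targets, function(tw) {
        o <- refs
        o$ref_well <- o$well
        o$well <- tw
        o
      })
    })
    overlays <- dplyr::bind_rows(overlays)
    if (nrow(overlays)) {
      overlays <- well_geometry(overlays)
      p <- p + ggplot2::geom_line(
        data = overlays,
        ggplot2::aes(group = .data$ref_well),
        color = "grey70", alpha = 0.5)
    }
  }
  p +
    ggplot2::geom_line(color = "black") +
    ggplot2::facet_grid(.row ~ .col) +
    ggplot2::labs(x = "runtime", y = y) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 6),
                   axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Render a plate view to a PNG file
#'
#' Thin wrapper over [plot_plate()] + [ggplot2::ggsave()].
#'
#' @inheritParams plot_plate
#' @param file Output PNG path.
#' @param width,height,dpi Image geometry passed to `ggsave()`.
#' @return The file path, invisibly.
#' @export
render_plate_view <- function(data, fill, file, width = 8, height = 5,
                              dpi = 150) {
  p <- plot_plate(data, fill)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
  invisible(file)
}
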