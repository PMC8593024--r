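#' @importFrom rlang .data
NULL

#' Plot per-plane Hoover coefficients
#'
#' @param object a `hoover_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hoover_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$position_mm, .data$hoover)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "mean"), linetype = 2) +
    ggplot2::labs(x = "plane position (mm)", y = "Hoover coefficient",
                  title = sprintf("Flow homogeneity (mean %.3f)", attr(object, "mean"))) +
    ggplot2::theme_minimal()
}

#' Plot a sweep report
#'
#' Connector sweeps are drawn as mean Hoover vs connector length by shape;
#' efficiency sweeps as efficiency vs the swept variable; configuration
#' comparisons as per-config enrichment and homogeneity summaries.
#'
#' @param object a `sweep_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_report <- function(object, ...) {
  kind <- attr(object, "kind")
  s <- sweep_summary(object)
  if (identical(kind, "connector_geometry")) {
    return(
      ggplot2::ggplot(s, ggplot2::aes(.data$length_mm, .data$mean_hoover,
                                      colour = .data$shape)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "connector length (mm)",
                      y = "mean Hoover coefficient", colour = "connector") +
        ggplot2::theme_minimal()
    )
  }
  if (grepl("^efficiency_", kind)) {
    xvar <- sub("^efficiency_", "", kind)
    return(
      ggplot2::ggplot(object, ggplot2::aes(.data[[xvar]], .data$efficiency)) +
        ggplot2::geom_point(alpha = 0.5) +
        ggplot2::stat_summary(fun = mean, geom = "line") +
        ggplot2::labs(x = xvar, y = "seeding efficiency") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(s, ggplot2::aes(.data$config, .data$hoover_60min)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "axial Hoover at 60 min") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a mid-domain slice of a field
#'
#' @param flow a `flow_field` (or any object with 3-D arrays and
#'   `voxel_mm`).
#' @param what `"speed"`, `"shear"` or `"pressure"`.
#' @param y_index slice index along y (default: middle).
#' @return a ggplot raster of the x-z slice.
#' @export
plot_flow_slice <- function(flow, what = c("speed", "shear", "pressure"),
                            y_index = NULL) {
  what <- match.arg(what)
  arr <- switch(what,
    speed = velocity_magnitude(flow),
    shear = shear_rate_field(flow),
    pressure = flow$p)
  if (is.null(arr)) abort(sprintf("flow field has no %s data", what))
  if (is.null(y_index)) y_index <- ceiling(dim(arr)[2] / 2)
  sl <- arr[, y_index, ]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), z = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$z, .data$x, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = switch(what,
      speed = "|u| (mm/s)", shear = "shear (1/s)", pressure = "p (Pa)")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "z (voxels, flow axis)", y = "x (voxels)") +
    ggplot2::theme_minimal()
}

#' Plot ROI time-activity curves
#'
#' @param object a `roi_table` from [roi_timecourses()].
#' @param ... unused.
#' @return a ggplot of the five ROI curves.
#' @export
autoplot.roi_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("whole", "upper", "middle", "lower", "outflow"),
                              names_to = "roi", values_to = "MBq")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_min, .data$MBq, colour = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "activity (MBq)", colour = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot the retention time series of a seeding run
#'
#' @param result a `seeding_result`.
#' @return a ggplot of retained cells per frame.
#' @export
plot_retention <- function(result) {
  stopifnot(inherits(result, "seeding_result"))
  ggplot2::ggplot(result$retention_series,
                  ggplot2::aes(.data$t_min, .data$retained_cells)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = result$protocol$seeding_duration_min,
                        linetype = 2) +
    ggplot2::labs(x = "time (min)", y = "retained cells",
                  title = sprintf("%s perfusion, %.2g ml/min",
                                  result$protocol$mode,
                                  result$protocol$rate_ml_min)) +
    ggplot2::theme_minimal()
}
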