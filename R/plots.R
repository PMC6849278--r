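#' Plot an isochrone activation map
#'
#' Tile map of per-electrode activation times with isochrone contours at the
#' requested interval; invalid electrodes are left blank. The y axis is
#' flipped so row 1 sits at the top, matching the physical grid layout.
#'
#' @param map an [ActivationMap-class].
#' @param interval isochrone step in ms.
#' @return a ggplot object.
#' @export
plotActivationMap <- function(map, interval = 10) {
  stopifnot(is(map, "ActivationMap"))
  iso <- buildIsochrones(map, interval)
  lab <- channelLabels(map@grid)
  df <- data.frame(row = lab[, "row"], col = lab[, "col"], at = map@at)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$at)) +
    ggplot2::geom_contour(
      ggplot2::aes(z = .data$at),
      breaks = isochroneLevels(iso), colour = "black",
      na.rm = TRUE) +
    ggplot2::scale_y_reverse(breaks = seq_len(map@grid@nRows)) +
    ggplot2::scale_x_continuous(breaks = seq_len(map@grid@nCols)) +
    ggplot2::scale_fill_viridis_c(name = "AT (ms)", na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "column", y = "row",
      title = sprintf("Beat %d: activation %0.1f-%0.1f ms after stimulus",
                      map@beatIndex, arrivalTime(map),
                      max(map@at[map@valid]))) +
    ggplot2::theme_minimal()
}

#' Plot a biomarker time course
#'
#' Per-experiment traces of one analyte with dashed reference limits, the
#' way perfusion blood panels are usually displayed.
#'
#' @param series long-format biomarker table (see [biomarkerSeries()]).
#' @param analyte which analyte to plot.
#' @return a ggplot object.
#' @export
plotBiomarker <- function(series, analyte) {
  series <- biomarkerSeries(series)
  d <- series[series$analyte == analyte, , drop = FALSE]
  if (!nrow(d)) stop("analyte not found: ", analyte)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$value,
                                       group = .data$experiment_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2, colour = "red3") +
    ggplot2::labs(x = "minutes from reperfusion",
                  y = sprintf("%s (%s)", analyte, d$unit[1L]),
                  title = analyte) +
    ggplot2::theme_minimal()
  for (rc in c("ref_low", "ref_high")) {
    lim <- d[[rc]][1L]
    if (!is.na(lim))
      p <- p + ggplot2::geom_hline(yintercept = lim, linetype = "dashed")
  }
  p
}
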