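#' Heatmap of a spatial response map
#'
#' Renders the level x order metric matrix as a colour-coded tile map, the
#' visual form of the spatial response.
#'
#' @param map A `spatial_response_map` from [spatial_map()].
#' @return A ggplot object.
#' @export
plot_spatial_map <- function(map) {
  stopifnot(inherits(map, "spatial_response_map"))
  vals <- unclass(map)
  df <- expand.grid(level = seq_len(nrow(vals)), order = seq_len(ncol(vals)))
  df$value <- as.numeric(vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$level,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(vals))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(vals))) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "wavelet order", y = "decomposition level",
                  fill = attr(map, "metric"),
                  title = sprintf("%s response, %s family",
                                  attr(map, "metric"), attr(map, "family")),
                  subtitle = if (is.finite(attr(map, "eta"))) {
                    sprintf("noise intensity eta = %g", attr(map, "eta"))
                  } else NULL) +
    ggplot2::theme_minimal()
}

#' Maximum-achievable-quality curve plot
#'
#' @param vr A `volumetric_response`, or a list of them (one curve per
#'   family).
#' @param aggregate Item aggregation, see [max_achievable_curve()].
#' @return A ggplot object.
#' @export
plot_max_achievable_curve <- function(vr, aggregate = "mean") {
  vrs <- as_vr_list(vr)
  df <- NULL
  for (fam in names(vrs)) {
    cur <- max_achievable_curve(vrs[[fam]], aggregate)
    cur$family <- fam
    df <- rbind(df, cur)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eta, y = .data$value,
                                   colour = .data$family)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "noise intensity (eta)",
                  y = sprintf("best achievable %s", vrs[[1]]$metric),
                  colour = "family") +
    ggplot2::theme_minimal()
}
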