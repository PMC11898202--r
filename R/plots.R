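#' Plot a synthetic scene with its ground-truth boxes
#'
#' Temperature raster with ear-root boxes overlaid, colored by anatomical
#' class. The y axis is reversed so the plot matches image orientation.
#'
#' @param object A `synthetic_scene`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.synthetic_scene <- function(object, ...) {
  fr <- object$frame
  df <- expand.grid(y = seq_len(nrow(fr$pixels)) - 0.5,
                    x = seq_len(ncol(fr$pixels)) - 0.5)
  df$temp <- gray_to_temp(as.vector(fr$pixels), fr$t_min, fr$t_max)
  polys <- tidyr::pivot_longer(
    object$boxes, cols = dplyr::all_of(.obb_cols),
    names_to = c(".value", "vertex"),
    names_pattern = "([xy])([1-4])")
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$temp)) +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$box_id,
                                       color = .data$class),
                          fill = NA, linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "degC") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot an ear pairing result
#'
#' Boxes with segments joining paired left/right centers, colored by
#' pairing stage.
#'
#' @param object An `ear_pairing`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ear_pairing <- function(object, ...) {
  boxes <- obb_centers(object$boxes)
  polys <- tidyr::pivot_longer(
    boxes, cols = dplyr::all_of(.obb_cols),
    names_to = c(".value", "vertex"),
    names_pattern = "([xy])([1-4])")
  p <- object$pairs
  segs <- purrr::map_dfr(seq_len(nrow(p)), function(k) {
    l <- boxes[boxes$box_id == p$left_id[k], ]
    r <- boxes[boxes$box_id == p$right_id[k], ]
    tibble(x = l$cx, y = l$cy, xend = r$cx, yend = r$cy,
           stage = p$stage[k])
  })
  g <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$box_id,
                                       linetype = .data$class),
                          fill = NA, color = "grey30", linewidth = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (nrow(segs) > 0) {
    g <- g + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, color = .data$stage),
      linewidth = 0.8)
  }
  g
}

#' Plot a bias analysis
#'
#' Histogram of per-sample biases with the mean bias and confidence
#' interval marked; the zero line shows at a glance whether the bias is
#' acceptable.
#'
#' @param object A `bias_analysis`.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.bias_analysis <- function(object, bins = 20, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bias)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            color = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$mean_bias, color = "red") +
    ggplot2::geom_vline(xintercept = c(object$conf_low, object$conf_high),
                        color = "red", linetype = "dotted") +
    ggplot2::labs(x = "bias (predicted - reference, degC)", y = "count")
}
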