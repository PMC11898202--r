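#' Convert gray levels to temperature
#'
#' The linear radiometric map of 8-bit thermal frames:
#' `T = (t_max - t_min) / 255 * P + t_min`, so gray 0 maps to the frame
#' minimum and gray 255 to the frame maximum. Strictly increasing in `P`.
#'
#' @param p Gray level(s) in \[0, 255\] (vectorized).
#' @param t_min,t_max Frame temperature extrema in degrees C.
#' @return Temperature(s) in degrees C.
#' @examples
#' gray_to_temp(128, 20, 40)
#' @export
gray_to_temp <- function(p, t_min, t_max) {
  if (any(p < 0 | p > 255)) stop("gray level outside [0, 255]", call. = FALSE)
  if (t_max <= t_min) stop("t_max must exceed t_min", call. = FALSE)
  (t_max - t_min) / 255 * p + t_min
}

#' Convert temperature to the nearest gray level
#'
#' Inverse of [gray_to_temp()] with rounding to the 8-bit grid; values
#' outside the frame range are clipped.
#'
#' @inheritParams gray_to_temp
#' @param t Temperature(s) in degrees C.
#' @return Integer gray level(s) in \[0, 255\].
#' @export
temp_to_gray <- function(t, t_min, t_max) {
  if (t_max <= t_min) stop("t_max must exceed t_min", call. = FALSE)
  pmin(pmax(round(255 * (t - t_min) / (t_max - t_min)), 0), 255)
}

#' Maximum temperature over oriented-box regions of interest
#'
#' Rasterizes each box onto the frame (pixel-center-inside membership) and
#' converts the maximum gray level to temperature. A box entirely outside
#' the frame yields `NA` with `n_px = 0` — an explicit no-measurement signal.
#'
#' @param frame A [thermal_frame()].
#' @param boxes A box tibble.
#' @return Tibble with `box_id`, `class`, `n_px`, `t_max_roi`.
#' @export
roi_max_temp <- function(frame, boxes) {
  .validate_boxes(boxes)
  dims <- dim(frame$pixels)
  purrr::map_dfr(seq_len(nrow(boxes)), function(i) {
    px <- rasterize_obb(obb_vertices(boxes, i), dims)
    tibble(box_id = boxes$box_id[i], class = boxes$class[i],
           n_px = nrow(px),
           t_max_roi = if (nrow(px) == 0) NA_real_ else {
             gray_to_temp(max(frame$pixels[px]), frame$t_min, frame$t_max)
           })
  })
}

#' Maximum temperature along a reference line band
#'
#' The reference region is a rectangular band of the given width centred on
#' the segment from `p0` to `p1`: pixels whose centers lie within
#' `width / 2` perpendicular distance of the segment, between the endpoint
#' projections, clipped to the frame. Its maximum temperature serves as the
#' manual reference value in agreement analysis.
#'
#' @param frame A [thermal_frame()].
#' @param p0,p1 Segment endpoints (length-2, pixel coordinates), distinct.
#' @param width Band width in pixels (default 5, the modal ear-root line
#'   width).
#' @return List with `t_ref` (`NA` if the band misses the frame) and `n_px`.
#' @export
reference_line_temp <- function(frame, p0, p1, width = 5) {
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  L <- sqrt(sum((p1 - p0)^2))
  if (L < 1e-9) stop("reference line endpoints must be distinct", call. = FALSE)
  u <- (p1 - p0) / L
  dims <- dim(frame$pixels)
  xr <- range(p0[1], p1[1]); yr <- range(p0[2], p1[2])
  c0 <- max(0L, floor(xr[1] - width)); c1 <- min(dims[2] - 1L, ceiling(xr[2] + width))
  r0 <- max(0L, floor(yr[1] - width)); r1 <- min(dims[1] - 1L, ceiling(yr[2] + width))
  if (c1 < c0 || r1 < r0) return(list(t_ref = NA_real_, n_px = 0L))
  cc <- seq.int(c0, c1); rr <- seq.int(r0, r1)
  px <- rep(cc, each = length(rr)) + 0.5
  py <- rep(rr, times = length(cc)) + 0.5
  t <- (px - p0[1]) * u[1] + (py - p0[2]) * u[2]
  perp <- abs((px - p0[1]) * u[2] - (py - p0[2]) * u[1])
  inside <- t >= 0 & t <= L & perp <= width / 2
  if (!any(inside)) return(list(t_ref = NA_real_, n_px = 0L))
  rows <- as.integer(py[inside] - 0.5) + 1L
  cols <- as.integer(px[inside] - 0.5) + 1L
  g <- max(frame$pixels[cbind(rows, cols)])
  list(t_ref = gray_to_temp(g, frame$t_min, frame$t_max),
       n_px = sum(inside))
}

#' Per-pig ear-root temperature records
#'
#' For every pair, extracts the maximum temperature over the left and right
#' ear-root boxes and reports the larger of the two as the pig's body
#' temperature. A pair with one empty ROI yields a single-ear record flagged
#' as degraded; both empty yields a no-measurement record.
#'
#' @param frame A [thermal_frame()].
#' @param pairing An `ear_pairing` (from [pair_ears()] or friends).
#' @return Tibble with one row per pair: `pair_id`, `left_id`, `right_id`,
#'   `t_left`, `t_right`, `t_pig`, `status` (`"ok"`, `"left_only"`,
#'   `"right_only"`, `"no_measurement"`).
#' @export
pig_temperature <- function(frame, pairing) {
  boxes <- pairing$boxes
  p <- pairing$pairs
  purrr::map_dfr(seq_len(nrow(p)), function(k) {
    lt <- roi_max_temp(frame, boxes[.box_row(boxes, p$left_id[k]), ])
    rt <- roi_max_temp(frame, boxes[.box_row(boxes, p$right_id[k]), ])
    tl <- lt$t_max_roi; tr <- rt$t_max_roi
    status <- if (is.na(tl) && is.na(tr)) "no_measurement"
      else if (is.na(tl)) "right_only"
      else if (is.na(tr)) "left_only"
      else "ok"
    tibble(pair_id = p$pair_id[k], left_id = p$left_id[k],
           right_id = p$right_id[k], t_left = tl, t_right = tr,
           t_pig = if (status == "no_measurement") NA_real_
                   else max(tl, tr, na.rm = TRUE),
           status = status)
  })
}
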