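#' Oriented-box tables
#'
#' Throughout the package a set of ear-root oriented bounding boxes is a
#' tibble with one box per row and columns:
#'
#' * `frame` — frame identifier (character),
#' * `box_id` — integer id, unique within a frame,
#' * `class` — `"left"` or `"right"` (detector / annotation class),
#' * `x1, y1, ..., x4, y4` — the four vertices in canonical cyclic order
#'   (see [canonicalize_vertices()]), 0-based pixel coordinates,
#' * `conf` — detection confidence in \[0, 1\], `NA` for ground truth.
#'
#' @name obb-tables
NULL

.obb_cols <- c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")

#' Assemble an oriented-box table from vertex matrices
#'
#' @param vertices A single 4x2 matrix or a list of them.
#' @param class Character vector of `"left"`/`"right"`, recycled.
#' @param frame Frame identifier, recycled.
#' @param conf Optional confidences, recycled.
#' @param box_id Optional integer ids; defaults to the sequence.
#' @return A box tibble (see [obb-tables]).
#' @examples
#' obb_table(rotated_rect(50, 50, 40, 8, pi / 6), class = "left")
#' @export
obb_table <- function(vertices, class, frame = "frame", conf = NA_real_,
                      box_id = NULL) {
  if (is.matrix(vertices)) vertices <- list(vertices)
  vertices <- lapply(vertices, canonicalize_vertices)
  n <- length(vertices)
  class <- rep_len(as.character(class), n)
  if (!all(class %in% c("left", "right"))) {
    stop("box class must be \"left\" or \"right\"", call. = FALSE)
  }
  coords <- matrix(numeric(0), nrow = 0, ncol = 8)
  if (n > 0) {
    coords <- do.call(rbind, lapply(vertices, function(v) as.vector(t(v))))
  }
  colnames(coords) <- .obb_cols
  tibble(
    frame = rep_len(as.character(frame), n),
    box_id = if (is.null(box_id)) seq_len(n) else as.integer(box_id),
    class = class,
    as_tibble(coords),
    conf = rep_len(as.numeric(conf), n)
  )
}

#' Extract the vertex matrix of one row of a box table
#'
#' @param boxes A box tibble.
#' @param i Row index (default 1).
#' @return 4x2 numeric matrix.
#' @export
obb_vertices <- function(boxes, i = 1L) {
  m <- matrix(unlist(boxes[i, .obb_cols], use.names = FALSE), ncol = 2,
              byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' Add center coordinates to a box table
#'
#' @param boxes A box tibble.
#' @return The table with `cx`, `cy` columns appended.
#' @export
obb_centers <- function(boxes) {
  boxes$cx <- rowMeans(boxes[, c("x1", "x2", "x3", "x4")])
  boxes$cy <- rowMeans(boxes[, c("y1", "y2", "y3", "y4")])
  boxes
}

.validate_boxes <- function(boxes) {
  need <- c("frame", "box_id", "class", .obb_cols)
  miss <- setdiff(need, names(boxes))
  if (length(miss) > 0) {
    stop("box table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(boxes)
}
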