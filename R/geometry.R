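#' @title Planar geometry for oriented bounding boxes
#'
#' @description Low-level geometry used throughout the package. All
#' coordinates are 0-based pixel coordinates: `x` is the column index
#' increasing rightward, `y` the row index increasing downward, origin at the
#' top-left corner of the frame. The pixel at (row `r`, col `c`) (0-based) has
#' its center at `(c + 0.5, r + 0.5)`.
#'
#' An oriented box is represented at this level as a 4x2 numeric matrix of
#' vertices, one `(x, y)` row per vertex.
#'
#' @name obb-geometry
NULL

.pt <- function(x, y) c(x = as.numeric(x), y = as.numeric(y))

#' Canonicalize the vertex order of an oriented box
#'
#' Reorders the four vertices of a convex quadrilateral to a fixed cyclic
#' order: counterclockwise in the y-down image frame (i.e. positive shoelace
#' signed area on the raw coordinates), starting at the vertex with the
#' smallest `(y, x)`. The operation is idempotent and preserves the point set.
#'
#' @param v 4x2 numeric matrix of vertices (columns x, y).
#' @return 4x2 numeric matrix in canonical order.
#' @examples
#' canonicalize_vertices(rbind(c(10, 0), c(0, 0), c(0, 10), c(10, 10)))
#' @export
canonicalize_vertices <- function(v) {
  v <- as.matrix(v)
  if (!is.numeric(v) || !identical(dim(v), c(4L, 2L)) || !all(is.finite(v))) {
    stop("vertices must be a finite 4x2 numeric matrix", call. = FALSE)
  }
  d <- stats::dist(v)
  if (min(d) < 1e-9) stop("degenerate box: duplicate vertices", call. = FALSE)
  ctr <- colMeans(v)
  ang <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  v <- v[order(ang), , drop = FALSE]
  # convexity / non-collinearity: successive cross products must be positive
  cr <- vapply(1:4, function(i) {
    a <- v[i, ]; b <- v[i %% 4 + 1, ]; c <- v[(i + 1) %% 4 + 1, ]
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }, numeric(1))
  if (any(cr <= 1e-9)) {
    stop("degenerate box: vertices are collinear or non-convex", call. = FALSE)
  }
  start <- order(v[, 2], v[, 1])[1]
  idx <- ((start - 1 + 0:3) %% 4) + 1
  out <- v[idx, , drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Polygon area by the shoelace formula
#'
#' @param v n x 2 matrix of polygon vertices in cyclic order.
#' @return Non-negative area.
#' @export
polygon_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' Center of an oriented box
#'
#' The arithmetic mean of the four vertices (equals the true center for a
#' rotated rectangle), invariant to vertex order.
#'
#' @param v 4x2 vertex matrix.
#' @return Length-2 named numeric `(x, y)`.
#' @export
obb_center <- function(v) {
  .pt(mean(v[, 1]), mean(v[, 2]))
}

#' Euclidean distance between the centers of two boxes
#'
#' @param a,b 4x2 vertex matrices.
#' @return Distance in pixels.
#' @export
center_distance <- function(a, b) {
  ca <- obb_center(a); cb <- obb_center(b)
  sqrt(sum((ca - cb)^2))
}

#' Nearest pair of vertices between two boxes
#'
#' Scans the 16 vertex pairs and returns the pair minimizing Euclidean
#' distance; ties are broken by the lowest canonical vertex index in `a`, then
#' in `b`, so the result is deterministic.
#'
#' @param a,b 4x2 vertex matrices (canonical order assumed for tie-breaking).
#' @return List with `p1` (vertex of `a`), `p2` (vertex of `b`), `i`, `j`
#'   (their indices) and `dist`.
#' @export
nearest_vertex_pair <- function(a, b) {
  d2 <- outer(1:4, 1:4, function(i, j) {
    (a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2
  })
  m <- min(d2)
  hit <- which(d2 - m < 1e-12, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- unname(hit[1, 1]); j <- unname(hit[1, 2])
  list(p1 = .pt(a[i, 1], a[i, 2]), p2 = .pt(b[j, 1], b[j, 2]),
       i = i, j = j, dist = sqrt(m))
}

#' Extreme vertices of a box relative to a base point
#'
#' Returns the vertex of the box nearest to `base` and the vertex farthest
#' from it (by default inclusive of a vertex coincident with `base`); ties
#' resolved by the lowest canonical vertex index. When the base point is
#' itself a vertex of the box, pass its index as `exclude` to select the
#' nearest *other* vertex; for an elongated box whose base vertex faces the
#' partner box, the excluded nearest/farthest pair spans the box's outer
#' long edge — the outermost line used by the precise pairing stage.
#'
#' @param v 4x2 vertex matrix.
#' @param base Length-2 numeric point.
#' @param exclude Optional vertex index excluded from the nearest-vertex
#'   search (the farthest search is unaffected).
#' @return List with `p_min`, `p_max`, `i_min`, `i_max`.
#' @export
extreme_vertices <- function(v, base, exclude = NULL) {
  d2 <- (v[, 1] - base[1])^2 + (v[, 2] - base[2])^2
  d2_min <- d2
  if (!is.null(exclude)) d2_min[exclude] <- Inf
  i_min <- which(d2_min - min(d2_min) < 1e-12)[1]
  i_max <- which(d2 - max(d2) > -1e-12)[1]
  list(p_min = .pt(v[i_min, 1], v[i_min, 2]),
       p_max = .pt(v[i_max, 1], v[i_max, 2]),
       i_min = i_min, i_max = i_max)
}

#' Line through two points, in normalized implicit form
#'
#' Returns coefficients `(a, b, c)` of `a*x + b*y + c = 0` with
#' `a^2 + b^2 = 1` and a canonical sign (first nonzero of `(a, b)` positive),
#' so vertical lines are representable and `line_through(p, q)` equals
#' `line_through(q, p)`.
#'
#' @param p,q Distinct length-2 numeric points.
#' @return Named numeric vector `c(a, b, c)`.
#' @export
line_through <- function(p, q) {
  if (sqrt(sum((p - q)^2)) < 1e-12) {
    stop("cannot construct a line through two identical points", call. = FALSE)
  }
  a <- p[2] - q[2]
  b <- q[1] - p[1]
  nrm <- sqrt(a^2 + b^2)
  a <- a / nrm; b <- b / nrm
  cc <- -(a * p[1] + b * p[2])
  if (a < -1e-12 || (abs(a) <= 1e-12 && b < 0)) {
    a <- -a; b <- -b; cc <- -cc
  }
  c(a = unname(a), b = unname(b), c = unname(cc))
}

#' Intersection point of two lines
#'
#' Lines are given in the normalized implicit form of [line_through()]. Lines
#' whose directions differ by less than the parallel tolerance (|sine of the
#' angle between them| < `tol`) have no usable intersection and `NULL` is
#' returned; callers treat this as a "no head origin" signal.
#'
#' @param l1,l2 Lines as `c(a, b, c)` with `a^2 + b^2 = 1`.
#' @param tol Parallel tolerance on the cross product of the unit normals.
#' @return Length-2 point, or `NULL` if the lines are (near-)parallel.
#' @export
line_intersection <- function(l1, l2, tol = 1e-6) {
  den <- l1[1] * l2[2] - l2[1] * l1[2]
  if (abs(den) < tol) return(NULL)
  x <- (l1[2] * l2[3] - l2[2] * l1[3]) / den
  y <- (l2[1] * l1[3] - l1[1] * l2[3]) / den
  .pt(x, y)
}

#' Polar coordinates of a point about an origin
#'
#' The angle is measured counterclockwise from the +x axis in the
#' conventional y-up mathematical sense: it is computed on the vector
#' `(p_x - o_x, o_y - p_y)`, so a point directly above the origin in the
#' image (smaller y) has angle 90 degrees.
#'
#' @param p Length-2 point, distinct from `origin`.
#' @param origin Length-2 origin.
#' @return Named numeric `c(radius, angle)`, angle in degrees in [0, 360).
#' @export
polar_angle <- function(p, origin) {
  dx <- p[1] - origin[1]
  dy <- origin[2] - p[2]
  r <- sqrt(dx^2 + dy^2)
  if (r < 1e-12) stop("point coincides with the polar origin", call. = FALSE)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  c(radius = unname(r), angle = unname(ang))
}

# Sutherland-Hodgman clip of convex polygon `subj` by convex polygon `clip`,
# both counterclockwise in the coordinate (y-down) sense.
.clip_convex <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[k, ]; b <- clip[k %% nc + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(2:n, 1)
    res <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      j <- nxt[i]
      ci <- side[i] >= -1e-9
      cj <- side[j] >= -1e-9
      if (ci) res <- rbind(res, out[i, ])
      if (ci != cj) {
        t <- side[i] / (side[i] - side[j])
        res <- rbind(res, out[i, ] + t * (out[j, ] - out[i, ]))
      }
    }
    out <- res
  }
  if (nrow(out) < 3) NULL else out
}

#' Intersection-over-union of two oriented boxes
#'
#' Exact rotated IoU via convex polygon clipping: the intersection polygon is
#' computed with the Sutherland-Hodgman algorithm and areas with the shoelace
#' formula. Symmetric; 1 for geometrically identical boxes; 0 for disjoint
#' boxes.
#'
#' @param a,b 4x2 vertex matrices.
#' @return IoU in [0, 1].
#' @export
rotated_iou <- function(a, b) {
  a <- canonicalize_vertices(a)
  b <- canonicalize_vertices(b)
  inter <- .clip_convex(a, b)
  ai <- if (is.null(inter)) 0 else polygon_area(inter)
  aa <- polygon_area(a); ab <- polygon_area(b)
  un <- aa + ab - ai
  if (un <= 0) return(0)
  min(max(ai / un, 0), 1)
}

#' Rasterize an oriented box onto a pixel grid
#'
#' Returns all pixels whose centers lie inside or on the boundary of the
#' quadrilateral, clipped to the frame. Pixel membership uses the
#' pixel-center-inside test: the 0-based pixel (r, c) has center
#' `(c + 0.5, r + 0.5)`. Indices are returned 1-based for direct use with R
#' matrices.
#'
#' @param v 4x2 vertex matrix.
#' @param dim Frame dimensions `c(rows, cols)`.
#' @return Integer matrix with columns `row`, `col` (1-based); zero rows if
#'   the box lies entirely outside the frame.
#' @export
rasterize_obb <- function(v, dim) {
  v <- canonicalize_vertices(v)
  rows <- dim[1]; cols <- dim[2]
  c0 <- max(0L, floor(min(v[, 1]) - 0.5))
  c1 <- min(cols - 1L, ceiling(max(v[, 1]) - 0.5))
  r0 <- max(0L, floor(min(v[, 2]) - 0.5))
  r1 <- min(rows - 1L, ceiling(max(v[, 2]) - 0.5))
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
  if (c1 < c0 || r1 < r0) return(empty)
  cc <- seq.int(c0, c1); rr <- seq.int(r0, r1)
  px <- rep(cc, each = length(rr)) + 0.5
  py <- rep(rr, times = length(cc)) + 0.5
  inside <- rep(TRUE, length(px))
  for (i in 1:4) {
    a <- v[i, ]; b <- v[i %% 4 + 1, ]
    inside <- inside &
      ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1]) >= -1e-9)
  }
  if (!any(inside)) return(empty)
  cbind(row = as.integer(py[inside] - 0.5) + 1L,
        col = as.integer(px[inside] - 0.5) + 1L)
}

#' Build a rotated rectangle from center, size and angle
#'
#' Utility constructor used by the I/O converters and the scene generator.
#' The rectangle of width `w` (along the axis) and height `h` is rotated by
#' `angle` radians clockwise in the image frame (the roLabelImg convention)
#' about its center.
#'
#' @param cx,cy Center coordinates.
#' @param w,h Side lengths: `w` along the unrotated x axis, `h` along y.
#' @param angle Rotation in radians, clockwise in the y-down image frame.
#' @return 4x2 canonical vertex matrix.
#' @export
rotated_rect <- function(cx, cy, w, h, angle = 0) {
  ca <- cos(angle); sa <- sin(angle)
  dx <- c(-w, w, w, -w) / 2
  dy <- c(-h, -h, h, h) / 2
  canonicalize_vertices(cbind(cx + dx * ca - dy * sa,
                              cy + dx * sa + dy * ca))
}
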