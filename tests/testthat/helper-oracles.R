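# Independent oracles and fixture builders used across the suite.

rand_rect <- function(xlim = c(20, 80), ylim = c(20, 80),
                      len = c(10, 40), wid = c(5, 20)) {
  rotated_rect(runif(1, xlim[1], xlim[2]), runif(1, ylim[1], ylim[2]),
               runif(1, len[1], len[2]), runif(1, wid[1], wid[2]),
               runif(1, 0, pi))
}

# dense pixel-center-count IoU oracle over the pair's joint bounding box
raster_iou_oracle <- function(a, b, n = 500) {
  xr <- range(a[, 1], b[, 1]); yr <- range(a[, 2], b[, 2])
  xs <- seq(xr[1], xr[2], length.out = n)
  ys <- seq(yr[1], yr[2], length.out = n)
  px <- rep(xs, each = n); py <- rep(ys, times = n)
  inside <- function(v) {
    r <- rep(TRUE, length(px))
    for (k in 1:4) {
      p <- v[k, ]; q <- v[k %% 4 + 1, ]
      r <- r & ((q[1] - p[1]) * (py - p[2]) -
                  (q[2] - p[2]) * (px - p[1]) >= 0)
    }
    r
  }
  ia <- inside(canonicalize_vertices(a))
  ib <- inside(canonicalize_vertices(b))
  u <- sum(ia | ib)
  if (u == 0) 0 else sum(ia & ib) / u
}

# exhaustive 16-pair scan
brute_nearest <- function(a, b) {
  best <- NULL; bd <- Inf
  for (i in 1:4) for (j in 1:4) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < bd - 1e-12) { bd <- d; best <- list(i = i, j = j, dist = d) }
  }
  best
}

# exhaustive 4-vertex scan
brute_extreme <- function(v, base) {
  d <- sqrt((v[, 1] - base[1])^2 + (v[, 2] - base[2])^2)
  list(i_min = which.min(d), i_max = which.max(d))
}

# independent all-point-interpolated AP: direct per-positive scan, no
# running-max shortcut
brute_ap <- function(tp_ranked, n_positive) {
  n <- length(tp_ranked)
  if (n == 0) return(0)
  cum_tp <- cumsum(tp_ranked)
  prec <- cum_tp / seq_len(n)
  rec <- cum_tp / n_positive
  total <- 0
  prev <- 0
  for (k in seq_len(n)) {
    if (!tp_ranked[k]) next
    p_interp <- max(prec[rec >= rec[k] - 1e-12])
    total <- total + (rec[k] - prev) * p_interp
    prev <- rec[k]
  }
  total
}

# step-by-step greedy minimum-distance matching simulation
greedy_oracle <- function(boxes, d_min, d_max, class_constrained = FALSE) {
  ctr <- obb_centers(boxes)
  alive <- rep(TRUE, nrow(boxes))
  picks <- list()
  repeat {
    best <- NULL; bd <- Inf
    for (i in seq_len(nrow(boxes))) for (j in seq_len(nrow(boxes))) {
      if (i >= j || !alive[i] || !alive[j]) next
      if (class_constrained && boxes$class[i] == boxes$class[j]) next
      d <- sqrt((ctr$cx[i] - ctr$cx[j])^2 + (ctr$cy[i] - ctr$cy[j])^2)
      if (d < d_min || d > d_max) next
      if (d < bd - 1e-12) { bd <- d; best <- c(i, j) }
    }
    if (is.null(best)) break
    alive[best] <- FALSE
    picks[[length(picks) + 1]] <- sort(boxes$box_id[best])
  }
  picks
}

# convenience: a horizontally laid-out left/right ear pair of one pig
# facing "up" the image, ears d apart, centered at (cx, cy)
simple_pig_boxes <- function(cx = 190, cy = 160, d = 120, splay = 32,
                             len = 40, wid = 8) {
  psi <- splay * pi / 180
  r <- (d / 2) / sin(psi)
  k <- c(cx, cy - r * cos(psi))
  phi <- c(0, -1)
  rot <- function(v, a) c(v[1] * cos(a) - v[2] * sin(a),
                          v[1] * sin(a) + v[2] * cos(a))
  mk <- function(sgn) {
    u <- rot(phi, sgn * psi)
    ctr <- k - r * u
    v <- c(-u[2], u[1])
    canonicalize_vertices(rbind(ctr + len / 2 * u + wid / 2 * v,
                                ctr + len / 2 * u - wid / 2 * v,
                                ctr - len / 2 * u - wid / 2 * v,
                                ctr - len / 2 * u + wid / 2 * v))
  }
  obb_table(list(mk(1), mk(-1)), class = c("left", "right"))
}
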