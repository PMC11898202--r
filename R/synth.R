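#' Synthetic scene configuration
#'
#' Parameters of the synthetic thermal-scene generator. Geometry defaults
#' emulate the statistical structure the pairing pipeline assumes: pairs of
#' elongated hot ear-root regions arranged in the splayed, head-converging
#' "eight" configuration, same-pig ear-center distances uniform on 80–160 px
#' on a 288 x 384 frame. Temperature levels are plausible for fattening pigs
#' under barn conditions (background about 21 degC, body surface 30–34 degC,
#' ear-root peak 35–39 degC) and are fully configurable.
#'
#' @param frame_rows,frame_cols Frame size in pixels (default 288 x 384).
#' @param n_pigs Number of pigs (ignored by the adversarial modes, which fix
#'   their own layouts).
#' @param d_range Same-pig ear-center distance range in px.
#' @param splay_range Ear splay half-angle range in degrees (angle between
#'   each ear's long axis and the heading).
#' @param ear_length,ear_width Ear-root box side ranges in px.
#' @param bg_mean,bg_sd Background temperature mean and per-pixel spatial
#'   standard deviation, degC.
#' @param body_range Body-surface temperature range, degC.
#' @param ear_peak_range Ear-root peak temperature range, degC.
#' @param noise_sd Additive Gaussian sensor noise, in gray levels.
#' @param ear_attenuation_sd Length-2 `(left, right)`: each ear's realized
#'   peak is the pig's nominal temperature minus the absolute value of a
#'   zero-mean Gaussian with this sd (degC); emulates pose, hair and dirt
#'   losses. Zero by default.
#' @param adversarial `"none"`, `"touching_heads"` (two pigs colliding
#'   head-on with a lateral offset so the nearest in-window candidate is a
#'   same-class cross-pig pair, forcing a rough mispairing that the precise
#'   stage can detect and repair) or `"edge_clip"` (one pig partially
#'   outside the frame).
#' @param th_offset,th_gap,th_d,th_splay Touching-heads geometry band:
#'   lateral head offset range, ear-row gap range, same-pig distance range
#'   and splay range.
#' @param th_jitter Heading jitter of the second pig away from exactly
#'   head-on, degrees.
#' @param line_width Width of the hottest central line along each ear axis
#'   (px; the modal ear-root line width).
#' @param line_inset Inset of the central line endpoints from the ear box
#'   ends (px).
#' @param margin Placement margin from the frame border (px).
#' @param max_tries Bounded placement retries before failing.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(frame_rows = 288, frame_cols = 384, n_pigs = 1,
                         d_range = c(80, 160), splay_range = c(25, 40),
                         ear_length = c(30, 50), ear_width = c(6, 10),
                         bg_mean = 21, bg_sd = 0.8,
                         body_range = c(30, 34), ear_peak_range = c(35, 39),
                         noise_sd = 0.5,
                         ear_attenuation_sd = c(left = 0, right = 0),
                         adversarial = c("none", "touching_heads",
                                         "edge_clip"),
                         th_offset = c(15, 50), th_gap = c(45, 70),
                         th_d = c(130, 150), th_splay = c(32, 38),
                         th_jitter = 12,
                         line_width = 5, line_inset = 3,
                         margin = 12, max_tries = 200) {
  adversarial <- match.arg(adversarial)
  stopifnot(d_range[1] < d_range[2], splay_range[1] < splay_range[2],
            body_range[1] < body_range[2],
            ear_peak_range[1] > body_range[2], body_range[1] > bg_mean)
  structure(as.list(environment()), class = "scene_config")
}

# y-down rotation: positive angle turns +x toward +y (visually clockwise)
.rot <- function(v, a) {
  c(v[1] * cos(a) - v[2] * sin(a), v[1] * sin(a) + v[2] * cos(a))
}

# ear box vertices from center, unit long axis, length and width
.ear_box <- function(ctr, u, len, wid) {
  v <- c(-u[2], u[1])
  canonicalize_vertices(rbind(
    ctr + len / 2 * u + wid / 2 * v,
    ctr + len / 2 * u - wid / 2 * v,
    ctr - len / 2 * u - wid / 2 * v,
    ctr - len / 2 * u + wid / 2 * v))
}

#' Generate the ground-truth geometry of one pig
#'
#' Samples (from the current RNG state) a head convergence point, heading
#' and ear geometry: the two ear-root boxes are placed symmetrically about
#' the heading axis with their long axes converging at the head point ahead
#' of the ears (narrow end head-ward), center separation drawn from the
#' configured distance distribution. The anatomical left ear lies on the
#' pig's left when facing along the heading (heading rotated -90 degrees in
#' the y-down frame). A warm elliptical body sits behind the ears.
#'
#' @param config A [scene_config()].
#' @param k Optional head point `c(x, y)`; sampled inside the frame if
#'   missing.
#' @param heading Optional heading angle in radians; sampled if missing.
#' @param d,splay Optional overrides for ear-center distance (px) and splay
#'   half-angle (degrees).
#' @return List describing the pig: head point `k`, heading vector `phi`,
#'   `d`, `psi`, per-ear boxes/axes/reference lines, body ellipse, nominal
#'   and per-ear peak temperatures.
#' @export
generate_pig <- function(config, k = NULL, heading = NULL, d = NULL,
                         splay = NULL) {
  if (is.null(heading)) heading <- runif(1, 0, 2 * pi)
  phi <- c(cos(heading), sin(heading))
  if (is.null(k)) {
    k <- c(runif(1, config$margin, config$frame_cols - config$margin),
           runif(1, config$margin, config$frame_rows - config$margin))
  }
  if (is.null(d)) d <- runif(1, config$d_range[1], config$d_range[2])
  if (is.null(splay)) {
    splay <- runif(1, config$splay_range[1], config$splay_range[2])
  }
  psi <- splay * pi / 180
  r <- (d / 2) / sin(psi)
  u_l <- .rot(phi, psi)   # axis of the left ear, pointing head-ward
  u_r <- .rot(phi, -psi)
  c_l <- k - r * u_l
  c_r <- k - r * u_r
  len <- runif(2, config$ear_length[1], config$ear_length[2])
  wid <- runif(2, config$ear_width[1], config$ear_width[2])
  t_nominal <- runif(1, config$ear_peak_range[1], config$ear_peak_range[2])
  att <- abs(rnorm(2, 0, config$ear_attenuation_sd))
  floor_t <- config$body_range[2] + 0.3
  t_ear <- pmax(t_nominal - att, floor_t)
  t_body <- runif(1, config$body_range[1], config$body_range[2])
  ref <- function(ctr, u, len) {
    off <- max(len / 2 - config$line_inset, 1)
    rbind(ctr - off * u, ctr + off * u)
  }
  body_ctr <- k - (r * cos(psi) + 35) * phi
  list(k = k, phi = phi, heading = heading, d = d, psi = splay,
       t_nominal = t_nominal, t_body = t_body,
       ears = list(
         left = list(v = .ear_box(c_l, u_l, len[1], wid[1]), ctr = c_l,
                     axis = u_l, t_peak = t_ear[1],
                     ref = ref(c_l, u_l, len[1])),
         right = list(v = .ear_box(c_r, u_r, len[2], wid[2]), ctr = c_r,
                      axis = u_r, t_peak = t_ear[2],
                      ref = ref(c_r, u_r, len[2]))),
       body = list(ctr = body_ctr, a = 45, b = 30, phi = phi))
}

.ears_in_frame <- function(pig, config, margin = config$margin) {
  ok <- function(v) {
    all(v[, 1] >= margin & v[, 1] <= config$frame_cols - margin &
        v[, 2] >= margin & v[, 2] <= config$frame_rows - margin)
  }
  ok(pig$ears$left$v) && ok(pig$ears$right$v)
}

.pig_ear_centers <- function(pig) {
  rbind(pig$ears$left$ctr, pig$ears$right$ctr)
}

# rotate + translate every geometric element of a pig
.transform_pig <- function(pig, rho, shift) {
  tr_p <- function(p) .rot(p, rho) + shift
  tr_m <- function(m) t(apply(m, 1, tr_p))
  for (side in c("left", "right")) {
    pig$ears[[side]]$v <- canonicalize_vertices(tr_m(pig$ears[[side]]$v))
    pig$ears[[side]]$ctr <- tr_p(pig$ears[[side]]$ctr)
    pig$ears[[side]]$axis <- .rot(pig$ears[[side]]$axis, rho)
    pig$ears[[side]]$ref <- tr_m(pig$ears[[side]]$ref)
  }
  pig$k <- tr_p(pig$k)
  pig$phi <- .rot(pig$phi, rho)
  pig$heading <- (pig$heading + rho) %% (2 * pi)
  pig$body$ctr <- tr_p(pig$body$ctr)
  pig$body$phi <- pig$phi
  pig
}

# Colliding-heads layout: pig A faces +y ("down" in the local frame), pig B
# faces roughly -y, their heads pushed past one another with a lateral
# offset, so the nearest in-window candidate is a SAME-class cross-pig pair
# (A's left ear with B's left ear) while both opposite-class cross distances
# fall below the pairing window. Greedy minimum-distance rough pairing then
# mispairs the two left ears; the detector labels refute that pair in the
# precise stage and re-pairing restores both same-pig pairs.
.place_touching_heads <- function(config) {
  win <- c(80, 160)  # the nominal pairing window the layout is built against
  for (try in seq_len(config$max_tries)) {
    d <- runif(1, config$th_d[1], config$th_d[2])
    splay <- runif(1, config$th_splay[1], config$th_splay[2])
    ox <- runif(1, config$th_offset[1], config$th_offset[2])
    h <- runif(1, config$th_gap[1], config$th_gap[2])
    eps <- runif(1, -config$th_jitter, config$th_jitter) * pi / 180
    psi <- splay * pi / 180
    f <- (d / 2) / tan(psi)
    pig_a <- generate_pig(config, k = c(0, 0), heading = pi / 2,
                          d = d, splay = splay)
    pig_b <- generate_pig(config, k = c(ox, h - 2 * f),
                          heading = -pi / 2 + eps, d = d, splay = splay)
    ctr_a <- .pig_ear_centers(pig_a)  # rows: left, right
    ctr_b <- .pig_ear_centers(pig_b)
    dd <- function(p, q) sqrt(sum((p - q)^2))
    d_ll <- dd(ctr_a[1, ], ctr_b[1, ])
    d_rr <- dd(ctr_a[2, ], ctr_b[2, ])
    d_lr <- dd(ctr_a[1, ], ctr_b[2, ])
    d_rl <- dd(ctr_a[2, ], ctr_b[1, ])
    ok <- d_ll >= win[1] + 2 && d_ll <= d - 8 &&
      (d_lr < win[1] - 2 || d_lr > win[2] + 2) &&
      (d_rl < win[1] - 2 || d_rl > win[2] + 2) &&
      (d_rr < win[1] - 2 || d_rr > win[2] + 2)
    if (!ok) next
    rho <- runif(1, 0, 2 * pi)
    shift <- c(runif(1, 0.3 * config$frame_cols, 0.7 * config$frame_cols),
               runif(1, 0.35 * config$frame_rows, 0.65 * config$frame_rows))
    a <- .transform_pig(pig_a, rho, shift)
    b <- .transform_pig(pig_b, rho, shift)
    if (.ears_in_frame(a, config) && .ears_in_frame(b, config)) {
      return(list(a, b))
    }
  }
  stop("could not place touching-heads layout inside the frame", call. = FALSE)
}

.place_edge_clip <- function(config) {
  for (try in seq_len(config$max_tries)) {
    side <- sample(4, 1)
    k <- switch(side,
      c(runif(1, -10, 30), runif(1, 40, config$frame_rows - 40)),
      c(runif(1, config$frame_cols - 30, config$frame_cols + 10),
        runif(1, 40, config$frame_rows - 40)),
      c(runif(1, 40, config$frame_cols - 40), runif(1, -10, 30)),
      c(runif(1, 40, config$frame_cols - 40),
        runif(1, config$frame_rows - 30, config$frame_rows + 10)))
    pig <- generate_pig(config, k = k)
    vv <- rbind(pig$ears$left$v, pig$ears$right$v)
    outside <- any(vv[, 1] < 0 | vv[, 1] > config$frame_cols |
                   vv[, 2] < 0 | vv[, 2] > config$frame_rows)
    ctr_in <- all(.pig_ear_centers(pig)[, 1] > 0 &
                  .pig_ear_centers(pig)[, 1] < config$frame_cols &
                  .pig_ear_centers(pig)[, 2] > 0 &
                  .pig_ear_centers(pig)[, 2] < config$frame_rows)
    if (outside && ctr_in) return(list(pig))
  }
  stop("could not place edge-clipped pig", call. = FALSE)
}

.place_pigs <- function(config) {
  if (config$adversarial == "touching_heads") {
    return(.place_touching_heads(config))
  }
  if (config$adversarial == "edge_clip") return(.place_edge_clip(config))
  # whole-scene restart: a first pig landing mid-frame can make a clash-free
  # second placement infeasible, so placement failures restart every pig
  for (restart in seq_len(config$max_tries)) {
    pigs <- list()
    for (i in seq_len(config$n_pigs)) {
      placed <- FALSE
      for (try in seq_len(config$max_tries)) {
        pig <- generate_pig(config)
        if (!.ears_in_frame(pig, config)) next
        ctrs <- .pig_ear_centers(pig)
        clash <- any(vapply(pigs, function(q) {
          qc <- .pig_ear_centers(q)
          min(sqrt(outer(ctrs[, 1], qc[, 1], "-")^2 +
                   outer(ctrs[, 2], qc[, 2], "-")^2)) <=
            config$d_range[2] + 10
        }, logical(1)))
        if (!clash) { pigs[[i]] <- pig; placed <- TRUE; break }
      }
      if (!placed) break
    }
    if (length(pigs) == config$n_pigs) return(pigs)
  }
  stop("could not place ", config$n_pigs, " pigs after bounded retries",
       call. = FALSE)
}

# pixel-center band membership (same membership rule as reference_line_temp)
.band_pixels <- function(p0, p1, width, dims) {
  L <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / L
  xr <- range(p0[1], p1[1]); yr <- range(p0[2], p1[2])
  c0 <- max(0L, floor(xr[1] - width)); c1 <- min(dims[2] - 1L, ceiling(xr[2] + width))
  r0 <- max(0L, floor(yr[1] - width)); r1 <- min(dims[1] - 1L, ceiling(yr[2] + width))
  if (c1 < c0 || r1 < r0) {
    return(matrix(integer(0), ncol = 2))
  }
  cc <- seq.int(c0, c1); rr <- seq.int(r0, r1)
  px <- rep(cc, each = length(rr)) + 0.5
  py <- rep(rr, times = length(cc)) + 0.5
  t <- (px - p0[1]) * u[1] + (py - p0[2]) * u[2]
  perp <- abs((px - p0[1]) * u[2] - (py - p0[2]) * u[1])
  inside <- t >= 0 & t <= L & perp <= width / 2
  cbind(as.integer(py[inside] - 0.5) + 1L, as.integer(px[inside] - 0.5) + 1L)
}

.ellipse_pixels <- function(ctr, a, b, phi, dims) {
  c0 <- max(0L, floor(ctr[1] - a - 1)); c1 <- min(dims[2] - 1L, ceiling(ctr[1] + a + 1))
  r0 <- max(0L, floor(ctr[2] - a - 1)); r1 <- min(dims[1] - 1L, ceiling(ctr[2] + a + 1))
  if (c1 < c0 || r1 < r0) return(matrix(integer(0), ncol = 2))
  cc <- seq.int(c0, c1); rr <- seq.int(r0, r1)
  px <- rep(cc, each = length(rr)) + 0.5
  py <- rep(rr, times = length(cc)) + 0.5
  dx <- px - ctr[1]; dy <- py - ctr[2]
  al <- dx * phi[1] + dy * phi[2]
  cr <- -dx * phi[2] + dy * phi[1]
  inside <- (al / a)^2 + (cr / b)^2 <= 1
  cbind(as.integer(py[inside] - 0.5) + 1L,
        as.integer(px[inside] - 0.5) + 1L)
}

#' Generate a synthetic thermal scene with full ground truth
#'
#' Composites a temperature field (background, warm elliptical bodies,
#' hotter ear-root rectangles, each with a hottest central line of the
#' configured width along its axis), adds Gaussian sensor noise, records the
#' field's extrema as the frame's `t_min`/`t_max`, and quantizes to 8 bits
#' with the inverse of the linear radiometric map. Fully reproducible for a
#' given seed.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; the scene is a pure function of
#'   `(config, seed)`.
#' @return Object of class `synthetic_scene`: `frame` (a [thermal_frame()]),
#'   `boxes` (ground-truth box tibble), `pairs` (pig, left_id, right_id,
#'   center distance), `ears` (per-ear planted peak temperatures and
#'   reference-line endpoints), `pigs` (per-pig heading and nominal
#'   temperature), `config`, `seed`.
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  withr::with_seed(seed, {
    pigs <- .place_pigs(config)
    dims <- c(config$frame_rows, config$frame_cols)
    field <- matrix(rnorm(prod(dims), config$bg_mean, config$bg_sd),
                    dims[1], dims[2])
    for (pig in pigs) {
      px <- .ellipse_pixels(pig$body$ctr, pig$body$a, pig$body$b,
                            pig$body$phi, dims)
      if (nrow(px) > 0) field[px] <- pig$t_body
    }
    for (pig in pigs) {
      for (side in c("left", "right")) {
        ear <- pig$ears[[side]]
        px <- rasterize_obb(ear$v, dims)
        if (nrow(px) > 0) field[px] <- ear$t_peak - 1.2
        band <- .band_pixels(ear$ref[1, ], ear$ref[2, ], config$line_width,
                             dims)
        if (nrow(band) > 0) field[band] <- ear$t_peak
      }
    }
    if (config$noise_sd > 0) {
      span <- diff(range(field))
      field <- field + rnorm(length(field), 0,
                             config$noise_sd * span / 255)
    }
    t_min <- min(field); t_max <- max(field)
    frame_id <- sprintf("scene_%d", seed)
    frame <- thermal_frame(temp_to_gray(field, t_min, t_max), t_min, t_max,
                           id = frame_id)

    verts <- list(); classes <- character(0)
    ears <- list(); pair_rows <- list(); pig_rows <- list()
    bid <- 0L
    for (i in seq_along(pigs)) {
      pg <- pigs[[i]]
      ids <- c(left = bid + 1L, right = bid + 2L)
      for (side in c("left", "right")) {
        bid <- bid + 1L
        ear <- pg$ears[[side]]
        verts[[bid]] <- ear$v
        classes <- c(classes, side)
        ears[[bid]] <- tibble(
          pig = i, class = side, box_id = bid, t_peak = ear$t_peak,
          ref_x0 = ear$ref[1, 1], ref_y0 = ear$ref[1, 2],
          ref_x1 = ear$ref[2, 1], ref_y1 = ear$ref[2, 2])
      }
      pair_rows[[i]] <- tibble(pig = i, left_id = ids[["left"]],
                               right_id = ids[["right"]], d = pg$d)
      pig_rows[[i]] <- tibble(pig = i, k_x = pg$k[1], k_y = pg$k[2],
                              heading = pg$heading, d = pg$d,
                              psi = pg$psi, t_nominal = pg$t_nominal,
                              t_body = pg$t_body)
    }
    structure(list(
      frame = frame,
      boxes = obb_table(verts, classes, frame = frame_id),
      pairs = dplyr::bind_rows(pair_rows),
      ears = dplyr::bind_rows(ears),
      pigs = dplyr::bind_rows(pig_rows),
      config = config, seed = seed), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene seed %d: %d pig(s), %s mode, %d x %d px>\n",
              x$seed, nrow(x$pigs), x$config$adversarial,
              nrow(x$frame$pixels), ncol(x$frame$pixels)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_frames` scenes with per-frame seeds derived from `seed` and
#' writes, for each, an 8-bit PNG frame, a JSON temperature sidecar and a
#' ground-truth label TXT, plus a CSV manifest of true pairs, planted
#' temperatures and reference lines.
#'
#' @param config A [scene_config()].
#' @param n_frames Number of frames.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param dialect Label TXT dialect (see [write_obb_txt()]).
#' @return The manifest tibble, invisibly. The manifest is also written as
#'   `manifest.csv`.
#' @export
generate_dataset <- function(config = scene_config(), n_frames, out_dir,
                             seed = 1L, dialect = "normalized") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  frame_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max - 1,
                                             n_frames))
  manifest <- purrr::map_dfr(seq_len(n_frames), function(i) {
    sc <- generate_scene(config, seed = frame_seeds[i])
    stem <- sprintf("frame_%04d", i)
    write_thermal_frame(sc$frame, file.path(out_dir, paste0(stem, ".png")))
    write_obb_txt(sc$boxes, file.path(out_dir, paste0(stem, ".txt")),
                  dialect = dialect,
                  frame_shape = dim(sc$frame$pixels))
    dplyr::left_join(sc$pairs,
                     dplyr::bind_cols(
                       tidyr::pivot_wider(
                         sc$ears[, c("pig", "class", "t_peak")],
                         names_from = "class", values_from = "t_peak",
                         names_prefix = "t_peak_"),
                       sc$pigs[, c("t_nominal", "t_body")]),
                     by = "pig") |>
      dplyr::mutate(frame = stem, seed = frame_seeds[i], .before = 1)
  })
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
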