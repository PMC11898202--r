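#' Pairing configuration
#'
#' Controls the two-stage ear-root pairing. The rough stage matches boxes by
#' minimum center distance inside the window `[d_min, d_max]`; the default
#' 80–160 px window is the empirical range of same-pig ear-center distances
#' at the nominal camera geometry.
#'
#' @param d_min,d_max Center-distance window in pixels, `0 < d_min < d_max`.
#' @param class_constrained Should the rough stage only consider one
#'   detector-left with one detector-right box? Default `FALSE`: rough
#'   pairing is purely geometric (minimum center distance), so a mispairing
#'   of two same-class ears is possible — and it is exactly the mispairing
#'   that the precise stage's detector-consistency test is guaranteed to
#'   catch. The constrained mode is available as an option.
#' @param parallel_fallback What to do with a pair whose outermost lines are
#'   parallel (no polar origin): `"keep_rough"` (default) keeps the rough
#'   pairing and detector labels, flagged as stage `"fallback"`; `"drop"`
#'   dissolves the pair into the unpaired pool.
#' @return A list of class `pairing_config`.
#' @export
pairing_config <- function(d_min = 80, d_max = 160,
                           class_constrained = FALSE,
                           parallel_fallback = c("keep_rough", "drop")) {
  parallel_fallback <- match.arg(parallel_fallback)
  if (!(d_min > 0 && d_max > d_min)) {
    stop("need 0 < d_min < d_max", call. = FALSE)
  }
  structure(list(d_min = d_min, d_max = d_max,
                 class_constrained = isTRUE(class_constrained),
                 parallel_fallback = parallel_fallback),
            class = "pairing_config")
}

.empty_pairs <- function() {
  tibble(pair_id = integer(0), left_id = integer(0), right_id = integer(0),
         center_dist = numeric(0), stage = character(0),
         theta = numeric(0), theta_left = numeric(0),
         theta_right = numeric(0), o_x = numeric(0), o_y = numeric(0),
         consistent = logical(0))
}

# Greedy minimum-center-distance matching over a candidate edge table.
# cand: tibble(i, j, dist) with i, j row indices into `boxes`, already
# filtered to the distance window and ordered by (dist, i, j).
.greedy_match <- function(cand, n_boxes) {
  free <- rep(TRUE, n_boxes)
  picks <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (free[i] && free[j]) {
      free[i] <- FALSE; free[j] <- FALSE
      picks[[length(picks) + 1]] <- c(i, j)
    }
  }
  list(picks = picks, free = free)
}

.candidate_edges <- function(boxes, cfg, forbidden = NULL) {
  n <- nrow(boxes)
  if (n < 2) return(tibble(i = integer(0), j = integer(0), dist = numeric(0)))
  ctr <- obb_centers(boxes)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i < idx$j, , drop = FALSE]
  if (cfg$class_constrained) {
    ok <- boxes$class[idx$i] != boxes$class[idx$j]
    idx <- idx[ok, , drop = FALSE]
  }
  d <- sqrt((ctr$cx[idx$i] - ctr$cx[idx$j])^2 +
            (ctr$cy[idx$i] - ctr$cy[idx$j])^2)
  keep <- d >= cfg$d_min & d <= cfg$d_max
  idx <- idx[keep, , drop = FALSE]; d <- d[keep]
  if (!is.null(forbidden) && nrow(idx) > 0) {
    key <- paste(pmin(boxes$box_id[idx$i], boxes$box_id[idx$j]),
                 pmax(boxes$box_id[idx$i], boxes$box_id[idx$j]))
    keep <- !key %in% forbidden
    idx <- idx[keep, , drop = FALSE]; d <- d[keep]
  }
  out <- tibble(i = idx$i, j = idx$j, dist = d)
  out[order(out$dist, out$i, out$j), ]
}

#' Rough ear-root pairing by minimum center distance
#'
#' Greedy global-minimum matching: among all candidate left/right box pairs
#' whose center distance lies in `[d_min, d_max]`, repeatedly emit the pair
#' with the smallest distance and remove both boxes, until no candidate
#' remains. Ties are broken deterministically by box order. Leftover boxes
#' are reported as unpaired.
#'
#' @param boxes A box tibble for one frame (see [obb-tables]).
#' @param config A [pairing_config()].
#' @return An object of class `ear_pairing`: a list with `pairs` (tibble),
#'   `unpaired` (box tibble), `boxes` (the input), `config`, and repair
#'   bookkeeping fields.
#' @export
pair_rough <- function(boxes, config = pairing_config()) {
  .validate_boxes(boxes)
  cand <- .candidate_edges(boxes, config)
  gm <- .greedy_match(cand, nrow(boxes))
  pairs <- .empty_pairs()
  for (k in seq_along(gm$picks)) {
    ij <- gm$picks[[k]]
    i <- ij[1]; j <- ij[2]
    # orient by detector class when the two classes differ
    if (boxes$class[i] == "right" && boxes$class[j] == "left") {
      tmp <- i; i <- j; j <- tmp
    }
    d <- center_distance(obb_vertices(boxes, i), obb_vertices(boxes, j))
    pairs <- dplyr::bind_rows(pairs, tibble(
      pair_id = k, left_id = boxes$box_id[i], right_id = boxes$box_id[j],
      center_dist = d, stage = "rough", theta = NA_real_,
      theta_left = NA_real_, theta_right = NA_real_,
      o_x = NA_real_, o_y = NA_real_, consistent = NA))
  }
  structure(list(pairs = pairs,
                 unpaired = boxes[gm$free, , drop = FALSE],
                 boxes = boxes, config = config,
                 n_dissolved = 0L, n_repaired = 0L),
            class = "ear_pairing")
}

#' Left/right classification from two polar angles
#'
#' The decision rule of the precise pairing stage, applied to the polar
#' angles `theta1`, `theta2` (degrees, y-up sense) of the two box centers
#' about the head origin. The angular difference is taken modulo 360 so the
#' rule is invariant to the order of the two boxes: with
#' `theta = (theta1 - theta2) mod 360`, box 2 is the left ear when
#' `theta < 180` and box 1 is the left ear when `theta > 180`. `theta`
#' exactly 0 or 180 is geometrically ambiguous and yields `NA`.
#'
#' @param theta1,theta2 Angles in degrees.
#' @return List with `theta` in \[0, 360) and `left` (1, 2 or `NA`).
#' @examples
#' classify_from_angles(91, 27) # theta 64, the 27-degree box is the left ear
#' @export
classify_from_angles <- function(theta1, theta2) {
  theta <- (theta1 - theta2) %% 360
  left <- if (abs(theta) < 1e-9 || abs(theta - 180) < 1e-9 ||
              abs(theta - 360) < 1e-9) {
    NA_integer_
  } else if (theta < 180) 2L else 1L
  list(theta = theta, left = left)
}

#' Polar-coordinate classification of one ear-root pair
#'
#' Computes the full pairing geometry for two boxes: the base points (the
#' nearest pair of vertices between the boxes), each box's extreme vertices
#' relative to its base point, the outermost line through them, the head
#' origin `O` where the two lines intersect, the polar angles of the two box
#' centers about `O` (y-up sense), and the angular difference `theta`; then
#' applies [classify_from_angles()].
#'
#' @param v1,v2 4x2 vertex matrices of the two boxes.
#' @return List with elements `p1`, `p2` (base points), `p1_max`, `p2_max`,
#'   `line1`, `line2`, `origin` (or `NULL`), `c1`, `c2` (centers as
#'   radius/angle), `theta`, `left` (1, 2 or `NA`) and `degenerate`
#'   (`"none"`, `"parallel"` or `"ambiguous"`).
#' @export
polar_classify <- function(v1, v2) {
  v1 <- canonicalize_vertices(v1)
  v2 <- canonicalize_vertices(v2)
  np <- nearest_vertex_pair(v1, v2)
  # each box's outermost line: through the vertex adjacent to its base point
  # across the short side (nearest vertex, base excluded) and the vertex
  # diagonally opposite the base (farthest) - the outer long edge
  e1 <- extreme_vertices(v1, np$p1, exclude = np$i)
  e2 <- extreme_vertices(v2, np$p2, exclude = np$j)
  l1 <- line_through(e1$p_min, e1$p_max)
  l2 <- line_through(e2$p_min, e2$p_max)
  o <- line_intersection(l1, l2)
  out <- list(p1 = np$p1, p2 = np$p2, p1_max = e1$p_max, p2_max = e2$p_max,
              line1 = l1, line2 = l2, origin = o,
              c1 = NULL, c2 = NULL, theta = NA_real_, left = NA_integer_,
              degenerate = "parallel")
  if (is.null(o)) return(out)
  ctr1 <- obb_center(v1); ctr2 <- obb_center(v2)
  if (sqrt(sum((ctr1 - o)^2)) < 1e-9 || sqrt(sum((ctr2 - o)^2)) < 1e-9) {
    return(out)
  }
  out$c1 <- polar_angle(ctr1, o)
  out$c2 <- polar_angle(ctr2, o)
  cls <- classify_from_angles(out$c1["angle"], out$c2["angle"])
  out$theta <- unname(cls$theta)
  out$left <- cls$left
  out$degenerate <- if (is.na(cls$left)) "ambiguous" else "none"
  out
}

.box_row <- function(boxes, id) which(boxes$box_id == id)[1]

#' Precise ear-root pairing by polar-coordinate validation
#'
#' Each rough pair is polar-classified. Pairs whose polar left/right
#' assignment agrees with the detector labels are confirmed. Disagreeing
#' pairs — including rough pairs of two same-class boxes, which the detector
#' labels refute outright — are dissolved and their boxes pooled with the
#' rough-stage unpaired boxes. Boxes from a dissolved one-left-one-right
#' pair re-enter the pool under their polar-derived classes; boxes from
#' same-class mispairs and from the unpaired list keep their detector
#' classes. The pool is re-paired by minimum center distance within the
#' window, one pool-left with one pool-right, with the dissolved box
#' combinations excluded (a dissolved pairing is known bad; re-admitting it
#' would deterministically re-form it, since it won the distance competition
#' once already). Re-formed pairs are validated once more; surviving
#' conflicts are kept as stage `"fallback"` with `consistent = FALSE`. Every
#' input box ends up in exactly one final pair or in the unpaired list.
#'
#' @param pairing An `ear_pairing` from [pair_rough()].
#' @param config A [pairing_config()]; defaults to the one stored in
#'   `pairing`.
#' @return The updated `ear_pairing`.
#' @export
pair_precise <- function(pairing, config = pairing$config) {
  boxes <- pairing$boxes
  pairs <- pairing$pairs
  keep <- .empty_pairs()
  pool_ids <- pairing$unpaired$box_id
  pool_class <- stats::setNames(pairing$unpaired$class,
                                as.character(pool_ids))
  forbidden <- character(0)
  n_dissolved <- 0L

  classify_pair <- function(left_id, right_id) {
    polar_classify(obb_vertices(boxes, .box_row(boxes, left_id)),
                   obb_vertices(boxes, .box_row(boxes, right_id)))
  }
  as_row <- function(pair_id, left_id, right_id, stage, cls, consistent) {
    tibble(pair_id = pair_id, left_id = left_id, right_id = right_id,
           center_dist = center_distance(
             obb_vertices(boxes, .box_row(boxes, left_id)),
             obb_vertices(boxes, .box_row(boxes, right_id))),
           stage = stage, theta = cls$theta,
           theta_left = unname(if (is.null(cls$c1)) NA_real_
                               else cls$c1["angle"]),
           theta_right = unname(if (is.null(cls$c2)) NA_real_
                                else cls$c2["angle"]),
           o_x = if (is.null(cls$origin)) NA_real_ else cls$origin[1],
           o_y = if (is.null(cls$origin)) NA_real_ else cls$origin[2],
           consistent = consistent)
  }

  for (k in seq_len(nrow(pairs))) {
    lid <- pairs$left_id[k]; rid <- pairs$right_id[k]
    det_l <- boxes$class[.box_row(boxes, lid)]
    det_r <- boxes$class[.box_row(boxes, rid)]
    one_each <- det_l == "left" && det_r == "right"
    cls <- classify_pair(lid, rid)
    if (cls$degenerate == "parallel") {
      if (config$parallel_fallback == "keep_rough") {
        keep <- dplyr::bind_rows(keep, as_row(NA_integer_, lid, rid,
                                              "fallback", cls, NA))
      } else {
        pool_ids <- c(pool_ids, lid, rid)
        pool_class[as.character(c(lid, rid))] <- c(det_l, det_r)
      }
    } else if (cls$degenerate == "ambiguous") {
      keep <- dplyr::bind_rows(keep, as_row(NA_integer_, lid, rid,
                                            "fallback", cls, FALSE))
    } else if (one_each && cls$left == 1L) {
      # polar agrees with the detector: box 1 (the detector-left box) is left
      keep <- dplyr::bind_rows(keep, as_row(NA_integer_, lid, rid,
                                            "precise_confirmed", cls, TRUE))
    } else {
      # disagreement: either the polar assignment contradicts the detector
      # labels, or the rough pair holds two same-class boxes (which the
      # detector labels refute outright)
      n_dissolved <- n_dissolved + 1L
      pool_ids <- c(pool_ids, lid, rid)
      if (one_each) {
        # polar-derived classes: the polar-left box re-enters the pool as left
        pool_class[as.character(lid)] <- "right"
        pool_class[as.character(rid)] <- "left"
      } else {
        # same-class mispair: its phantom-origin polar classes carry no
        # information, keep the detector's
        pool_class[as.character(c(lid, rid))] <- c(det_l, det_r)
      }
      forbidden <- c(forbidden, paste(min(lid, rid), max(lid, rid)))
    }
  }

  n_repaired <- 0L
  if (length(pool_ids) >= 1) {
    pool <- boxes[vapply(pool_ids, function(id) .box_row(boxes, id),
                         integer(1)), , drop = FALSE]
    pool$class <- unname(pool_class[as.character(pool$box_id)])
    # re-pairing is always one pool-left with one pool-right
    recfg <- config
    recfg$class_constrained <- TRUE
    cand <- .candidate_edges(pool, recfg, forbidden = forbidden)
    gm <- .greedy_match(cand, nrow(pool))
    for (ij in gm$picks) {
      b1 <- pool[ij[1], ]; b2 <- pool[ij[2], ]
      det1 <- boxes$class[.box_row(boxes, b1$box_id)]
      det2 <- boxes$class[.box_row(boxes, b2$box_id)]
      if (det1 == "left" && det2 == "right") {
        lid <- b1$box_id; rid <- b2$box_id
      } else if (det1 == "right" && det2 == "left") {
        lid <- b2$box_id; rid <- b1$box_id
      } else {
        # detector classes do not form a left/right pair: orient by the pool
        # (polar-derived) classes and flag below
        lid <- if (b1$class == "left") b1$box_id else b2$box_id
        rid <- if (b1$class == "left") b2$box_id else b1$box_id
      }
      cls <- classify_pair(lid, rid)
      ok_det <- det1 != det2
      if (cls$degenerate == "none" && cls$left == 1L && ok_det) {
        n_repaired <- n_repaired + 1L
        keep <- dplyr::bind_rows(keep, as_row(NA_integer_, lid, rid,
                                              "precise_repaired", cls, TRUE))
      } else {
        keep <- dplyr::bind_rows(keep, as_row(NA_integer_, lid, rid,
                                              "fallback", cls, FALSE))
      }
    }
    unpaired <- pool[gm$free, , drop = FALSE]
    unpaired$class <- boxes$class[vapply(unpaired$box_id, function(id) {
      .box_row(boxes, id)
    }, integer(1))]  # restore detector classes in the report
  } else {
    unpaired <- pairing$unpaired[!pairing$unpaired$box_id %in%
                                   unlist(keep[, c("left_id", "right_id")]),
                                 , drop = FALSE]
  }

  if (nrow(keep) > 0) keep$pair_id <- seq_len(nrow(keep))
  structure(list(pairs = keep, unpaired = unpaired, boxes = boxes,
                 config = config, n_dissolved = n_dissolved,
                 n_repaired = n_repaired),
            class = "ear_pairing")
}

#' Two-stage ear-root pairing
#'
#' Runs [pair_rough()] followed by [pair_precise()].
#'
#' @inheritParams pair_rough
#' @return An `ear_pairing` (see [pair_precise()]).
#' @examples
#' sc <- generate_scene(scene_config(n_pigs = 1), seed = 1)
#' pair_ears(sc$boxes)
#' @export
pair_ears <- function(boxes, config = pairing_config()) {
  pair_precise(pair_rough(boxes, config), config)
}

#' @export
print.ear_pairing <- function(x, ...) {
  cat(sprintf("<ear_pairing: %d pairs (%s), %d unpaired, %d dissolved, %d repaired>\n",
              nrow(x$pairs),
              paste(sprintf("%s: %d", names(table(x$pairs$stage)),
                            table(x$pairs$stage)), collapse = ", "),
              nrow(x$unpaired), x$n_dissolved, x$n_repaired))
  invisible(x)
}

#' @export
tidy.ear_pairing <- function(x, ...) x$pairs

#' @export
glance.ear_pairing <- function(x, ...) {
  tibble(n_boxes = nrow(x$boxes), n_pairs = nrow(x$pairs),
         n_unpaired = nrow(x$unpaired),
         n_confirmed = sum(x$pairs$stage == "precise_confirmed"),
         n_repaired = sum(x$pairs$stage == "precise_repaired"),
         n_fallback = sum(x$pairs$stage == "fallback"),
         n_rough = sum(x$pairs$stage == "rough"),
         n_dissolved = x$n_dissolved)
}

#' Score predicted pairs against ground truth
#'
#' A predicted pair is correct when its two boxes are the two ear roots of
#' the same ground-truth pig and the left/right assignment matches the
#' anatomical labels.
#'
#' @param pairing An `ear_pairing`.
#' @param truth_pairs Tibble with columns `left_id`, `right_id` (one row per
#'   pig), e.g. the `pairs` element of a [generate_scene()] result.
#' @return One-row tibble: `n_pairs`, `n_correct`, `n_true`, `accuracy`
#'   (correct / true pig count).
#' @export
score_pairing <- function(pairing, truth_pairs) {
  p <- pairing$pairs
  correct <- vapply(seq_len(nrow(p)), function(k) {
    any(truth_pairs$left_id == p$left_id[k] &
          truth_pairs$right_id == p$right_id[k])
  }, logical(1))
  tibble(n_pairs = nrow(p), n_correct = sum(correct),
         n_true = nrow(truth_pairs),
         accuracy = if (nrow(truth_pairs) > 0) {
           sum(correct) / nrow(truth_pairs)
         } else NA_real_)
}
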