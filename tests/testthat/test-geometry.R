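test_that("canonicalization fixes the cycle, preserves geometry, rejects degenerates", {
  sq <- canonicalize_vertices(rbind(c(10, 0), c(0, 0), c(0, 10), c(10, 10)))
  expect_equal(sq[1, ], c(x = 0, y = 0))
  # positive shoelace orientation in raw (y-down) coordinates
  n <- nrow(sq); i2 <- c(2:n, 1)
  expect_gt(sum(sq[, 1] * sq[i2, 2] - sq[i2, 1] * sq[, 2]) / 2, 0)

  withr::with_seed(11, {
    for (rep in 1:50) {
      v <- rand_rect()
      perm <- v[sample(4), ]
      canon <- canonicalize_vertices(perm)
      expect_identical(canonicalize_vertices(canon), canon)  # idempotent
      expect_equal(polygon_area(canon), polygon_area(v), tolerance = 1e-9)
      expect_equal(sort(canon[, 1]), sort(v[, 1]))
    }
  })

  expect_error(canonicalize_vertices(rbind(c(0, 0), c(1, 1), c(2, 2),
                                           c(3, 3))), "degenerate")
  expect_error(canonicalize_vertices(rbind(c(0, 0), c(0, 0), c(1, 0),
                                           c(1, 1))), "degenerate")
})

test_that("box centers and center distances behave like the arithmetic mean", {
  sq <- canonicalize_vertices(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_equal(obb_center(sq), c(x = 5, y = 5))
  # rotated rectangle recovers its construction center
  r <- rotated_rect(100, 50, 40, 8, 30 * pi / 180)
  expect_equal(obb_center(r), c(x = 100, y = 50), tolerance = 1e-9)
  # 3-4-5 distance and symmetry
  a <- rotated_rect(0, 0, 4, 2, 0); b <- rotated_rect(3, 4, 4, 2, 1)
  expect_equal(center_distance(a, b), 5, tolerance = 1e-9)
  expect_equal(center_distance(b, a), center_distance(a, b))
  expect_equal(center_distance(a, a), 0)
})

test_that("nearest and extreme vertex selection match exhaustive scans", {
  withr::with_seed(21, {
    for (rep in 1:100) {
      a <- rand_rect(); b <- rand_rect(xlim = c(60, 140))
      np <- nearest_vertex_pair(a, b)
      bo <- brute_nearest(a, b)
      expect_equal(np$dist, bo$dist, tolerance = 1e-9)
      base <- c(runif(1, 0, 150), runif(1, 0, 150))
      ev <- extreme_vertices(a, base)
      bv <- brute_extreme(a, base)
      d <- sqrt((a[, 1] - base[1])^2 + (a[, 2] - base[2])^2)
      expect_equal(d[ev$i_min], min(d), tolerance = 1e-9)
      expect_equal(d[ev$i_max], max(d), tolerance = 1e-9)
      expect_equal(d[bv$i_min], d[ev$i_min], tolerance = 1e-9)
    }
  })
})

test_that("nearest-vertex ties break by canonical index and translate equivariantly", {
  a <- canonicalize_vertices(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  b <- canonicalize_vertices(rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1)))
  np <- nearest_vertex_pair(a, b)
  expect_equal(np$dist, 0)
  # lowest canonical index in a among the touching vertices, then in b
  expect_equal(np$i, min(which(a[, 1] == 1)))
  withr::with_seed(31, {
    a <- rand_rect(); b <- rand_rect(xlim = c(90, 140))
    sh <- c(7.25, -3.5)
    np0 <- nearest_vertex_pair(a, b)
    np1 <- nearest_vertex_pair(sweep(a, 2, -sh), sweep(b, 2, -sh))
    expect_equal(np1$p1, np0$p1 + c(x = sh[1], y = sh[2]), tolerance = 1e-9)
    expect_equal(np1$p2, np0$p2 + c(x = sh[1], y = sh[2]), tolerance = 1e-9)
  })
})

test_that("extreme vertices honor the base-exclusion used for outermost lines", {
  # elongated box: nearest-other vertex to a corner is across the short side
  v <- rotated_rect(50, 50, 40, 8, 0.3)
  np_base <- 1L
  ev <- extreme_vertices(v, v[np_base, ], exclude = np_base)
  expect_false(ev$i_min == np_base)
  d_short <- sqrt(sum((v[ev$i_min, ] - v[np_base, ])^2))
  expect_equal(d_short, 8, tolerance = 1e-9)   # across the width
  d_long <- sqrt(sum((v[ev$i_max, ] - v[np_base, ])^2))
  expect_equal(d_long, sqrt(40^2 + 8^2), tolerance = 1e-9)  # diagonal
})

test_that("implicit lines handle vertical cases and satisfy incidence", {
  l <- line_through(c(0, 0), c(1, 2))
  expect_equal(unname(l[1] * 1 + l[2] * 2 + l[3]), 0, tolerance = 1e-12)
  lv <- line_through(c(3, 0), c(3, 5))
  expect_equal(unname(lv[1] * 3 + lv[2] * 4 + lv[3]), 0, tolerance = 1e-12)
  expect_error(line_through(c(1, 1), c(1, 1)), "identical")
  withr::with_seed(41, {
    for (rep in 1:50) {
      p <- runif(2, -50, 50); q <- runif(2, -50, 50)
      if (sqrt(sum((p - q)^2)) < 1e-6) next
      l <- line_through(p, q)
      expect_equal(unname(l[1] * p[1] + l[2] * p[2] + l[3]), 0,
                   tolerance = 1e-9)
      expect_equal(unname(l[1] * q[1] + l[2] * q[2] + l[3]), 0,
                   tolerance = 1e-9)
      expect_equal(line_through(q, p), l, tolerance = 1e-12)
    }
  })
})

test_that("line intersections resolve, and parallels signal no origin", {
  o <- line_intersection(line_through(c(0, 0), c(1, 1)),
                         line_through(c(0, 2), c(2, 0)))
  expect_equal(o, c(x = 1, y = 1), tolerance = 1e-12)
  o2 <- line_intersection(line_through(c(3, 0), c(3, 1)),
                          line_through(c(0, 4), c(1, 4)))
  expect_equal(o2, c(x = 3, y = 4), tolerance = 1e-12)
  expect_null(line_intersection(line_through(c(0, 0), c(1, 1)),
                                line_through(c(0, 1), c(1, 2))))
})

test_that("polar angles are y-up, with antipode and rotation properties", {
  expect_equal(polar_angle(c(5, 2), c(5, 7))[["angle"]], 90)  # above -> 90
  expect_equal(polar_angle(c(9, 7), c(5, 7))[["angle"]], 0)   # right -> 0
  expect_equal(polar_angle(c(5, 12), c(5, 7))[["angle"]], 270)
  expect_error(polar_angle(c(1, 1), c(1, 1)), "origin")
  withr::with_seed(51, {
    for (rep in 1:50) {
      o <- runif(2, 0, 100); p <- runif(2, 0, 100)
      if (sqrt(sum((p - o)^2)) < 1e-3) next
      a <- polar_angle(p, o)[["angle"]]
      anti <- polar_angle(o - (p - o), o)[["angle"]]
      expect_equal(anti, (a + 180) %% 360, tolerance = 1e-9)
      # rotating p about o by alpha (y-up sense) adds alpha
      alpha <- runif(1, 0, 360)
      th <- alpha * pi / 180
      d <- p - o
      # y-up rotation written in image coordinates
      pr <- o + c(d[1] * cos(th) + d[2] * sin(th),
                  -d[1] * sin(th) + d[2] * cos(th))
      expect_equal(polar_angle(pr, o)[["angle"]], (a + alpha) %% 360,
                   tolerance = 1e-6)
    }
  })
})

test_that("rotated IoU matches closed cases and stays within [0, 1]", {
  a <- rotated_rect(5, 5, 10, 10, 0)
  expect_equal(rotated_iou(a, a), 1)
  b <- rotated_rect(10, 5, 10, 10, 0)  # offset by 5: 50 / 150
  expect_equal(rotated_iou(a, b), 1 / 3, tolerance = 1e-9)
  withr::with_seed(61, {
    for (rep in 1:200) {
      x <- rand_rect(); y <- rand_rect()
      i1 <- rotated_iou(x, y)
      expect_gte(i1, 0); expect_lte(i1, 1)
      expect_equal(rotated_iou(y, x), i1, tolerance = 1e-12)
    }
  })
})

test_that("rasterization counts pixels by centers and clips to the frame", {
  # box spanning columns 0-1, rows 0-2 exactly (0-based): 6 pixel centers
  v <- canonicalize_vertices(rbind(c(0, 0), c(2, 0), c(2, 3), c(0, 3)))
  px <- rasterize_obb(v, c(10, 10))
  expect_equal(nrow(px), 6)
  expect_setequal(px[, "row"], c(1, 2, 3))
  expect_setequal(px[, "col"], c(1, 2))
  # fully outside -> empty, not an error
  out <- rasterize_obb(rotated_rect(500, 500, 10, 10, 0.4), c(288, 384))
  expect_equal(nrow(out), 0)
  # pixel count tracks the shoelace area to within the perimeter
  withr::with_seed(71, {
    for (rep in 1:30) {
      v <- rand_rect(xlim = c(30, 90), ylim = c(30, 90))
      n <- nrow(rasterize_obb(v, c(150, 150)))
      area <- polygon_area(v)
      per <- sum(sqrt(rowSums((v - v[c(2:4, 1), ])^2)))
      expect_lt(abs(n - area), per + 4)
    }
  })
})
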