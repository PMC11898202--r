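test_that("rough pairing forms in-window pairs and leaves the rest unpaired", {
  two <- obb_table(list(rotated_rect(100, 100, 40, 8, 0.4),
                        rotated_rect(200, 100, 40, 8, 2.8)),
                   class = c("left", "right"))
  pr <- pair_rough(two)
  expect_equal(nrow(pr$pairs), 1)
  expect_equal(pr$pairs$center_dist, 100, tolerance = 1e-9)
  expect_equal(nrow(pr$unpaired), 0)

  far <- obb_table(list(rotated_rect(50, 100, 40, 8, 0.4),
                        rotated_rect(250, 100, 40, 8, 2.8)),
                   class = c("left", "right"))
  pf <- pair_rough(far)  # 200 px apart: unrelated boxes
  expect_equal(nrow(pf$pairs), 0)
  expect_equal(nrow(pf$unpaired), 2)

  expect_equal(nrow(pair_rough(two[0, ])$pairs), 0)
})

test_that("rough pairing equals a step-by-step greedy simulation", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      boxes <- obb_table(
        lapply(seq_len(n), function(i) {
          rand_rect(xlim = c(30, 350), ylim = c(30, 250),
                    len = c(30, 45), wid = c(6, 10))
        }),
        class = sample(c("left", "right"), n, replace = TRUE))
      for (constrained in c(TRUE, FALSE)) {
        cfg <- pairing_config(class_constrained = constrained)
        got <- pair_rough(boxes, cfg)
        want <- greedy_oracle(boxes, cfg$d_min, cfg$d_max, constrained)
        got_sets <- lapply(seq_len(nrow(got$pairs)), function(k) {
          sort(c(got$pairs$left_id[k], got$pairs$right_id[k]))
        })
        expect_setequal(got_sets, want)
        # conservation
        expect_equal(2 * nrow(got$pairs) + nrow(got$unpaired), n)
      }
    }
  })
})

test_that("rough pairing is invariant to input order and rigid translation", {
  withr::with_seed(111, {
    sc <- generate_scene(scene_config(n_pigs = 2, noise_sd = 0), seed = 7)
    boxes <- sc$boxes
    base <- pair_rough(boxes)
    perm <- boxes[sample(nrow(boxes)), ]
    permuted <- pair_rough(perm)
    key <- function(p) sort(paste(p$pairs$left_id, p$pairs$right_id))
    expect_equal(key(permuted), key(base))
    shifted <- boxes
    for (cc in c("x1", "x2", "x3", "x4")) shifted[[cc]] <- shifted[[cc]] + 3.5
    for (cc in c("y1", "y2", "y3", "y4")) shifted[[cc]] <- shifted[[cc]] - 2.25
    expect_equal(key(pair_rough(shifted)), key(base))
  })
})

test_that("the angular decision rule reproduces the worked pair and is order-invariant", {
  res <- classify_from_angles(91, 27)
  expect_equal(res$theta, 64)
  expect_equal(res$left, 2L)  # the 27-degree box is the left ear

  swapped <- classify_from_angles(27, 91)
  expect_equal(swapped$theta, 296)
  expect_equal(swapped$left, 1L)  # same physical box

  withr::with_seed(121, {
    for (rep in 1:100) {
      t1 <- runif(1, 0, 360); t2 <- runif(1, 0, 360)
      if (min(abs(((t1 - t2) %% 360) - c(0, 180, 360))) < 1e-6) next
      a <- classify_from_angles(t1, t2)
      b <- classify_from_angles(t2, t1)
      expect_equal(b$theta, (360 - a$theta) %% 360, tolerance = 1e-9)
      expect_equal(b$left, 3L - a$left)  # identical physical assignment
    }
  })

  expect_true(is.na(classify_from_angles(90, 270)$left))
  expect_true(is.na(classify_from_angles(45, 45)$left))
})

test_that("polar classification recovers anatomy and respects symmetries", {
  boxes <- simple_pig_boxes()
  cl <- polar_classify(obb_vertices(boxes, 1), obb_vertices(boxes, 2))
  expect_equal(cl$degenerate, "none")
  expect_equal(cl$left, 1L)  # anatomical left recognized as left
  # swapping the two boxes flips theta but selects the same physical box
  cl2 <- polar_classify(obb_vertices(boxes, 2), obb_vertices(boxes, 1))
  expect_equal(cl2$left, 2L)
  expect_equal(cl2$theta, (360 - cl$theta) %% 360, tolerance = 1e-6)
  # mirroring the scene about a vertical axis flips the assignment
  mirror <- function(v) canonicalize_vertices(cbind(384 - v[, 1], v[, 2]))
  clm <- polar_classify(mirror(obb_vertices(boxes, 1)),
                        mirror(obb_vertices(boxes, 2)))
  expect_equal(clm$left, 2L)
  # anatomy holds across random headings (generator calibration)
  cfg <- scene_config(noise_sd = 0)
  for (s in 1:150) {
    sc <- generate_scene(cfg, seed = s)
    cl <- polar_classify(obb_vertices(sc$boxes, 1), obb_vertices(sc$boxes, 2))
    expect_identical(cl$left, 1L)
  }
})

test_that("parallel outermost lines yield an explicit no-origin signal", {
  a <- rotated_rect(50, 50, 40, 8, 0.2)
  # translate along the base-excluded outer-edge direction: the two outer
  # edges become collinear, hence no usable intersection
  shift <- 2 * (a[2, ] - a[1, ])
  b <- canonicalize_vertices(sweep(a, 2, -shift))
  np <- nearest_vertex_pair(a, b)
  l1 <- line_through(extreme_vertices(a, np$p1, exclude = np$i)$p_min,
                     extreme_vertices(a, np$p1, exclude = np$i)$p_max)
  l2 <- line_through(extreme_vertices(b, np$p2, exclude = np$j)$p_min,
                     extreme_vertices(b, np$p2, exclude = np$j)$p_max)
  if (is.null(line_intersection(l1, l2))) {
    cl <- polar_classify(a, b)
    expect_equal(cl$degenerate, "parallel")
    expect_true(is.na(cl$left))
  }
  # identical boxes are always degenerate
  expect_equal(polar_classify(a, a)$degenerate, "parallel")
})

test_that("a single correct rough pair is confirmed unchanged", {
  sc <- generate_scene(scene_config(noise_sd = 0), seed = 5)
  pp <- pair_ears(sc$boxes)
  expect_equal(nrow(pp$pairs), 1)
  expect_equal(pp$pairs$stage, "precise_confirmed")
  expect_true(pp$pairs$consistent)
  expect_equal(pp$pairs$left_id, sc$pairs$left_id)
  expect_equal(pp$pairs$right_id, sc$pairs$right_id)
})

test_that("touching-heads mispairs are dissolved and repaired to same-pig pairs", {
  cfg <- scene_config(adversarial = "touching_heads", noise_sd = 0)
  for (s in 1:25) {
    sc <- generate_scene(cfg, seed = s)
    rough <- pair_rough(sc$boxes)
    expect_lt(score_pairing(rough, sc$pairs)$accuracy, 1)
    precise <- pair_precise(rough)
    expect_gte(precise$n_dissolved, 1)
    expect_equal(score_pairing(precise, sc$pairs)$accuracy, 1)
    expect_true(all(precise$pairs$stage %in%
                      c("precise_confirmed", "precise_repaired")))
    # conservation: every box in exactly one pair or unpaired
    ids <- c(precise$pairs$left_id, precise$pairs$right_id,
             precise$unpaired$box_id)
    expect_setequal(ids, sc$boxes$box_id)
    expect_equal(length(ids), nrow(sc$boxes))
  }
})

test_that("precise pairing permutation invariance holds on adversarial scenes", {
  cfg <- scene_config(adversarial = "touching_heads", noise_sd = 0)
  withr::with_seed(131, {
    for (s in 1:5) {
      sc <- generate_scene(cfg, seed = s)
      key <- function(p) sort(paste(p$pairs$left_id, p$pairs$right_id))
      base <- pair_ears(sc$boxes)
      perm <- pair_ears(sc$boxes[sample(nrow(sc$boxes)), ])
      expect_equal(key(perm), key(base))
    }
  })
})

test_that("pairing ignores detection confidence", {
  sc <- generate_scene(scene_config(noise_sd = 0), seed = 17)
  with_conf <- sc$boxes
  with_conf$conf <- c(0.51, 0.99)
  a <- pair_ears(sc$boxes); b <- pair_ears(with_conf)
  expect_equal(a$pairs$left_id, b$pairs$left_id)
  expect_equal(a$pairs$theta, b$pairs$theta)
})

test_that("pairing reports expose tidy and glance summaries", {
  sc <- generate_scene(scene_config(noise_sd = 0), seed = 3)
  pp <- pair_ears(sc$boxes)
  expect_s3_class(tidy(pp), "tbl_df")
  g <- glance(pp)
  expect_equal(g$n_boxes, 2)
  expect_equal(g$n_pairs, 1)
  expect_equal(g$n_confirmed, 1)
})
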