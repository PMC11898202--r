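test_that("detection matching handles perfect, empty and toy cases", {
  truth <- obb_table(list(rotated_rect(50, 50, 30, 10, 0.3),
                          rotated_rect(150, 60, 30, 10, 1.2),
                          rotated_rect(250, 70, 30, 10, 2.0)),
                     class = c("left", "right", "left"))
  perfect <- truth
  perfect$conf <- c(0.9, 0.8, 0.95)
  md <- match_detections(perfect, truth)
  expect_equal(sum(md$counts$fp), 0)
  expect_equal(sum(md$counts$fn), 0)
  expect_equal(sum(md$counts$tp), 3)

  none <- truth[0, ]
  md0 <- match_detections(none, truth)
  expect_equal(sum(md0$counts$tp), 0)
  expect_equal(sum(md0$counts$fn), 3)

  # double detection of the same truth: higher-confidence one wins, the
  # duplicate is a false positive (hand-enumerated assignment)
  dup <- perfect[c(1, 1, 2, 3), ]
  dup$conf <- c(0.9, 0.6, 0.8, 0.95)
  dup$box_id <- 1:4
  mdd <- match_detections(dup, truth)
  expect_equal(sum(mdd$counts$tp), 3)
  expect_equal(sum(mdd$counts$fp), 1)
  left <- mdd$matches[mdd$matches$class == "left", ]
  expect_equal(left$tp[left$conf == 0.6], FALSE)
})

test_that("precision and recall follow the confusion-count definitions", {
  pr <- precision_recall(3, 1, 0)
  expect_equal(pr$precision, 0.75)
  pr2 <- precision_recall(3, 0, 2)
  expect_equal(pr2$recall, 0.6)
  deg <- precision_recall(0, 0, 5)
  expect_equal(deg$precision, 1)
  expect_true(deg$degenerate_precision)
  expect_true(is.na(precision_recall(0, 0, 0)$recall))
})

test_that("average precision matches hand-computed envelopes and a brute oracle", {
  expect_equal(average_precision(TRUE, 1), 1)
  # ranked [TP, FP, TP] with 2 truths:
  # recall steps 0.5 (p_interp 1) and 1.0 (p_interp 2/3)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_warning(average_precision(c(TRUE, FALSE), 0), "no positives")
  expect_equal(mean_ap(c(0.4, 0.8)), 0.6)
  withr::with_seed(161, {
    for (rep in 1:50) {
      n <- sample(1:10, 1)
      flags <- sample(c(TRUE, FALSE), n, replace = TRUE)
      npos <- sum(flags) + sample(0:3, 1)
      if (npos == 0) next
      expect_equal(average_precision(flags, npos), brute_ap(flags, npos),
                   tolerance = 1e-12)
    }
  })
})

test_that("a perfect detector scores P = R = mAP = 1", {
  sc <- generate_scene(scene_config(n_pigs = 2, noise_sd = 0), seed = 37)
  pred <- sc$boxes
  pred$conf <- 0.9
  ev <- evaluate_detections(pred, sc$boxes)
  expect_equal(ev$map, 1)
  expect_true(all(ev$per_class$precision == 1))
  expect_true(all(ev$per_class$recall == 1))
  expect_equal(glance(ev)$fp, 0)
})

test_that("pairing accuracy reproduces published-style counts at print precision", {
  expect_equal(round(100 * pairing_accuracy(313, 369)$accuracy, 1), 84.8)
  expect_equal(round(100 * pairing_accuracy(56, 369)$accuracy, 1), 15.2)
  expect_equal(round(100 * pairing_accuracy(364, 371)$accuracy, 1), 98.1)
  expect_equal(round(100 * pairing_accuracy(51, 56)$accuracy, 1), 91.1)
  expect_equal(round(100 * pairing_accuracy(80, 138)$accuracy, 0), 58)
  expect_equal(round(100 * pairing_accuracy(131, 138)$accuracy, 1), 94.9)
  expect_equal(pairing_accuracy(233, 233)$accuracy, 1)
  expect_equal(pairing_accuracy(0, 5)$accuracy, 0)
  expect_error(pairing_accuracy(1, 0), "positive")
  expect_error(pairing_accuracy(6, 5), "pc <= pt")
})

test_that("pearson correlation matches direct arithmetic and its symmetries", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2, 4, 5, 4)
  # direct product-moment arithmetic, frozen
  expect_equal(pearson_r(x, y), 3.5 / sqrt(5 * 4.75), tolerance = 1e-12)
  # invariance under positive affine transforms; sign flip under negation
  withr::with_seed(171, {
    a <- rnorm(20); b <- rnorm(20)
    r <- pearson_r(a, b)
    expect_equal(pearson_r(2.5 * a + 3, b), r, tolerance = 1e-12)
    expect_equal(pearson_r(a, 0.1 * b - 7), r, tolerance = 1e-12)
    expect_equal(pearson_r(-a, b), -r, tolerance = 1e-12)
  })
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3 samples")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("bias analysis computes the t-based interval and verdict", {
  pred <- c(38.1, 38.4, 38.2, 38.6, 38.0)
  ba <- bias_analysis(pred, pred)
  expect_equal(ba$mean_bias, 0)
  expect_true(ba$acceptable)

  # near-constant +1 degC offset: interval excludes zero
  withr::with_seed(181, {
    ref <- rnorm(30, 38, 0.2)
    ba2 <- bias_analysis(ref + 1 + rnorm(30, 0, 1e-3), ref)
  })
  expect_false(ba2$acceptable)
  expect_lt(ba2$p_value, 1e-6)
  # exactly constant offset is handled without failure
  ba3 <- bias_analysis(pred + 1, pred)
  expect_false(ba3$acceptable)

  # cross-check the hand formulas against the standard one-sample t-test
  withr::with_seed(191, {
    p <- rnorm(40, 0.05, 0.15); r <- rnorm(40, 0, 0.1)
  })
  ba4 <- bias_analysis(p, r)
  tt <- t.test(p - r)
  expect_equal(ba4$p_value, tt$p.value, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(c(ba4$conf_low, ba4$conf_high), as.numeric(tt$conf.int),
               tolerance = 1e-12)
  expect_error(bias_analysis(1:4, 1:5), "mismatch")
})

test_that("report objects expose tidy and glance methods", {
  ba <- bias_analysis(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.3))
  expect_equal(nrow(tidy(ba)), 4)
  expect_named(glance(ba), c("n", "mean_bias", "sd_bias", "conf_low",
                             "conf_high", "p_value", "acceptable"))
})
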