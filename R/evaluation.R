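#' Match detections to ground truth for oriented boxes
#'
#' Per frame and per class, predictions are ranked by descending confidence
#' (ties and missing confidences keep input order) and each is greedily
#' matched to the unmatched ground-truth box of the same class with the
#' highest rotated IoU at or above the threshold. Matched predictions are
#' true positives, the rest false positives; unmatched truths are false
#' negatives. True negatives are not applicable to detection.
#'
#' @param pred Box tibble of predictions (with `conf`).
#' @param truth Box tibble of ground truth.
#' @param iou_threshold Rotated-IoU threshold (default 0.5).
#' @return List with `matches` (per-prediction tibble: `frame`, `class`,
#'   `box_id`, `conf`, `iou`, `tp`) and `counts` (per-class `tp`, `fp`,
#'   `fn`, `n_truth`).
#' @export
match_detections <- function(pred, truth, iou_threshold = 0.5) {
  .validate_boxes(pred); .validate_boxes(truth)
  classes <- sort(unique(c(pred$class, truth$class)))
  matches <- list(); counts <- list()
  for (cl in classes) {
    p <- pred[pred$class == cl, , drop = FALSE]
    p <- p[order(-ifelse(is.na(p$conf), 1, p$conf)), , drop = FALSE]
    t_all <- truth[truth$class == cl, , drop = FALSE]
    used <- rep(FALSE, nrow(t_all))
    rows <- tibble(frame = character(0), class = character(0),
                   box_id = integer(0), conf = numeric(0),
                   iou = numeric(0), tp = logical(0))
    if (nrow(p) > 0) rows <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
      cand <- which(!used & t_all$frame == p$frame[i])
      best <- NA_integer_; best_iou <- 0
      for (j in cand) {
        iou <- rotated_iou(obb_vertices(p, i), obb_vertices(t_all, j))
        if (iou > best_iou) { best_iou <- iou; best <- j }
      }
      tp <- !is.na(best) && best_iou >= iou_threshold
      if (tp) used[best] <<- TRUE
      tibble(frame = p$frame[i], class = cl, box_id = p$box_id[i],
             conf = p$conf[i], iou = best_iou, tp = tp)
    })
    matches[[cl]] <- rows
    counts[[cl]] <- tibble(class = cl,
                           tp = sum(rows$tp), fp = sum(!rows$tp),
                           fn = sum(!used), n_truth = nrow(t_all))
  }
  list(matches = dplyr::bind_rows(matches), counts = dplyr::bind_rows(counts))
}

#' Precision and recall from confusion counts
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`. With no predictions at all
#' (`TP + FP = 0`) precision is reported as 1 with a degeneracy flag (no
#' false claims were made); with no positives (`TP + FN = 0`) recall is
#' undefined and reported `NA`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return One-row tibble: `precision`, `recall`, `degenerate_precision`,
#'   `degenerate_recall`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tibble(
    precision = if (tp + fp > 0) tp / (tp + fp) else 1,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    degenerate_precision = tp + fp == 0,
    degenerate_recall = tp + fn == 0
  )
}

#' Average precision over a ranked detection list
#'
#' All-point interpolated area under the precision-recall envelope:
#' `AP = sum over recall steps of (R_i - R_{i-1}) * max_{j >= i} P_j`.
#'
#' @param tp_ranked Logical vector: TP flag of each prediction in descending
#'   confidence order.
#' @param n_positive Number of ground-truth positives for the class.
#' @return AP in \[0, 1\]; `NA` (with a warning) if `n_positive` is 0.
#' @export
average_precision <- function(tp_ranked, n_positive) {
  if (n_positive <= 0) {
    warning("AP undefined for a class with no positives", call. = FALSE)
    return(NA_real_)
  }
  if (length(tp_ranked) == 0) return(0)
  cum_tp <- cumsum(tp_ranked)
  prec <- cum_tp / seq_along(tp_ranked)
  rec <- cum_tp / n_positive
  prec_env <- rev(cummax(rev(prec)))
  prev_rec <- c(0, head(rec, -1))
  sum((rec - prev_rec) * prec_env)
}

#' Mean average precision
#'
#' Unweighted mean of the per-class APs; classes with undefined AP (no
#' positives) are excluded.
#'
#' @param ap Numeric vector of per-class APs.
#' @return mAP.
#' @export
mean_ap <- function(ap) mean(ap, na.rm = TRUE)

#' Full detection evaluation for oriented boxes
#'
#' Runs [match_detections()] and assembles per-class precision, recall and
#' AP and their mean into a report object.
#'
#' @inheritParams match_detections
#' @return Object of class `detection_eval` with `per_class` (tibble),
#'   `map`, `iou_threshold`, `n_classes`. `tidy()` returns the per-class
#'   table; `glance()` a one-row summary.
#' @export
evaluate_detections <- function(pred, truth, iou_threshold = 0.5) {
  md <- match_detections(pred, truth, iou_threshold)
  per_class <- purrr::map_dfr(seq_len(nrow(md$counts)), function(k) {
    cl <- md$counts$class[k]
    m <- md$matches[md$matches$class == cl, , drop = FALSE]
    pr <- precision_recall(md$counts$tp[k], md$counts$fp[k], md$counts$fn[k])
    ap <- if (md$counts$n_truth[k] > 0) {
      average_precision(m$tp, md$counts$n_truth[k])
    } else NA_real_
    dplyr::bind_cols(md$counts[k, ], pr, tibble(ap = ap))
  })
  structure(list(per_class = per_class, map = mean_ap(per_class$ap),
                 iou_threshold = iou_threshold,
                 n_classes = nrow(per_class), matches = md$matches),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval: mAP %.3f at IoU %.2f over %d classes>\n",
              x$map, x$iou_threshold, x$n_classes))
  print(x$per_class)
  invisible(x)
}

#' @export
tidy.detection_eval <- function(x, ...) x$per_class

#' @export
glance.detection_eval <- function(x, ...) {
  tibble(map = x$map, iou_threshold = x$iou_threshold,
         n_classes = x$n_classes,
         tp = sum(x$per_class$tp), fp = sum(x$per_class$fp),
         fn = sum(x$per_class$fn))
}

#' Pairing accuracy
#'
#' `A = Pc / Pt`: the fraction of correctly paired left/right ear roots out
#' of the pairs evaluated. The caller chooses the denominator (pairs
#' evaluated vs. total pairs including exclusions); both conventions appear
#' in published pairing tables and each is reported with its own denominator.
#'
#' @param pc Correctly paired count, `0 <= pc <= pt`.
#' @param pt Total pair count, `> 0`.
#' @return One-row tibble: `n_correct`, `n_total`, `accuracy`.
#' @examples
#' pairing_accuracy(313, 369) # 84.8%
#' @export
pairing_accuracy <- function(pc, pt) {
  if (pt <= 0) stop("total pair count must be positive", call. = FALSE)
  if (pc < 0 || pc > pt) stop("need 0 <= pc <= pt", call. = FALSE)
  tibble(n_correct = pc, n_total = pt, accuracy = pc / pt)
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between predicted and reference values.
#' Requires at least 3 samples and nonzero variance in both arguments.
#'
#' @param x,y Numeric vectors of equal length.
#' @return `r` in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Measurement-system bias (agreement) analysis
#'
#' Per-sample bias is predicted minus reference. The mean bias, its sample
#' standard deviation (n-1 denominator), the two-sided
#' `100 * (1 - alpha)` percent confidence interval
#' `mean ± t(1 - alpha/2, n-1) * sd / sqrt(n)` and the one-sample t-test
#' p-value for zero mean bias are reported. The bias is acceptable when 0
#' lies inside the confidence interval.
#'
#' @param predicted,reference Paired numeric vectors, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `bias_analysis` with fields `n`, `mean_bias`,
#'   `sd_bias`, `conf_low`, `conf_high`, `p_value`, `alpha`, `acceptable`,
#'   `biases`. `tidy()` returns per-sample biases, `glance()` the summary.
#' @export
bias_analysis <- function(predicted, reference, alpha = 0.05) {
  if (length(predicted) != length(reference)) {
    stop("length mismatch between predicted and reference", call. = FALSE)
  }
  n <- length(predicted)
  if (n < 3) stop("need at least 3 paired samples", call. = FALSE)
  biases <- predicted - reference
  m <- mean(biases)
  s <- stats::sd(biases)
  if (s > 0) {
    se <- s / sqrt(n)
    tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
    ci <- c(m - tcrit * se, m + tcrit * se)
    p <- 2 * stats::pt(-abs(m / se), df = n - 1)
  } else {
    ci <- c(m, m)
    p <- if (m == 0) 1 else 0
  }
  structure(list(n = n, mean_bias = m, sd_bias = s,
                 conf_low = ci[1], conf_high = ci[2], p_value = p,
                 alpha = alpha,
                 acceptable = ci[1] <= 0 && 0 <= ci[2],
                 biases = biases),
            class = "bias_analysis")
}

#' @export
print.bias_analysis <- function(x, ...) {
  cat(sprintf(paste0("<bias_analysis: n = %d, mean bias %.4f (sd %.4f), ",
                     "%d%% CI [%.4f, %.4f], p = %.3f -> %s>\n"),
              x$n, x$mean_bias, x$sd_bias, round(100 * (1 - x$alpha)),
              x$conf_low, x$conf_high, x$p_value,
              if (x$acceptable) "acceptable" else "not acceptable"))
  invisible(x)
}

#' @export
tidy.bias_analysis <- function(x, ...) {
  tibble(sample = seq_len(x$n), bias = x$biases)
}

#' @export
glance.bias_analysis <- function(x, ...) {
  tibble(n = x$n, mean_bias = x$mean_bias, sd_bias = x$sd_bias,
         conf_low = x$conf_low, conf_high = x$conf_high,
         p_value = x$p_value, acceptable = x$acceptable)
}
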