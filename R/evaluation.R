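# Evaluation metrics: counting accuracy from absolute error, per-frame
# TP/FP/FN detection matching at a fixed IoU threshold, and single-class
# average precision over a confidence sweep.

#' Counting accuracy
#'
#' `(1 - |num_gt - num_m| / num_gt) * 100`. Uses the absolute error, so
#' over- and under-counts of equal size score the same; the value can go
#' negative when the absolute error exceeds the ground truth.
#'
#' @param num_gt Ground-truth count (>= 1).
#' @param num_m Measured count (>= 0).
#' @return Accuracy in percent.
#' @examples
#' counting_accuracy(100, 98)  # 98
#' counting_accuracy(100, 102) # 98
#' @export
counting_accuracy <- function(num_gt, num_m) {
  if (num_gt < 1) stop("counting accuracy undefined for num_gt < 1",
                       call. = FALSE)
  (1 - abs(num_gt - num_m) / num_gt) * 100
}

#' Summarize counting accuracy across rows
#'
#' Field counts are reported per crop row; this aggregates a vector of
#' per-row accuracies into mean and standard deviation.
#'
#' @param accuracies Numeric vector of per-row accuracies (percent).
#' @return List with `mean`, `sd`, `n`.
#' @export
aggregate_accuracy <- function(accuracies) {
  stopifnot(length(accuracies) >= 1)
  list(mean = mean(accuracies),
       sd = if (length(accuracies) > 1) stats::sd(accuracies) else 0,
       n = length(accuracies))
}

#' Match predicted to ground-truth boxes in one frame
#'
#' Pascal-VOC-style greedy matching: predictions are visited in
#' descending confidence order (ties broken by input order); each takes
#' the free ground-truth box of highest IoU if that IoU reaches the
#' threshold (true positive), otherwise it is a false positive. Each
#' ground-truth box is used at most once, so a split detection yields one
#' TP plus extra FPs. Unmatched ground truth is a false negative.
#'
#' @param gt `n x 4` box matrix of ground truth.
#' @param pred `m x 4` box matrix of predictions.
#' @param conf Length-m confidences (default all 1).
#' @param iou_threshold IoU required for a TP, in `(0, 1]`. Default 0.5.
#' @return List with `tp`, `fp`, `fn`, `pred_is_tp` (logical in input
#'   order), and `matches` (2-column matrix `pred`, `gt`).
#' @export
match_detections <- function(gt, pred, conf = NULL, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  gt <- as_box_matrix(gt); pred <- as_box_matrix(pred)
  m <- nrow(pred); n <- nrow(gt)
  if (is.null(conf)) conf <- rep(1, m)
  stopifnot(length(conf) == m)
  ord <- order(-conf, seq_len(m))
  gt_free <- rep(TRUE, n)
  pred_is_tp <- logical(m)
  matches <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("pred", "gt")))
  if (m > 0L && n > 0L) {
    iomat <- iou_matrix(pred, gt)
    for (j in ord) {
      cand <- which(gt_free & iomat[j, ] >= iou_threshold)
      if (length(cand)) {
        g <- cand[which.max(iomat[j, cand])]
        gt_free[g] <- FALSE
        pred_is_tp[j] <- TRUE
        matches <- rbind(matches, cbind(pred = j, gt = g))
      }
    }
  }
  list(tp = sum(pred_is_tp), fp = m - sum(pred_is_tp), fn = sum(gt_free),
       pred_is_tp = pred_is_tp, matches = matches)
}

#' Average precision at a fixed IoU threshold
#'
#' Single-class AP: predictions from all frames are pooled, sorted by
#' descending confidence, matched greedily per frame, and the area under
#' the precision-recall curve is taken with all-point (continuous)
#' interpolation -- precision at each recall level is the maximum
#' precision at that recall or beyond.
#'
#' @param gt,pred Detection data frames with columns `frame`, `x1`, `y1`,
#'   `x2`, `y2`; `pred` additionally `conf`.
#' @param iou_threshold IoU defining a true positive. Default 0.5.
#' @return AP in percent, in `[0, 100]`.
#' @export
average_precision <- function(gt, pred, iou_threshold = 0.5) {
  n_gt <- nrow(gt)
  if (n_gt == 0L)
    stop("average precision undefined without ground-truth boxes",
         call. = FALSE)
  if (nrow(pred) == 0L) return(0)
  # global confidence order; matching is per frame with single-use gt
  ord <- order(-pred$conf, seq_len(nrow(pred)))
  gt_free <- split(seq_len(n_gt), gt$frame)
  gt_boxes <- as.matrix(gt[, c("x1", "y1", "x2", "y2")])
  is_tp <- logical(nrow(pred))
  taken <- logical(n_gt)
  for (j in ord) {
    fr <- as.character(pred$frame[j])
    cand <- gt_free[[fr]]
    cand <- cand[!taken[cand]]
    if (length(cand) == 0L) next
    pb <- as.numeric(pred[j, c("x1", "y1", "x2", "y2")])
    ious <- iou_matrix(boxes(pb), gt_boxes[cand, , drop = FALSE])[1L, ]
    ok <- which(ious >= iou_threshold)
    if (length(ok)) {
      g <- cand[ok[which.max(ious[ok])]]
      taken[g] <- TRUE
      is_tp[j] <- TRUE
    }
  }
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # all-point interpolation: envelope from the right, integrate recall steps
  prec_env <- rev(cummax(rev(precision)))
  rec_prev <- c(0, recall[-length(recall)])
  100 * sum((recall - rec_prev) * prec_env)
}

#' Evaluate a detection file against ground truth
#'
#' @param gt,pred Detection data frames (see [read_detections()]).
#' @param iou_threshold IoU defining a true positive.
#' @return List with `ap` (percent), pooled `tp`, `fp`, `fn`, `precision`
#'   and `recall` at the full operating point.
#' @export
evaluate_detections <- function(gt, pred, iou_threshold = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  tp <- fp <- fn <- 0L
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    gm <- if (nrow(g)) as.matrix(g[, c("x1", "y1", "x2", "y2")]) else boxes()
    pm <- if (nrow(p)) as.matrix(p[, c("x1", "y1", "x2", "y2")]) else boxes()
    res <- match_detections(gm, pm, conf = p$conf,
                            iou_threshold = iou_threshold)
    tp <- tp + res$tp; fp <- fp + res$fp; fn <- fn + res$fn
  }
  list(ap = average_precision(gt, pred, iou_threshold),
       tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
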