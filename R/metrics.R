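#' Detection evaluation metrics
#'
#' Matching follows the usual single-class detector protocol: detections are
#' processed in descending score order and greedily matched to the unmatched
#' ground-truth box of highest IoU, counting as a true positive only when that
#' IoU reaches the threshold. Precision and recall are reported at a fixed
#' confidence threshold (0.5 by default), while average precision sweeps all
#' confidences and integrates the precision-recall curve with all-point
#' interpolation. `mAP@0.5:0.95` averages AP over IoU thresholds 0.50 to 0.95
#' in steps of 0.05 (also reported under its `mAP@0.95` alias).
#'
#' @name metrics
NULL

# normalise a detection table: columns cx, cy, w, h, score [, image_id]
as_detections <- function(dets) {
  if (is.null(dets) || NROW(dets) == 0) {
    return(data.frame(image_id = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), score = numeric()))
  }
  stopifnot(all(c("cx", "cy", "w", "h", "score") %in% names(dets)))
  dets <- as.data.frame(dets)
  if (is.null(dets$image_id)) dets$image_id <- "img1"
  stopifnot(all(is.finite(dets$score)))
  dets
}

as_gt_table <- function(gts) {
  if (is.null(gts) || NROW(gts) == 0) {
    return(data.frame(image_id = character(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  }
  gts <- as.data.frame(gts)
  stopifnot(all(c("cx", "cy", "w", "h") %in% names(gts)))
  if (is.null(gts$image_id)) gts$image_id <- "img1"
  gts
}

#' Greedy score-ordered matching of detections to ground truth
#'
#' @param dets Data frame of detections with columns `cx, cy, w, h, score`
#'   (single image).
#' @param gts Ground-truth boxes for the same image.
#' @param iou_thresh Minimum IoU for a match (default 0.5).
#' @return A list with `tp` (logical per detection, in input order),
#'   `matched_gt` (index of matched ground truth or `NA`), `n_gt`, and
#'   `unmatched_gt` (count of ground-truth boxes left unmatched). Each ground
#'   truth is matched at most once.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  dets <- as_detections(dets)
  n_gt <- NROW(gts)
  nd <- nrow(dets)
  tp <- logical(nd); matched <- rep(NA_integer_, nd)
  if (nd > 0 && n_gt > 0) {
    g <- as_bbox(as_gt_table(gts)[, c("cx", "cy", "w", "h")])
    ord <- order(dets$score, decreasing = TRUE)
    taken <- logical(n_gt)
    for (i in ord) {
      ious <- box_iou(as_bbox(as.matrix(dets[i, c("cx", "cy", "w", "h")])), g)
      ious[taken] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_thresh) {
        tp[i] <- TRUE; matched[i] <- j; taken[j] <- TRUE
      }
    }
  }
  list(tp = tp, matched_gt = matched, n_gt = n_gt,
       unmatched_gt = n_gt - sum(tp))
}

#' Precision and recall at a confidence threshold
#'
#' @param tp Logical vector of true-positive flags per detection.
#' @param scores Detection confidences aligned with `tp`.
#' @param n_gt Number of ground-truth boxes.
#' @param conf_thresh Confidence cut-off (default 0.5); only detections at or
#'   above it are counted.
#' @return Named numeric vector `c(precision, recall)`; both are 0 when their
#'   denominators are 0.
#' @export
precision_recall <- function(tp, scores, n_gt, conf_thresh = 0.5) {
  keep <- scores >= conf_thresh
  ntp <- sum(tp & keep); nfp <- sum(!tp & keep)
  p <- if (ntp + nfp > 0) ntp / (ntp + nfp) else 0
  r <- if (n_gt > 0) ntp / n_gt else 0
  c(precision = p, recall = r)
}

# match per image at one IoU threshold; returns tp flags + scores pooled
match_all_images <- function(dets, gts, iou_thresh) {
  dets <- as_detections(dets); gts <- as_gt_table(gts)
  tp <- logical(nrow(dets))
  for (id in unique(c(dets$image_id, gts$image_id))) {
    di <- which(dets$image_id == id)
    gi <- gts[gts$image_id == id, , drop = FALSE]
    if (length(di)) {
      m <- match_detections(dets[di, , drop = FALSE], gi, iou_thresh)
      tp[di] <- m$tp
    }
  }
  list(tp = tp, scores = dets$score, n_gt = nrow(gts))
}

#' Average precision at one IoU threshold
#'
#' All detections enter the precision-recall sweep regardless of confidence;
#' the curve is integrated with all-point interpolation (precision envelope).
#'
#' @param dets Detection table with columns `cx, cy, w, h, score` and
#'   optionally `image_id`.
#' @param gts Ground-truth table (same columns minus `score`).
#' @param iou_thresh IoU threshold for a true positive.
#' @return AP in `[0, 1]`. Errors when there is no ground truth.
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5) {
  m <- match_all_images(dets, gts, iou_thresh)
  if (m$n_gt == 0) stop("average precision undefined: no ground-truth boxes")
  if (length(m$tp) == 0) return(0)
  ord <- order(m$scores, decreasing = TRUE)
  tp <- m$tp[ord]
  cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
  rec <- cum_tp / m$n_gt
  pre <- cum_tp / (cum_tp + cum_fp)
  # precision envelope from the right, integrate over recall steps
  env <- rev(cummax(rev(pre)))
  sum(diff(c(0, rec)) * env)
}

#' Mean AP over IoU 0.50 to 0.95
#'
#' @inheritParams average_precision
#' @return Mean of AP at thresholds `seq(0.5, 0.95, by = 0.05)`; never exceeds
#'   AP at 0.5 alone.
#' @export
map_range <- function(dets, gts) {
  mean(vapply(seq(0.5, 0.95, by = 0.05),
              function(t) average_precision(dets, gts, t), numeric(1)))
}

#' Headline evaluation report
#'
#' @inheritParams average_precision
#' @param conf_thresh Confidence threshold for precision/recall (default 0.5).
#' @return A list with `map50`, `map50_95` (alias `map95`), `precision`,
#'   `recall`, and counts.
#' @export
evaluation_report <- function(dets, gts, conf_thresh = 0.5) {
  m <- match_all_images(dets, gts, 0.5)
  pr <- precision_recall(m$tp, m$scores, m$n_gt, conf_thresh)
  map50 <- average_precision(dets, gts, 0.5)
  mrange <- map_range(dets, gts)
  list(map50 = map50, map50_95 = mrange, map95 = mrange,
       precision = unname(pr["precision"]), recall = unname(pr["recall"]),
       n_detections = length(m$tp), n_gt = m$n_gt)
}
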