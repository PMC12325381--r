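#' COCO-style detection metrics
#'
#' Computes average precision with 101-point interpolation per category and
#' IoU threshold (mean over IoU 0.5:0.95:0.05 for AP, plus AP50 and AP75),
#' and precision / recall / F1 at IoU 0.5 with a score threshold of 0.5.
#' All values are in \[0, 1\]; multiply by 100 for the conventional
#' percentage reporting.
#'
#' @param predictions Tibble of detections (`image_id`, `category_id`,
#'   `score`, `x`, `y`, `w`, `h`), boxes in pixels.
#' @param dataset A `detection_dataset` providing the ground truth (must
#'   contain at least one non-crowd annotation).
#' @param iou_thresholds IoU thresholds for the AP average.
#' @param score_threshold Operating point for precision / recall / F1.
#' @return A one-row tibble of class `detection_metrics`: `ap`, `ap50`,
#'   `ap75`, `precision`, `recall`, `f1`, `n_predictions`, `n_gt`.
#' @export
evaluate_detections <- function(predictions, dataset,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                score_threshold = 0.5) {
  gt <- dataset$annotations
  gt <- gt[!gt$iscrowd, , drop = FALSE]
  if (nrow(gt) == 0L) stopf("empty ground truth")
  predictions <- tibble::as_tibble(predictions)
  cats <- sort(unique(gt$category_id))
  ap_mat <- matrix(NA_real_, length(cats), length(iou_thresholds))
  for (ci in seq_along(cats)) {
    for (ti in seq_along(iou_thresholds)) {
      ap_mat[ci, ti] <- category_ap(
        predictions[predictions$category_id == cats[ci], , drop = FALSE],
        gt[gt$category_id == cats[ci], , drop = FALSE],
        iou_thresholds[ti])
    }
  }
  ap <- mean(ap_mat)
  ap50 <- if (0.5 %in% iou_thresholds) {
    mean(ap_mat[, which(abs(iou_thresholds - 0.5) < 1e-9)])
  } else {
    mean(vapply(seq_along(cats), function(ci) category_ap(
      predictions[predictions$category_id == cats[ci], , drop = FALSE],
      gt[gt$category_id == cats[ci], , drop = FALSE], 0.5), numeric(1)))
  }
  ap75 <- mean(vapply(seq_along(cats), function(ci) category_ap(
    predictions[predictions$category_id == cats[ci], , drop = FALSE],
    gt[gt$category_id == cats[ci], , drop = FALSE], 0.75), numeric(1)))
  prf <- precision_recall_at(predictions, gt, iou = 0.5,
                             score_threshold = score_threshold)
  structure(tibble::tibble(
    ap = ap, ap50 = ap50, ap75 = ap75,
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    n_predictions = nrow(predictions), n_gt = nrow(gt)),
    class = c("detection_metrics", class(tibble::tibble())))
}

# Greedy matching of score-ranked predictions to GT at one IoU threshold,
# then 101-point interpolated AP.
category_ap <- function(preds, gts, iou_threshold) {
  n_gt <- nrow(gts)
  if (n_gt == 0L) return(NA_real_)
  if (nrow(preds) == 0L) return(0)
  preds <- preds[order(-preds$score), , drop = FALSE]
  gt_xy <- cbind(gts$x, gts$y, gts$x + gts$w, gts$y + gts$h)
  matched <- rep(FALSE, n_gt)
  tp <- numeric(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    same_img <- which(gts$image_id == preds$image_id[i] & !matched)
    if (length(same_img) == 0L) next
    p_xy <- c(preds$x[i], preds$y[i], preds$x[i] + preds$w[i],
              preds$y[i] + preds$h[i])
    ious <- box_iou(matrix(p_xy, 1L), gt_xy[same_img, , drop = FALSE])
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- 1
      matched[same_img[best]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  # 101-point interpolation: mean over recall levels 0, 0.01, ..., 1 of the
  # maximum precision at recall >= level.
  p_interp <- rev(cummax(rev(precision)))
  levels <- seq(0, 1, by = 0.01)
  idx <- findInterval(levels, recall, left.open = TRUE) + 1L
  mean(ifelse(idx <= length(p_interp), p_interp[idx], 0))
}

precision_recall_at <- function(preds, gts, iou = 0.5,
                                score_threshold = 0.5) {
  preds <- preds[preds$score >= score_threshold, , drop = FALSE]
  n_gt <- nrow(gts)
  if (nrow(preds) == 0L) {
    return(list(precision = 0, recall = 0, f1 = 0))
  }
  preds <- preds[order(-preds$score), , drop = FALSE]
  matched <- rep(FALSE, n_gt)
  tp <- 0L
  for (i in seq_len(nrow(preds))) {
    same <- which(gts$image_id == preds$image_id[i] &
                    gts$category_id == preds$category_id[i] & !matched)
    if (length(same) == 0L) next
    p_xy <- c(preds$x[i], preds$y[i], preds$x[i] + preds$w[i],
              preds$y[i] + preds$h[i])
    gt_xy <- cbind(gts$x[same], gts$y[same], gts$x[same] + gts$w[same],
                   gts$y[same] + gts$h[same])
    ious <- box_iou(matrix(p_xy, 1L), gt_xy)
    best <- which.max(ious)
    if (ious[best] >= iou) {
      tp <- tp + 1L
      matched[same[best]] <- TRUE
    }
  }
  precision <- tp / nrow(preds)
  recall <- tp / n_gt
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  list(precision = precision, recall = recall, f1 = f1)
}
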