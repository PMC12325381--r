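# Box utilities (normalized (cx, cy, w, h) inside the model, converted to
# corner form for overlap computations) and Hungarian set matching.

#' Box format conversions
#'
#' Boxes inside the model are normalized `(cx, cy, w, h)`; overlap
#' computations use corner form `(x1, y1, x2, y2)`.
#'
#' @param boxes n x 4 matrix.
#' @return n x 4 matrix in the other convention.
#' @export
box_cxcywh_to_xyxy <- function(boxes) {
  boxes <- matrix(boxes, ncol = 4L)
  cbind(boxes[, 1] - boxes[, 3] / 2, boxes[, 2] - boxes[, 4] / 2,
        boxes[, 1] + boxes[, 3] / 2, boxes[, 2] + boxes[, 4] / 2)
}

#' @rdname box_cxcywh_to_xyxy
#' @export
box_xyxy_to_cxcywh <- function(boxes) {
  boxes <- matrix(boxes, ncol = 4L)
  cbind((boxes[, 1] + boxes[, 3]) / 2, (boxes[, 2] + boxes[, 4]) / 2,
        boxes[, 3] - boxes[, 1], boxes[, 4] - boxes[, 2])
}

#' Pairwise IoU and generalized IoU of corner-form boxes
#'
#' @param a n x 4, `b` m x 4 matrices in `(x1, y1, x2, y2)` form.
#' @return n x m matrix.
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4L); b <- matrix(b, ncol = 4L)
  ix1 <- outer(a[, 1], b[, 1], pmax); iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin); iy2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- outer(area_a, area_b, `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

#' @rdname box_iou
#' @export
generalized_box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4L); b <- matrix(b, ncol = 4L)
  iou <- box_iou(a, b)
  cx1 <- outer(a[, 1], b[, 1], pmin); cy1 <- outer(a[, 2], b[, 2], pmin)
  cx2 <- outer(a[, 3], b[, 3], pmax); cy2 <- outer(a[, 4], b[, 4], pmax)
  hull <- (cx2 - cx1) * (cy2 - cy1)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter <- iou * (outer(area_a, area_b, `+`)) / (1 + iou)  # recover inter
  un <- outer(area_a, area_b, `+`) - inter
  iou - ifelse(hull > 0, (hull - un) / hull, 0)
}

# GIoU loss value and analytic gradient for matched pairs (one pred per gt),
# corner form. Returns list(value = vector of (1 - GIoU), grad = n x 4
# gradient of sum(1 - GIoU) wrt pred coords). Piecewise-smooth; at ties the
# subgradient of the active branch is used.
giou_pair_grad <- function(pred, gt) {
  pred <- matrix(pred, ncol = 4L); gt <- matrix(gt, ncol = 4L)
  n <- nrow(pred)
  val <- numeric(n)
  grad <- matrix(0, n, 4L)
  for (i in seq_len(n)) {
    p <- pred[i, ]; g <- gt[i, ]
    dAp <- c(-(p[4] - p[2]), -(p[3] - p[1]), p[4] - p[2], p[3] - p[1])
    area_p <- (p[3] - p[1]) * (p[4] - p[2])
    area_g <- (g[3] - g[1]) * (g[4] - g[2])
    ix1 <- max(p[1], g[1]); iy1 <- max(p[2], g[2])
    ix2 <- min(p[3], g[3]); iy2 <- min(p[4], g[4])
    iw <- max(ix2 - ix1, 0); ih <- max(iy2 - iy1, 0)
    I <- iw * ih
    dI <- c(
      if (iw > 0 && ih > 0 && p[1] >= g[1]) -ih else 0,
      if (iw > 0 && ih > 0 && p[2] >= g[2]) -iw else 0,
      if (iw > 0 && ih > 0 && p[3] <= g[3])  ih else 0,
      if (iw > 0 && ih > 0 && p[4] <= g[4])  iw else 0)
    U <- area_p + area_g - I
    dU <- dAp - dI
    cx1 <- min(p[1], g[1]); cy1 <- min(p[2], g[2])
    cx2 <- max(p[3], g[3]); cy2 <- max(p[4], g[4])
    cw <- cx2 - cx1; ch <- cy2 - cy1
    C <- cw * ch
    dC <- c(if (p[1] <= g[1]) -ch else 0,
            if (p[2] <= g[2]) -cw else 0,
            if (p[3] >= g[3])  ch else 0,
            if (p[4] >= g[4])  cw else 0)
    iou <- if (U > 0) I / U else 0
    diou <- if (U > 0) (dI * U - I * dU) / U^2 else rep(0, 4L)
    pen <- if (C > 0) (C - U) / C else 0
    dpen <- if (C > 0) ((dC - dU) * C - (C - U) * dC) / C^2 else rep(0, 4L)
    val[i] <- 1 - (iou - pen)
    grad[i, ] <- -(diou - dpen)
  }
  list(value = val, grad = grad)
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the rectangular assignment problem with the O(n^3) potentials /
#' shortest-augmenting-path method. Requires at least as many rows
#' (predictions) as columns (ground truths); each column is assigned a
#' distinct row.
#'
#' @param cost n x m numeric matrix (n >= m).
#' @return Integer vector of length m: `result[j]` is the row assigned to
#'   column j.
#' @export
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  n_pred <- nrow(cost); n_gt <- ncol(cost)
  if (n_pred < n_gt) {
    stopf("need at least as many rows (%d) as columns (%d)", n_pred, n_gt)
  }
  # Assign each ground truth (row of the transposed problem) to a distinct
  # prediction (column), minimizing total cost.
  a <- t(cost)                       # n_gt x n_pred, n_gt <= n_pred
  n <- n_gt; m <- n_pred
  u <- rep(0, n + 1L)
  v <- rep(0, m + 1L)
  p <- rep(0L, m + 1L)               # p[j+1]: gt assigned to prediction j
  way <- rep(0L, m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      free_j <- which(!used[-1L])
      cur <- a[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      minv[free_j[upd]] <- cur[upd]
      way[free_j[upd] + 1L] <- j0
      jmin <- free_j[which.min(minv[free_j])]
      delta <- minv[jmin]; j1 <- jmin
      used_j <- which(used) - 1L
      u[p[used_j + 1L] + 1L] <- u[p[used_j + 1L] + 1L] + delta
      v[used_j + 1L] <- v[used_j + 1L] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

#' Hungarian matching of predictions to ground truths
#'
#' Builds the DETR-style matching cost
#' `w_cls * (1 - prob[gt class]) + w_l1 * L1(box) + w_giou * (1 - GIoU)`
#' over all (prediction, ground-truth) pairs and solves the minimum-cost
#' one-to-one assignment with the Hungarian algorithm.
#'
#' @param pred_boxes n x 4 matrix, normalized `(cx, cy, w, h)`.
#' @param pred_probs n x K matrix of per-class probabilities.
#' @param gt_boxes m x 4 matrix (m <= n), normalized `(cx, cy, w, h)`.
#' @param gt_labels Length-m integer class indices into the columns of
#'   `pred_probs`.
#' @param cost_weights Named numeric vector with `cls`, `l1`, `giou`
#'   components; defaults c(cls = 2, l1 = 5, giou = 2).
#' @return A tibble with columns `gt_index`, `pred_index`, `cost`.
#' @export
hungarian_match <- function(pred_boxes, pred_probs, gt_boxes, gt_labels,
                            cost_weights = c(cls = 2, l1 = 5, giou = 2)) {
  pred_boxes <- matrix(pred_boxes, ncol = 4L)
  gt_boxes <- matrix(gt_boxes, ncol = 4L)
  pred_probs <- as.matrix(pred_probs)
  n <- nrow(pred_boxes); m <- nrow(gt_boxes)
  if (n < m) stopf("fewer predictions (%d) than ground truths (%d)", n, m)
  cost <- matching_cost(pred_boxes, pred_probs, gt_boxes, gt_labels,
                        cost_weights)
  assign <- hungarian_assign(cost)
  tibble::tibble(
    gt_index = seq_len(m),
    pred_index = assign,
    cost = cost[cbind(assign, seq_len(m))])
}

matching_cost <- function(pred_boxes, pred_probs, gt_boxes, gt_labels,
                          cost_weights = c(cls = 2, l1 = 5, giou = 2)) {
  cls_cost <- 1 - pred_probs[, gt_labels, drop = FALSE]
  l1_cost <- vapply(seq_len(nrow(gt_boxes)), function(j) {
    rowSums(abs(sweep(pred_boxes, 2L, gt_boxes[j, ])))
  }, numeric(nrow(pred_boxes)))
  giou_cost <- 1 - generalized_box_iou(box_cxcywh_to_xyxy(pred_boxes),
                                       box_cxcywh_to_xyxy(gt_boxes))
  cost_weights[["cls"]] * cls_cost + cost_weights[["l1"]] * l1_cost +
    cost_weights[["giou"]] * giou_cost
}
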