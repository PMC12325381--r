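#' Build denoising query groups from ground-truth objects
#'
#' Training-only queries made by corrupting ground-truth boxes and labels:
#' each of `n_groups` groups holds one noised copy of every GT object
#' (centre jittered within half the box extent scaled by
#' `box_noise_scale`, sizes rescaled by factors in
#' `[1 - box_noise_scale, 1 + box_noise_scale]`, boxes clamped to the image,
#' labels flipped to a random other class with probability
#' `label_flip_prob`). The accompanying attention mask isolates them: the
#' ordinary matching queries may never attend to any denoising query, and
#' denoising groups may not attend to each other, so no ground-truth
#' information leaks into the matched predictions.
#'
#' @param gt_boxes m x 4 matrix, normalized `(cx, cy, w, h)`; may have zero
#'   rows (the denoising part is then empty).
#' @param gt_labels Length-m integer labels in `1..n_classes`.
#' @param n_classes Number of classes (>= 1).
#' @param n_matching Number of ordinary matching queries in the decoder.
#' @param n_groups Number of denoising groups (default 5).
#' @param box_noise_scale Box corruption strength (default 0.4, >= 0).
#' @param label_flip_prob Label corruption probability (default 0.5).
#' @param seed Optional seed.
#' @return An object of class `denoising_batch`: list with `boxes`
#'   (G*m x 4), `labels`, `group` (integer vector), `gt_index` (which GT each
#'   noised query descends from), `n_dn`, `n_matching`, and `attn_mask`, a
#'   (G*m + n_matching)^2 logical matrix (queries ordered denoising first,
#'   then matching; TRUE = attention blocked).
#' @export
build_denoising_queries <- function(gt_boxes, gt_labels, n_classes,
                                    n_matching, n_groups = 5L,
                                    box_noise_scale = 0.4,
                                    label_flip_prob = 0.5, seed = NULL) {
  if (box_noise_scale < 0) stopf("box_noise_scale must be >= 0")
  gt_boxes <- matrix(gt_boxes, ncol = 4L)
  m <- nrow(gt_boxes)
  n_dn <- n_groups * m
  total <- n_dn + n_matching
  attn_mask <- matrix(FALSE, total, total)
  if (m == 0L) {
    return(structure(list(boxes = gt_boxes, labels = integer(0),
                          group = integer(0), gt_index = integer(0),
                          n_dn = 0L, n_matching = n_matching,
                          attn_mask = attn_mask),
                     class = "denoising_batch"))
  }
  with_seed(seed, {
    group <- rep(seq_len(n_groups), each = m)
    gt_index <- rep(seq_len(m), times = n_groups)
    base <- gt_boxes[gt_index, , drop = FALSE]
    dcx <- runif(n_dn, -1, 1) * box_noise_scale * base[, 3] / 2
    dcy <- runif(n_dn, -1, 1) * box_noise_scale * base[, 4] / 2
    sw <- runif(n_dn, 1 - box_noise_scale, 1 + box_noise_scale)
    sh <- runif(n_dn, 1 - box_noise_scale, 1 + box_noise_scale)
    noised <- cbind(base[, 1] + dcx, base[, 2] + dcy,
                    base[, 3] * sw, base[, 4] * sh)
    xy <- box_cxcywh_to_xyxy(noised)
    xy <- cbind(clamp(xy[, 1], 0, 1), clamp(xy[, 2], 0, 1),
                clamp(xy[, 3], 0, 1), clamp(xy[, 4], 0, 1))
    noised <- box_xyxy_to_cxcywh(xy)
    labels <- gt_labels[gt_index]
    if (n_classes > 1L && label_flip_prob > 0) {
      flip <- runif(n_dn) < label_flip_prob
      if (any(flip)) {
        labels[flip] <- vapply(labels[flip], function(l) {
          sample(setdiff(seq_len(n_classes), l), 1L)
        }, integer(1))
      }
    }
    # Matching queries (rows n_dn+1..total) must not see denoising queries.
    if (n_matching > 0L) attn_mask[n_dn + seq_len(n_matching), seq_len(n_dn)] <- TRUE
    # Denoising groups must not see each other.
    for (g in seq_len(n_groups)) {
      attn_mask[which(group == g), which(group != g)] <- TRUE
    }
    structure(list(boxes = noised, labels = labels, group = group,
                   gt_index = gt_index, n_dn = n_dn,
                   n_matching = n_matching, attn_mask = attn_mask),
              class = "denoising_batch")
  })
}
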