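# Multi-scale deformable attention and DropKey-regularized softmax
# attention. Feature maps are H x W x C arrays; sampling locations are
# continuous pixel coordinates with (1, 1) at the centre of the top-left
# cell; samples falling outside a map contribute zero (zero padding).

# Bilinear sampling of a level at continuous points (n x 2: x, y in pixel
# units). Returns n x C.
bilinear_sample <- function(level, x, y) {
  H <- dim(level)[1]; W <- dim(level)[2]; C <- dim(level)[3]
  flat <- matrix(level, ncol = C)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- matrix(0, length(x), C)
  corner <- function(cx, cy, wgt) {
    ok <- cx >= 1 & cx <= W & cy >= 1 & cy <= H & wgt > 0
    if (any(ok)) {
      idx <- cy[ok] + (cx[ok] - 1) * H
      out[ok, ] <<- out[ok, , drop = FALSE] +
        flat[idx, , drop = FALSE] * wgt[ok]
    }
  }
  corner(x0, y0, (1 - fx) * (1 - fy))
  corner(x0 + 1, y0, fx * (1 - fy))
  corner(x0, y0 + 1, (1 - fx) * fy)
  corner(x0 + 1, y0 + 1, fx * fy)
  out
}

#' Multi-scale deformable attention
#'
#' For each query q with normalized reference point p in \[0, 1\]^2, each
#' attention head m samples K offset locations per pyramid level l by
#' bilinear interpolation, combines the per-head value projections of the
#' samples with non-negative weights A (normalized so the L*K weights of
#' each head sum to 1), projects each head's aggregate back to the model
#' width, and sums over heads. The reference point is scaled into each
#' level's own pixel grid; offsets are expressed in that level's pixel
#' units; samples outside a map contribute zero.
#'
#' @param pyramid List of L feature maps (H_l x W_l x C arrays, shared C).
#' @param reference Q x 2 matrix of normalized reference points (x, y).
#' @param offsets Array \[M, L, Q, K, 2\] of sampling offsets (pixel units of
#'   the corresponding level).
#' @param weights Array \[M, L, Q, K\] of attention weights; for each (m, q)
#'   the L*K entries must sum to 1.
#' @param value_proj Optional list of M matrices (C x C_head) applied to the
#'   sampled features (the per-head value projection). Identity when NULL.
#' @param output_proj Optional list of M matrices (C_head x C) mapping each
#'   head back to the model width. Identity when NULL.
#' @return Q x C matrix of attended features.
#' @export
ms_deform_attn <- function(pyramid, reference, offsets, weights,
                           value_proj = NULL, output_proj = NULL) {
  reference <- matrix(reference, ncol = 2L)
  Q <- nrow(reference)
  M <- dim(weights)[1]; L <- dim(weights)[2]; K <- dim(weights)[4]
  if (length(pyramid) != L) stopf("pyramid has %d levels, weights expect %d",
                                  length(pyramid), L)
  C <- dim(pyramid[[1]])[3]
  wsum <- apply(weights, c(1, 3), sum)
  if (any(abs(wsum - 1) > 1e-6)) {
    stopf("attention weights must sum to 1 over (levels x points) per head")
  }
  if (any(weights < -1e-12)) stopf("attention weights must be non-negative")
  if (any(!is.finite(offsets))) stopf("non-finite sampling offsets")
  # Weighted sample accumulation per (head, query); the value and output
  # projections are linear, so they are applied once per head after the
  # weighted sum over levels and points.
  acc <- matrix(0, M * Q, C)  # row g = head + (query - 1) * M
  for (l in seq_len(L)) {
    lev <- pyramid[[l]]
    if (dim(lev)[3] != C) stopf("level %d channel mismatch", l)
    H <- dim(lev)[1]; W <- dim(lev)[2]
    base_x <- rep(rep(reference[, 1] * W + 0.5, each = M), times = K)
    base_y <- rep(rep(reference[, 2] * H + 0.5, each = M), times = K)
    sx <- base_x + as.vector(offsets[, l, , , 1])
    sy <- base_y + as.vector(offsets[, l, , , 2])
    w <- as.vector(weights[, l, , ])
    samp <- bilinear_sample(lev, sx, sy) * w
    g <- rep(seq_len(M * Q), times = K)
    acc <- acc + rowsum(samp, g)
  }
  out <- matrix(0, Q, C)
  for (m in seq_len(M)) {
    head_acc <- acc[seq(m, M * Q, by = M), , drop = FALSE]
    if (!is.null(value_proj)) head_acc <- head_acc %*% value_proj[[m]]
    out <- out + if (is.null(output_proj)) head_acc else
      head_acc %*% output_proj[[m]]
  }
  out
}

# A deformable-attention layer: offsets and (softmax-normalized) weights are
# linear functions of the query feature, as in standard deformable DETR.
deform_layer_init <- function(C, M, L, K, seed) {
  with_seed(seed, {
    C_head <- max(1L, C %/% M)
    list(
      M = M, L = L, K = K, C = C, C_head = C_head,
      W_off = matrix(rnorm(C * M * L * K * 2, sd = 0.05), C),
      b_off = rnorm(M * L * K * 2, sd = 0.5),
      W_att = matrix(rnorm(C * M * L * K, sd = 0.2), C),
      b_att = rep(0, M * L * K),
      value_proj = lapply(seq_len(M), function(m)
        matrix(rnorm(C * C_head, sd = 1 / sqrt(C)), C, C_head)),
      output_proj = lapply(seq_len(M), function(m)
        matrix(rnorm(C_head * C, sd = 1 / sqrt(C_head)), C_head, C))
    )
  })
}

# Apply a deformable layer to queries z (Q x C) at reference points.
deform_layer_apply <- function(layer, z, reference, pyramid) {
  Q <- nrow(z)
  M <- layer$M; L <- layer$L; K <- layer$K
  off_raw <- z %*% layer$W_off +
    matrix(layer$b_off, Q, length(layer$b_off), byrow = TRUE)
  att_raw <- z %*% layer$W_att +
    matrix(layer$b_att, Q, length(layer$b_att), byrow = TRUE)
  # Column layout of W_off / W_att: (coord, point, level, head), fastest
  # first; reshape + permute to the [M, L, Q, K, ...] arrays the attention
  # core expects. Softmax normalizes the L*K weights of each (head, query).
  offsets <- aperm(array(t(off_raw), dim = c(2, K, L, M, Q)),
                   c(4, 3, 5, 2, 1))
  a <- matrix(array(t(att_raw), dim = c(K, L, M, Q)), nrow = K * L)
  a <- exp(sweep(a, 2L, apply(a, 2L, max)))
  a <- sweep(a, 2L, colSums(a), "/")
  weights <- aperm(array(a, dim = c(K, L, M, Q)), c(3, 2, 4, 1))
  ms_deform_attn(pyramid, reference, offsets, weights,
                 value_proj = layer$value_proj,
                 output_proj = layer$output_proj)
}

#' Scaled dot-product attention with DropKey regularization
#'
#' Standard softmax attention over `queries`/`keys`/`values`, optionally
#' masking entries (`attn_mask`), with DropKey applied during training: each
#' (query, key) logit is independently set to -Inf with probability
#' `drop_ratio` *before* the softmax, so the surviving keys renormalize and
#' each output row remains a convex combination of value rows. At inference
#' (`training = FALSE`) no dropping occurs. Rows whose keys are all dropped
#' fall back to the undropped attention for that row.
#'
#' @param queries nq x d matrix.
#' @param keys nk x d matrix.
#' @param values nk x dv matrix.
#' @param drop_ratio Probability of masking a logit, in \[0, 1).
#' @param training Apply DropKey only when TRUE.
#' @param attn_mask Optional nq x nk logical matrix; TRUE entries are
#'   blocked (set to -Inf) regardless of DropKey.
#' @return List with `output` (nq x dv) and `weights` (nq x nk, rows sum
#'   to 1).
#' @export
dropkey_attention <- function(queries, keys, values, drop_ratio = 0,
                              training = TRUE, attn_mask = NULL) {
  if (drop_ratio < 0 || drop_ratio >= 1) stopf("drop_ratio must be in [0, 1)")
  queries <- as.matrix(queries); keys <- as.matrix(keys)
  values <- as.matrix(values)
  logits <- queries %*% t(keys) / sqrt(ncol(queries))
  if (!is.null(attn_mask)) logits[attn_mask] <- -Inf
  base <- logits
  if (training && drop_ratio > 0) {
    drop <- matrix(runif(length(logits)) < drop_ratio, nrow(logits))
    logits[drop] <- -Inf
  }
  dead <- !apply(logits, 1L, function(r) any(is.finite(r)))
  if (any(dead)) {
    message(sprintf("DropKey: %d row(s) lost all keys; falling back", sum(dead)))
    logits[dead, ] <- base[dead, ]
  }
  w <- softmax_rows(logits)
  list(output = w %*% values, weights = w)
}
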