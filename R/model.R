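#' ResNet-50 backbone stage shape chain
#'
#' The deterministic spatial-size arithmetic of the detector backbone: a
#' stride-2 7x7 stem, a stride-2 3x3 max pool, then four residual stages of
#' strides 1, 2, 2, 2 with output widths 256/512/1024/2048. All stride-2
#' steps use "same" padding, i.e. ceiling division of the spatial size.
#'
#' @param input_h,input_w Input image size in pixels (>= 32).
#' @return A tibble with columns `stage`, `height`, `width`, `channels`.
#' @export
#' @examples
#' backbone_stage_shapes(1333, 800)
backbone_stage_shapes <- function(input_h, input_w) {
  if (input_h < 32 || input_w < 32) stopf("input must be at least 32x32")
  half <- function(x) ceiling(x / 2)
  h1 <- half(input_h); w1 <- half(input_w)      # conv1
  h2 <- half(h1); w2 <- half(w1)                # max pool
  h3 <- half(h2); w3 <- half(w2)                # conv3_x
  h4 <- half(h3); w4 <- half(w3)                # conv4_x
  h5 <- half(h4); w5 <- half(w4)                # conv5_x
  tibble::tibble(
    stage = c("conv1", "pool", "conv2_x", "conv3_x", "conv4_x", "conv5_x"),
    height = c(h1, h2, h2, h3, h4, h5),
    width = c(w1, w2, w2, w3, w4, w5),
    channels = c(64L, 64L, 256L, 512L, 1024L, 2048L))
}

#' Fine-grained token scores
#'
#' Scores each feature token as the product P = C * S of its best class
#' probability C (max over per-class sigmoids) and its foreground
#' probability S (sigmoid of the foreground logit). The product ranks tokens
#' that are simultaneously confidently classified and likely foreground,
#' which is what camouflaged objects need: a high class score on a
#' background-like token is down-weighted by a low foreground score.
#'
#' @param class_logits n x K matrix of per-token class logits.
#' @param foreground_logits Length-n vector of foreground logits.
#' @return Tibble with columns `token`, `class_prob`, `fg_prob`, `score`.
#' @export
fgsp_scores <- function(class_logits, foreground_logits) {
  class_logits <- as.matrix(class_logits)
  if (nrow(class_logits) != length(foreground_logits)) {
    stopf("one foreground logit per token required")
  }
  P <- sigmoid(class_logits)
  C <- if (ncol(P) == 1L) P[, 1L] else P[cbind(seq_len(nrow(P)),
                                               max.col(P, "first"))]
  S <- sigmoid(foreground_logits)
  tibble::tibble(token = seq_along(S), class_prob = C, fg_prob = S,
                 score = C * S)
}

#' Keep the top-scoring fraction of tokens
#'
#' @param scores A tibble from [fgsp_scores()] (needs `score`).
#' @param keep_ratio Fraction of tokens to keep, in (0, 1\].
#' @return Integer indices of the top `ceiling(keep_ratio * n)` tokens by
#'   score; ties broken toward the lower index.
#' @export
select_foreground_tokens <- function(scores, keep_ratio) {
  if (keep_ratio <= 0 || keep_ratio > 1) stopf("keep_ratio must be in (0, 1]")
  n <- nrow(scores)
  if (n == 0L) stopf("empty token list")
  k <- ceiling(keep_ratio * n)
  ord <- order(-scores$score, seq_len(n))
  sort(ord[seq_len(k)])
}

#' Desk-scale detector configuration
#'
#' The full-scale architecture (ResNet-50, 4 pyramid levels at model width
#' 256, 8 heads, 4 sampling points, 6+6 layers, 300 queries) is far beyond
#' what CPU-bound tests should run, so the package ships a `desk` profile:
#' 2 pyramid levels (strides 8 and 16) at width 16, 2 heads, 2 points, 2+2
#' layers, 20 queries, fixed 128x128 inputs. The architectural contracts
#' (attention normalization, masking, score products, loss structure) are
#' identical across profiles.
#'
#' @param profile `"desk"` (default) or `"full"` (shape bookkeeping only;
#'   the trainer always runs the desk profile).
#' @param image_size Square input size in pixels.
#' @param maskmlp,dn,dropkey,fgsp Ablation flags; all TRUE is the full
#'   model, all FALSE the plain deformable-DETR-style baseline.
#' @param dropkey_ratio DropKey masking probability in decoder
#'   self-attention (training only).
#' @param keep_ratio Foreground token keep fraction used when `fgsp` is on.
#' @param n_queries Number of matching queries.
#' @param dn_groups,dn_box_noise,dn_label_flip Denoising settings.
#' @param weights A [loss_weights()] vector.
#' @param cost_weights Hungarian cost weights (cls, l1, giou).
#' @return A list of class `keyfg_config`.
#' @export
keyfg_config <- function(profile = c("desk", "full"), image_size = 128L,
                         maskmlp = TRUE, dn = TRUE, dropkey = TRUE,
                         fgsp = TRUE, dropkey_ratio = 0.1, keep_ratio = 0.3,
                         n_queries = 20L, dn_groups = 3L, dn_box_noise = 0.4,
                         dn_label_flip = 0.5, weights = loss_weights(),
                         cost_weights = c(cls = 2, l1 = 5, giou = 2)) {
  profile <- match.arg(profile)
  dims <- if (profile == "desk") {
    list(strides = c(8L, 16L), d_model = 32L, heads = 2L, points = 2L,
         enc_layers = 2L, dec_layers = 2L, hidden = 64L)
  } else {
    list(strides = c(8L, 16L, 32L, 64L), d_model = 256L, heads = 8L,
         points = 4L, enc_layers = 6L, dec_layers = 6L, hidden = 256L)
  }
  structure(c(dims, list(
    profile = profile, image_size = as.integer(image_size),
    flags = list(maskmlp = maskmlp, dn = dn, dropkey = dropkey, fgsp = fgsp),
    dropkey_ratio = dropkey_ratio, keep_ratio = keep_ratio,
    n_queries = as.integer(n_queries),
    dn = list(groups = dn_groups, box_noise = dn_box_noise,
              label_flip = dn_label_flip),
    weights = weights, cost_weights = cost_weights)),
    class = "keyfg_config")
}

# --- stand-in backbone ------------------------------------------------------
# A deterministic, weightless feature extractor with the same stride
# arithmetic as the convolutional backbone: per grid cell it computes the
# block mean and standard deviation of each colour channel (6 statistics),
# which a fixed seeded linear map projects to the model width. It needs no
# pretrained weights, is bias-free for constant inputs, and keeps the
# chromatic information the camouflage task revolves around.

block_stats <- function(image, stride) {
  H <- dim(image)[1]; W <- dim(image)[2]
  Hc <- ceiling(H / stride); Wc <- ceiling(W / stride)
  r_cell <- (seq_len(H) - 1L) %/% stride + 1L
  c_cell <- (seq_len(W) - 1L) %/% stride + 1L
  cell <- matrix(r_cell, H, W) + (matrix(c_cell, H, W, byrow = TRUE) - 1L) * Hc
  flat <- matrix(image, ncol = 3L) / 255
  grp <- as.vector(cell)
  n <- tabulate(grp, nbins = Hc * Wc)
  sums <- rowsum(flat, grp)
  means <- sums / n
  sq <- rowsum(flat^2, grp) / n
  sds <- sqrt(pmax(sq - means^2, 0))
  array(cbind(means, sds), dim = c(Hc, Wc, 6L))
}

# Project 6 block statistics to the model width with a fixed seeded linear
# map + tanh. One map per pyramid level.
project_level <- function(stats, proj) {
  dm <- dim(stats)
  flat <- matrix(stats, ncol = 6L)
  z <- tanh(flat %*% proj$P + matrix(proj$b, nrow(flat), length(proj$b),
                                     byrow = TRUE))
  array(z, dim = c(dm[1], dm[2], ncol(proj$P)))
}

#' Construct a desk-scale detector
#'
#' Builds the fixed (seeded) parts of the model — per-level feature
#' projections, encoder/decoder attention layers, denoising-query embedding
#' — and the trainable parts: the token prediction head (class / foreground
#' / box over encoder tokens, feeding the fine-grained score selection), the
#' query prediction head (class / box over decoder outputs) and the
#' soft-mask module. At desk scale only the heads and the soft-mask module
#' receive gradient updates; the attention stack acts as a fixed, residual
#' feature transform.
#'
#' @param config A [keyfg_config()].
#' @param n_classes Number of object classes.
#' @param seed Master seed; all parameter streams derive from it.
#' @return An object of class `keyfg_model`.
#' @export
keyfg_model <- function(config = keyfg_config(), n_classes = 1L, seed = 1L) {
  C <- config$d_model
  L <- length(config$strides)
  grid <- lapply(config$strides, function(s)
    c(ceiling(config$image_size / s), ceiling(config$image_size / s)))
  proj <- lapply(seq_len(L), function(l) {
    with_seed(derive_seed(seed, paste0("proj", l)), list(
      P = matrix(rnorm(6 * C, sd = 0.8), 6L, C),
      b = rnorm(C, sd = 0.1)))
  })
  enc_layers <- lapply(seq_len(config$enc_layers), function(i)
    deform_layer_init(C, config$heads, L, config$points,
                      derive_seed(seed, paste0("enc", i))))
  dec_layers <- lapply(seq_len(config$dec_layers), function(i) {
    list(
      self = with_seed(derive_seed(seed, paste0("dec_self", i)), list(
        Wq = matrix(rnorm(C * C, sd = 1 / sqrt(C)), C),
        Wk = matrix(rnorm(C * C, sd = 1 / sqrt(C)), C),
        Wv = matrix(rnorm(C * C, sd = 1 / sqrt(C)), C))),
      cross = deform_layer_init(C, config$heads, L, config$points,
                                derive_seed(seed, paste0("dec_cross", i))))
  })
  dn_embed <- with_seed(derive_seed(seed, "dn_embed"),
                        matrix(rnorm(4 * C, sd = 0.5), 4L, C))
  # Fixed positional/level embeddings added to the projected tokens, so a
  # token's feature encodes where it sits as well as what it looks like
  # (box regression needs both).
  posenc <- with_seed(derive_seed(seed, "posenc"), list(
    W = matrix(rnorm(16 * C, sd = 0.3), 16L, C),
    level = matrix(rnorm(L * C, sd = 0.2), L, C)))
  hd <- config$hidden
  heads <- list(
    token_class = mlp_init(c(C, hd, n_classes),
                           derive_seed(seed, "token_class")),
    token_fg = mlp_init(c(C, hd, 1L), derive_seed(seed, "token_fg")),
    token_box = mlp_init(c(C, hd, 4L), derive_seed(seed, "token_box")),
    query_class = mlp_init(c(C, hd, n_classes),
                           derive_seed(seed, "query_class")),
    query_box = mlp_init(c(C, hd, 4L), derive_seed(seed, "query_box")))
  # Detection-style priors: classification/foreground logits start negative
  # (objects are rare among tokens), box sizes start near a quarter of the
  # image rather than half.
  for (nm in c("token_class", "token_fg", "query_class")) {
    heads[[nm]]$b[[2]][] <- -2
  }
  heads$token_box$b[[2]][3:4] <- -1.1
  # query_box refines an anchor box; zero deltas keep the anchor.
  mask_mod <- maskmlp_init(grid[[1]][1], grid[[1]][2], C, hidden = 16L,
                           seed = derive_seed(seed, "maskmlp"))
  structure(
    list(config = config, n_classes = as.integer(n_classes), seed = seed,
         grid = grid, proj = proj, enc_layers = enc_layers,
         dec_layers = dec_layers, dn_embed = dn_embed, posenc = posenc,
         heads = heads, maskmlp = mask_mod),
    class = "keyfg_model")
}

#' @export
print.keyfg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<keyfg_model (%s): %d levels (strides %s), width %d, %d+%d layers, %d queries, %d class(es)>\n",
    cfg$profile, length(cfg$strides),
    paste(cfg$strides, collapse = "/"), cfg$d_model, cfg$enc_layers,
    cfg$dec_layers, cfg$n_queries, x$n_classes))
  flags <- cfg$flags
  cat(sprintf("  flags: maskmlp=%s dn=%s dropkey=%s fgsp=%s\n",
              flags$maskmlp, flags$dn, flags$dropkey, flags$fgsp))
  invisible(x)
}

# Token table (level, row, col, normalized centre) in the order token
# features are stacked: level by level, rows fastest within a level.
token_table <- function(grid) {
  dplyr::bind_rows(lapply(seq_along(grid), function(l) {
    Hc <- grid[[l]][1]; Wc <- grid[[l]][2]
    tibble::tibble(
      level = l,
      row = rep(seq_len(Hc), Wc),
      col = rep(seq_len(Wc), each = Hc),
      cx = (rep(seq_len(Wc), each = Hc) - 0.5) / Wc,
      cy = (rep(seq_len(Hc), Wc) - 0.5) / Hc)
  }))
}

tokens_to_pyramid <- function(z, grid) {
  out <- vector("list", length(grid))
  off <- 0L
  for (l in seq_along(grid)) {
    n <- grid[[l]][1] * grid[[l]][2]
    out[[l]] <- array(z[off + seq_len(n), , drop = FALSE],
                      dim = c(grid[[l]][1], grid[[l]][2], ncol(z)))
    off <- off + n
  }
  out
}

# Box decoding: deltas -> normalized cxcywh around an anchor point/box.
decode_boxes <- function(deltas, anchor_cx, anchor_cy) {
  cbind(anchor_cx + 0.25 * tanh(deltas[, 1]),
        anchor_cy + 0.25 * tanh(deltas[, 2]),
        sigmoid(deltas[, 3]), sigmoid(deltas[, 4]))
}

# Jacobian factors of decode_boxes wrt the deltas.
decode_boxes_jac <- function(deltas) {
  cbind(0.25 * (1 - tanh(deltas[, 1])^2),
        0.25 * (1 - tanh(deltas[, 2])^2),
        sigmoid(deltas[, 3]) * (1 - sigmoid(deltas[, 3])),
        sigmoid(deltas[, 4]) * (1 - sigmoid(deltas[, 4])))
}

# Iterative-refinement decoding: deltas adjust an anchor box (the token
# proposal for matching queries, the noised box for denoising queries).
# Zero deltas reproduce the anchor; the anchor is treated as detached.
decode_refine <- function(deltas, anchor_boxes) {
  cbind(anchor_boxes[, 1] + 0.25 * tanh(deltas[, 1]),
        anchor_boxes[, 2] + 0.25 * tanh(deltas[, 2]),
        pmin(anchor_boxes[, 3] * exp(0.5 * tanh(deltas[, 3])), 1),
        pmin(anchor_boxes[, 4] * exp(0.5 * tanh(deltas[, 4])), 1))
}

decode_refine_jac <- function(deltas, anchor_boxes) {
  w <- anchor_boxes[, 3] * exp(0.5 * tanh(deltas[, 3]))
  h <- anchor_boxes[, 4] * exp(0.5 * tanh(deltas[, 4]))
  cbind(0.25 * (1 - tanh(deltas[, 1])^2),
        0.25 * (1 - tanh(deltas[, 2])^2),
        ifelse(w < 1, w * 0.5 * (1 - tanh(deltas[, 3])^2), 0),
        ifelse(h < 1, h * 0.5 * (1 - tanh(deltas[, 4])^2), 0))
}


# Sinusoidal positional features of the token centres (4 frequencies per
# axis) mapped through a fixed projection, plus a per-level embedding.
positional_embedding <- function(tok, posenc) {
  freqs <- c(1, 2, 4, 8)
  feats <- do.call(cbind, lapply(freqs, function(f)
    cbind(sin(2 * pi * f * tok$cx), cos(2 * pi * f * tok$cx),
          sin(2 * pi * f * tok$cy), cos(2 * pi * f * tok$cy))))
  feats %*% posenc$W + posenc$level[tok$level, , drop = FALSE]
}

#' Forward pass of the desk-scale detector
#'
#' Runs the stand-in backbone, per-level projection, deformable-attention
#' encoder (with optional soft-mask refinement of the finest memory level),
#' fine-grained token scoring and selection, and the decoder (DropKey
#' self-attention + deformable cross-attention) over the selected queries,
#' plus — during training with ground truth — a parallel denoising-query
#' branch isolated by the attention mask.
#'
#' @param model A [keyfg_model()].
#' @param image H x W x 3 array in \[0, 255\] with H = W =
#'   `config$image_size`.
#' @param annotations Optional tibble of ground-truth boxes (`x`, `y`, `w`,
#'   `h` in pixels, `category_id`); required for the denoising branch.
#' @param training Logical; enables DropKey and the denoising branch.
#' @return A list with the token table and scores, proposals, selected
#'   indices, decoder outputs (`query_logits`, `query_boxes`), denoising
#'   outputs, the soft mask, and the caches needed for head gradients.
#' @export
keyfg_forward <- function(model, image, annotations = NULL,
                          training = FALSE) {
  enc <- keyfg_encode(model, image)
  keyfg_head_forward(model, enc, annotations = annotations,
                     training = training)
}

# Fixed portion of the forward pass (stand-in backbone, projections,
# deformable-attention encoder). None of it carries trainable parameters at
# desk scale, so the training loop computes it once per image and caches it.
keyfg_encode <- function(model, image) {
  cfg <- model$config
  if (dim(image)[1] != cfg$image_size || dim(image)[2] != cfg$image_size) {
    stopf("image must be %dx%d for this model", cfg$image_size,
          cfg$image_size)
  }
  L <- length(cfg$strides)
  stats <- lapply(cfg$strides, function(s) block_stats(image, s))
  pyramid <- lapply(seq_len(L), function(l)
    project_level(stats[[l]], model$proj[[l]]))
  tok <- token_table(model$grid)
  z <- do.call(rbind, lapply(pyramid, function(p)
    matrix(p, ncol = dim(p)[3])))
  z <- z + positional_embedding(tok, model$posenc)
  refs <- cbind(tok$cx, tok$cy)
  for (layer in model$enc_layers) {
    z <- z + 0.1 * deform_layer_apply(layer, z, refs,
                                      tokens_to_pyramid(z, model$grid))
  }
  list(z = z, tokens = tok, refs = refs)
}

# Trainable portion: soft mask, token head + fine-grained selection,
# decoder, query head, denoising branch.
keyfg_head_forward <- function(model, enc, annotations = NULL,
                               training = FALSE) {
  cfg <- model$config
  tok <- enc$tokens
  refs <- enc$refs
  z <- enc$z
  soft_mask <- NULL
  if (cfg$flags$maskmlp) {
    mem_l1 <- tokens_to_pyramid(z, model$grid)[[1]]
    soft_mask <- maskmlp_mask(mem_l1, model$maskmlp)
    n1 <- model$grid[[1]][1] * model$grid[[1]][2]
    z[seq_len(n1), ] <- matrix(apply_soft_mask(mem_l1, soft_mask),
                               ncol = ncol(z))
  }
  memory <- z
  # Token head: dense proposals + fine-grained scores.
  f_cls <- mlp_forward(model$heads$token_class, memory)
  f_fg <- mlp_forward(model$heads$token_fg, memory)
  f_box <- mlp_forward(model$heads$token_box, memory)
  token_logits <- f_cls$out
  fg_logits <- as.vector(f_fg$out)
  proposals <- decode_boxes(f_box$out, tok$cx, tok$cy)
  # Inline fine-grained scores (fgsp_scores() returns the same quantities
  # as a tibble for interactive use; the hot path keeps plain vectors).
  P <- sigmoid(token_logits)
  class_prob <- if (ncol(P) == 1L) P[, 1L] else
    P[cbind(seq_len(nrow(P)), max.col(P, "first"))]
  fg_prob <- sigmoid(fg_logits)
  scores <- list(class_prob = class_prob, fg_prob = fg_prob,
                 score = class_prob * fg_prob)
  rank_score <- if (cfg$flags$fgsp) scores$score else scores$class_prob
  n_sel <- min(cfg$n_queries, nrow(tok))
  sel <- order(-rank_score, seq_len(nrow(tok)))[seq_len(n_sel)]
  sel <- sort(sel)

  # Denoising branch inputs.
  dn <- NULL
  gt <- normalize_gt(annotations, cfg$image_size)
  if (training && cfg$flags$dn && !is.null(gt) && nrow(gt$boxes) > 0L) {
    dn <- build_denoising_queries(
      gt$boxes, gt$labels, model$n_classes, n_matching = n_sel,
      n_groups = cfg$dn$groups, box_noise_scale = cfg$dn$box_noise,
      label_flip_prob = cfg$dn$label_flip)
  }
  n_dn <- if (is.null(dn)) 0L else dn$n_dn
  q_feat <- memory[sel, , drop = FALSE]
  q_ref <- refs[sel, , drop = FALSE]
  if (n_dn > 0L) {
    dn_feat <- dn$boxes %*% model$dn_embed
    q_feat <- rbind(dn_feat, q_feat)
    q_ref <- rbind(dn$boxes[, 1:2, drop = FALSE], q_ref)
  }
  attn_mask <- if (n_dn > 0L) dn$attn_mask else NULL
  ratio <- if (training && cfg$flags$dropkey) cfg$dropkey_ratio else 0
  mem_pyramid <- tokens_to_pyramid(memory, model$grid)
  for (layer in model$dec_layers) {
    sa <- dropkey_attention(q_feat %*% layer$self$Wq,
                            q_feat %*% layer$self$Wk,
                            q_feat %*% layer$self$Wv,
                            drop_ratio = ratio, training = training,
                            attn_mask = attn_mask)
    q_feat <- q_feat + 0.1 * sa$output
    q_feat <- q_feat + 0.1 * deform_layer_apply(layer$cross, q_feat, q_ref,
                                                mem_pyramid)
  }
  g_cls <- mlp_forward(model$heads$query_class, q_feat)
  g_box <- mlp_forward(model$heads$query_box, q_feat)
  anchor_boxes <- proposals[sel, , drop = FALSE]
  if (n_dn > 0L) anchor_boxes <- rbind(dn$boxes, anchor_boxes)
  query_boxes <- decode_refine(g_box$out, anchor_boxes)
  match_rows <- n_dn + seq_len(n_sel)
  list(
    tokens = tok, token_logits = token_logits, fg_logits = fg_logits,
    proposals = proposals, scores = scores, selected = sel,
    soft_mask = soft_mask, gt = gt, dn = dn, n_dn = n_dn,
    query_logits = g_cls$out[match_rows, , drop = FALSE],
    query_boxes = query_boxes[match_rows, , drop = FALSE],
    dn_logits = if (n_dn > 0L) g_cls$out[seq_len(n_dn), , drop = FALSE],
    dn_boxes = if (n_dn > 0L) query_boxes[seq_len(n_dn), , drop = FALSE],
    caches = list(token_class = f_cls$cache, token_fg = f_fg$cache,
                  token_box = f_box$cache, query_class = g_cls$cache,
                  query_box = g_box$cache),
    deltas = list(token_box = f_box$out, query_box = g_box$out),
    anchor_boxes = anchor_boxes)
}

# Normalized (cx, cy, w, h) GT boxes + labels from a pixel annotation table.
normalize_gt <- function(annotations, image_size) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(NULL)
  an <- annotations
  if ("iscrowd" %in% names(an)) an <- an[!an$iscrowd, , drop = FALSE]
  if (nrow(an) == 0L) return(NULL)
  list(
    boxes = cbind((an$x + an$w / 2) / image_size,
                  (an$y + an$h / 2) / image_size,
                  an$w / image_size, an$h / image_size),
    labels = as.integer(an$category_id),
    masks = if ("mask" %in% names(an)) an$mask else NULL)
}
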