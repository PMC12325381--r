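#' Training configuration
#'
#' Defaults follow the standard operating point for this detector family:
#' Adam, initial learning rate 0.001, weight decay 0.0005, cosine-annealed
#' schedule, batch size 4. Ablation flags switch the four architectural
#' additions on or off.
#'
#' @param lr Initial learning rate.
#' @param optimizer Only `"adam"` is implemented.
#' @param weight_decay L2 weight decay coefficient.
#' @param schedule `"cosine"` (annealed to 0 at the final epoch) or
#'   `"constant"`.
#' @param batch_size Images per optimizer step.
#' @param epochs Training epochs.
#' @param seed Master seed; model init, data order, DropKey and denoising
#'   noise all derive their streams from it.
#' @param maskmlp,dn,dropkey,fgsp Ablation flags.
#' @param image_size,n_queries Passed to [keyfg_config()].
#' @param min_steps_per_epoch Minimum optimizer steps per epoch. Full-scale
#'   detection epochs span hundreds of batches; a desk dataset of a handful
#'   of images would otherwise give an "epoch" of one or two steps, so
#'   batches are cycled (reshuffling each pass) until at least this many
#'   steps have run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, optimizer = "adam",
                         weight_decay = 0.0005, schedule = "cosine",
                         batch_size = 4L, epochs = 50L, seed = 1L,
                         maskmlp = TRUE, dn = TRUE, dropkey = TRUE,
                         fgsp = TRUE, image_size = 128L, n_queries = 20L,
                         min_steps_per_epoch = 40L) {
  if (optimizer != "adam") stopf("only the adam optimizer is implemented")
  if (!schedule %in% c("cosine", "constant")) {
    stopf("schedule must be 'cosine' or 'constant'")
  }
  structure(
    list(lr = lr, optimizer = optimizer, weight_decay = weight_decay,
         schedule = schedule, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed),
         flags = list(maskmlp = maskmlp, dn = dn, dropkey = dropkey,
                      fgsp = fgsp),
         image_size = as.integer(image_size),
         n_queries = as.integer(n_queries),
         min_steps_per_epoch = as.integer(min_steps_per_epoch)),
    class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' @param epoch Epoch index, 1-based.
#' @param total_epochs Total number of epochs.
#' @param lr0 Initial learning rate.
#' @return The learning rate for that epoch; `lr0` at epoch 1, annealed to 0
#'   at the final epoch.
#' @export
cosine_lr <- function(epoch, total_epochs, lr0) {
  if (total_epochs <= 1L) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / (total_epochs - 1)))
}

# --- trainable parameter bookkeeping ---------------------------------------

trainable_names <- c("token_class", "token_fg", "token_box",
                     "query_class", "query_box")

get_model_params <- function(model) {
  v <- unlist(lapply(trainable_names, function(nm)
    flatten_params(model$heads[[nm]])))
  c(v, flatten_params(model$maskmlp$spatial),
    flatten_params(model$maskmlp$channel))
}

set_model_params <- function(model, v) {
  off <- 0L
  for (nm in trainable_names) {
    n <- length(flatten_params(model$heads[[nm]]))
    model$heads[[nm]] <- unflatten_params(model$heads[[nm]],
                                          v[off + seq_len(n)])
    off <- off + n
  }
  for (nm in c("spatial", "channel")) {
    n <- length(flatten_params(model$maskmlp[[nm]]))
    model$maskmlp[[nm]] <- unflatten_params(model$maskmlp[[nm]],
                                            v[off + seq_len(n)])
    off <- off + n
  }
  model
}

flatten_grads <- function(g) unlist(c(lapply(g$W, as.vector),
                                      lapply(g$b, as.vector)))

# Foreground labels: 1 when a token's centre lies inside any GT box.
token_fg_labels <- function(tokens, gt_boxes) {
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0L) {
    return(rep(0, nrow(tokens)))
  }
  lab <- rep(0, nrow(tokens))
  for (i in seq_len(nrow(gt_boxes))) {
    b <- gt_boxes[i, ]
    inside <- abs(tokens$cx - b[1]) <= b[3] / 2 &
      abs(tokens$cy - b[2]) <= b[4] / 2
    lab[inside] <- 1
  }
  lab
}

# Union of GT object masks downsampled to the finest feature grid
# (block mean >= 0.25 counts as foreground).
gt_grid_mask <- function(masks, grid1, stride) {
  if (is.null(masks) || all(vapply(masks, is.null, logical(1)))) return(NULL)
  acc <- NULL
  for (m in masks) {
    if (is.null(m)) next
    acc <- if (is.null(acc)) (m > 0) * 1 else pmax(acc, (m > 0) * 1)
  }
  if (is.null(acc)) return(NULL)
  down <- block_stats(array(rep(acc * 255, 3), dim = c(dim(acc), 3L)),
                      stride)[, , 1]
  (down >= 0.25) * 1
}

# Per-image loss components and parameter gradients (same flattened layout
# as get_model_params). The attention stack is a fixed transform at desk
# scale, so gradients stop at the head inputs.
image_loss_grads <- function(model, fwd, grid_mask = NULL) {
  cfg <- model$config
  lw <- cfg$weights
  n_tok <- nrow(fwd$tokens)
  K <- model$n_classes
  gt <- fwd$gt
  comp <- c(match = 0, dn = 0, mask = 0, fg = 0, enc = 0)

  d_token_class <- matrix(0, n_tok, K)
  d_token_fg <- matrix(0, n_tok, 1L)
  d_token_box <- matrix(0, n_tok, 4L)
  nq <- nrow(fwd$query_logits)
  n_all <- fwd$n_dn + nq
  d_query_class <- matrix(0, n_all, K)
  d_query_box_delta <- matrix(0, n_all, 4L)

  gt_boxes <- if (is.null(gt)) NULL else gt$boxes
  gt_labels <- if (is.null(gt)) integer(0) else gt$labels

  # Foreground-selector component.
  fg_lab <- token_fg_labels(fwd$tokens, gt_boxes)
  s <- sigmoid(fwd$fg_logits)
  bce <- bce_loss(s, fg_lab)
  comp["fg"] <- bce$value
  d_token_fg[, 1] <- lw[["fg"]] * bce$grad * s * (1 - s)

  # Encoder auxiliary component over candidate tokens.
  if (!is.null(gt_boxes) && nrow(gt_boxes) > 0L) {
    cand <- union(which(fg_lab == 1),
                  utils::head(order(-fwd$scores$class_prob), 20L))
    cand <- sort(cand)
    if (length(cand) >= nrow(gt_boxes)) {
      probs <- sigmoid(fwd$token_logits[cand, , drop = FALSE])
      assign <- hungarian_assign(matching_cost(
        fwd$proposals[cand, , drop = FALSE], probs, gt_boxes, gt_labels,
        cfg$cost_weights))
      sl <- set_loss_grad(fwd$token_logits[cand, , drop = FALSE],
                          fwd$proposals[cand, , drop = FALSE],
                          gt_boxes, gt_labels, assign)
      comp["enc"] <- sl$value
      d_token_class[cand, ] <- lw[["enc"]] * sl$g_logits
      jac <- decode_boxes_jac(fwd$deltas$token_box[cand, , drop = FALSE])
      d_token_box[cand, ] <- lw[["enc"]] * sl$g_boxes * jac
    }
  }

  # Hungarian-matched set component on the decoder outputs.
  if (!is.null(gt_boxes) && nrow(gt_boxes) > 0L &&
      nq >= nrow(gt_boxes)) {
    probs <- sigmoid(fwd$query_logits)
    assign <- hungarian_assign(matching_cost(fwd$query_boxes, probs,
                                             gt_boxes, gt_labels,
                                             cfg$cost_weights))
    sl <- set_loss_grad(fwd$query_logits, fwd$query_boxes, gt_boxes,
                        gt_labels, assign)
    comp["match"] <- sl$value
    rows <- fwd$n_dn + seq_len(nq)
    d_query_class[rows, ] <- d_query_class[rows, , drop = FALSE] +
      lw[["match"]] * sl$g_logits
    jac <- decode_refine_jac(fwd$deltas$query_box[rows, , drop = FALSE],
                             fwd$anchor_boxes[rows, , drop = FALSE])
    d_query_box_delta[rows, ] <- d_query_box_delta[rows, , drop = FALSE] +
      lw[["match"]] * sl$g_boxes * jac
  } else if (!is.null(fwd$query_logits)) {
    sl <- set_loss_grad(fwd$query_logits, fwd$query_boxes,
                        matrix(numeric(0), 0, 4), integer(0), integer(0))
    comp["match"] <- sl$value
    rows <- fwd$n_dn + seq_len(nq)
    d_query_class[rows, ] <- lw[["match"]] * sl$g_logits
  }

  # Denoising component: each noised query reconstructs its own GT.
  if (fwd$n_dn > 0L) {
    own_boxes <- gt_boxes[fwd$dn$gt_index, , drop = FALSE]
    own_labels <- gt_labels[fwd$dn$gt_index]
    sl <- set_loss_grad(fwd$dn_logits, fwd$dn_boxes, own_boxes, own_labels,
                        seq_len(fwd$n_dn))
    comp["dn"] <- sl$value
    rows <- seq_len(fwd$n_dn)
    d_query_class[rows, ] <- d_query_class[rows, , drop = FALSE] +
      lw[["dn"]] * sl$g_logits
    jac <- decode_refine_jac(fwd$deltas$query_box[rows, , drop = FALSE],
                             fwd$anchor_boxes[rows, , drop = FALSE])
    d_query_box_delta[rows, ] <- d_query_box_delta[rows, , drop = FALSE] +
      lw[["dn"]] * sl$g_boxes * jac
  }

  # Soft-mask component.
  mask_grads <- NULL
  if (!is.null(fwd$soft_mask) && !is.null(gt)) {
    gm <- if (!is.null(grid_mask)) grid_mask else
      gt_grid_mask(gt$masks, model$grid[[1]], cfg$strides[1])
    if (!is.null(gm)) {
      ml <- maskmlp_loss_grad(model$maskmlp, fwd$soft_mask, gm)
      comp["mask"] <- ml$value
      mask_grads <- ml$grads
    }
  }

  # Backpropagate the accumulated head gradients.
  g <- list(
    token_class = mlp_backward(model$heads$token_class,
                               fwd$caches$token_class, d_token_class),
    token_fg = mlp_backward(model$heads$token_fg, fwd$caches$token_fg,
                            d_token_fg),
    token_box = mlp_backward(model$heads$token_box, fwd$caches$token_box,
                             d_token_box),
    query_class = mlp_backward(model$heads$query_class,
                               fwd$caches$query_class, d_query_class),
    query_box = mlp_backward(model$heads$query_box, fwd$caches$query_box,
                             d_query_box_delta))
  gv <- unlist(lapply(trainable_names, function(nm) flatten_grads(g[[nm]])))
  zero_s <- rep(0, length(flatten_params(model$maskmlp$spatial)))
  zero_c <- rep(0, length(flatten_params(model$maskmlp$channel)))
  if (!is.null(mask_grads)) {
    zero_s <- lw[["mask"]] * flatten_grads(mask_grads$spatial)
    zero_c <- lw[["mask"]] * flatten_grads(mask_grads$channel)
  }
  list(components = comp, grad = c(gv, zero_s, zero_c),
       total = sum(comp * as.numeric(lw[names(comp)])))
}

#' Train the desk-scale detector
#'
#' Full forward / loss / update loop: per batch, forward every image
#' (DropKey and denoising noise active), assemble the five-component
#' composite loss, backpropagate into the prediction heads and the soft-mask
#' module, and take an Adam step on the cosine-annealed learning rate. The
#' run is deterministic given `config$seed` (up to floating-point reduction
#' order) and aborts with a diagnostic if the loss diverges.
#'
#' @param dataset A `detection_dataset` with in-memory pixels whose images
#'   match `config$image_size`.
#' @param config A [train_config()].
#' @return An object of class `keyfg_fit`: the trained model, the config and
#'   a per-epoch log tibble (`epoch`, `lr`, component means and `total`).
#' @export
train_detector <- function(dataset, config = train_config()) {
  validate_dataset(dataset)
  if (nrow(dataset$annotations) == 0L) stopf("dataset has no annotations")
  mcfg <- keyfg_config(
    image_size = config$image_size, n_queries = config$n_queries,
    maskmlp = config$flags$maskmlp, dn = config$flags$dn,
    dropkey = config$flags$dropkey, fgsp = config$flags$fgsp)
  model <- keyfg_model(mcfg, n_classes = max(dataset$categories$id),
                       seed = derive_seed(config$seed, "model_init"))
  theta <- get_model_params(model)
  state <- adam_init(length(theta))
  img_ids <- dataset$images$id
  ann_by_img <- split(seq_len(nrow(dataset$annotations)),
                      dataset$annotations$image_id)
  # The encoder stack carries no trainable parameters, so its output per
  # image is computed once and reused every step.
  enc_cache <- lapply(setNames(img_ids, as.character(img_ids)), function(id)
    keyfg_encode(model, get_image(dataset, id)))
  mask_cache <- lapply(setNames(img_ids, as.character(img_ids)), function(id) {
    anns <- dataset$annotations[ann_by_img[[as.character(id)]], ,
                                drop = FALSE]
    if (!"mask" %in% names(anns)) return(NULL)
    gt_grid_mask(anns$mask, model$grid[[1]], mcfg$strides[1])
  })
  log <- vector("list", config$epochs)
  with_seed(derive_seed(config$seed, "train_loop"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- if (config$schedule == "cosine") {
        cosine_lr(epoch, config$epochs, config$lr)
      } else {
        config$lr
      }
      batches <- list()
      while (length(batches) < config$min_steps_per_epoch ||
               length(batches) %% ceiling(length(img_ids) /
                                            config$batch_size) != 0L) {
        order_ids <- sample(img_ids)
        batches <- c(batches,
                     split(order_ids,
                           ceiling(seq_along(order_ids) /
                                     config$batch_size)))
      }
      comp_sum <- c(match = 0, dn = 0, mask = 0, fg = 0, enc = 0)
      total_sum <- 0
      n_seen <- 0L
      for (batch in batches) {
        grad <- rep(0, length(theta))
        for (id in batch) {
          anns <- dataset$annotations[ann_by_img[[as.character(id)]], ,
                                      drop = FALSE]
          fwd <- keyfg_head_forward(model, enc_cache[[as.character(id)]],
                                    annotations = anns, training = TRUE)
          lg <- image_loss_grads(model, fwd,
                                 grid_mask = mask_cache[[as.character(id)]])
          if (!is.finite(lg$total)) {
            stopf("training diverged (non-finite loss) at epoch %d, image %s",
                  epoch, id)
          }
          grad <- grad + lg$grad / length(batch)
          comp_sum <- comp_sum + lg$components
          total_sum <- total_sum + lg$total
          n_seen <- n_seen + 1L
        }
        st <- adam_step(theta, grad, state, lr,
                        weight_decay = config$weight_decay)
        theta <- st$theta
        state <- st$state
        model <- set_model_params(model, theta)
      }
      log[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr,
        match = comp_sum[["match"]] / n_seen, dn = comp_sum[["dn"]] / n_seen,
        mask = comp_sum[["mask"]] / n_seen, fg = comp_sum[["fg"]] / n_seen,
        enc = comp_sum[["enc"]] / n_seen, total = total_sum / n_seen)
    }
  })
  structure(list(model = model, config = config,
                 log = dplyr::bind_rows(log)),
            class = "keyfg_fit")
}

#' @export
print.keyfg_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<keyfg_fit: %d epochs, final total loss %.4f>\n",
              nrow(x$log), last$total))
  invisible(x)
}

#' @rdname train_detector
#' @param x,object A `keyfg_fit`.
#' @param ... Unused.
#' @export
tidy.keyfg_fit <- function(x, ...) x$log

#' @rdname train_detector
#' @export
glance.keyfg_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), c("total", "match", "dn", "mask", "fg", "enc")]
  names(last) <- paste0("final_", names(last))
  dplyr::bind_cols(tibble::tibble(epochs = nrow(x$log)), last)
}

#' @rdname train_detector
#' @export
autoplot.keyfg_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, cols = c("match", "dn", "mask",
                                                   "fg", "enc", "total"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss")
}

#' Detect objects in a dataset with a trained model
#'
#' @param object A `keyfg_fit` (or `keyfg_model`).
#' @param dataset A `detection_dataset` with images matching the model's
#'   input size.
#' @param score_threshold Minimum detection score to report.
#' @param ... Unused.
#' @return A tibble of detections: `image_id`, `category_id`, `score`,
#'   `x`, `y`, `w`, `h` (pixels).
#' @export
predict.keyfg_fit <- function(object, dataset, score_threshold = 0.05, ...) {
  predict_detections(object$model, dataset, score_threshold)
}

#' @rdname predict.keyfg_fit
#' @export
predict.keyfg_model <- function(object, dataset, score_threshold = 0.05,
                                ...) {
  predict_detections(object, dataset, score_threshold)
}

predict_detections <- function(model, dataset, score_threshold = 0.05) {
  sz <- model$config$image_size
  out <- list()
  for (id in dataset$images$id) {
    fwd <- keyfg_forward(model, get_image(dataset, id), training = FALSE)
    probs <- sigmoid(fwd$query_logits)
    score <- apply(probs, 1L, max)
    cls <- apply(probs, 1L, which.max)
    keep <- which(score >= score_threshold)
    if (length(keep) == 0L) next
    xy <- box_cxcywh_to_xyxy(fwd$query_boxes[keep, , drop = FALSE]) * sz
    xy <- cbind(clamp(xy[, 1], 0, sz), clamp(xy[, 2], 0, sz),
                clamp(xy[, 3], 0, sz), clamp(xy[, 4], 0, sz))
    out[[length(out) + 1L]] <- tibble::tibble(
      image_id = id, category_id = as.integer(cls[keep]),
      score = score[keep],
      x = xy[, 1], y = xy[, 2],
      w = pmax(xy[, 3] - xy[, 1], 0), h = pmax(xy[, 4] - xy[, 2], 0))
  }
  if (length(out) == 0L) {
    return(tibble::tibble(image_id = integer(), category_id = integer(),
                          score = numeric(), x = numeric(), y = numeric(),
                          w = numeric(), h = numeric()))
  }
  dplyr::bind_rows(out)
}
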