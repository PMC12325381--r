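#' Extract an annotated object as a patch with its mask
#'
#' Crops the annotation's bounding box from its image. When the annotation
#' carries a pixel mask (synthetic scenes) that mask is cropped alongside;
#' otherwise the full box rectangle acts as the mask (real detection
#' datasets typically lack instance masks).
#'
#' @param dataset A `detection_dataset`.
#' @param annotation_id Id of the annotation to extract.
#' @return An `object_patch`: list with `pixels` (h x w x 3), `mask`
#'   (h x w, 0/1), `category_id`, `source_annotation_id`.
#' @export
extract_object_patch <- function(dataset, annotation_id) {
  an <- dataset$annotations
  i <- which(an$id == annotation_id)
  if (length(i) != 1L) stopf("unknown annotation id %s", annotation_id)
  img <- get_image(dataset, an$image_id[i])
  H <- dim(img)[1]; W <- dim(img)[2]
  x0 <- floor(an$x[i]); y0 <- floor(an$y[i])
  wp <- max(1L, round(an$w[i])); hp <- max(1L, round(an$h[i]))
  rows <- clamp(y0 + 1L, 1L, H):clamp(y0 + hp, 1L, H)
  cols <- clamp(x0 + 1L, 1L, W):clamp(x0 + wp, 1L, W)
  patch <- img[rows, cols, , drop = FALSE]
  m <- an$mask[[i]]
  mask <- if (is.null(m)) {
    matrix(1, length(rows), length(cols))
  } else {
    (m[rows, cols, drop = FALSE] > 0) * 1
  }
  if (sum(mask) == 0L) stopf("annotation %s has an empty mask", annotation_id)
  structure(list(pixels = patch, mask = mask,
                 category_id = an$category_id[i],
                 source_annotation_id = an$id[i]),
            class = "object_patch")
}

# Rotate (degrees, about the patch centre) and scale a patch + mask by
# inverse-map nearest-neighbour resampling, then tight-crop to the mask.
warp_patch <- function(patch, rotation_deg = 0, scale = 1) {
  h <- dim(patch$pixels)[1]; w <- dim(patch$pixels)[2]
  theta <- rotation_deg * pi / 180
  ct <- cos(theta); st <- sin(theta)
  # Output canvas: transformed corner extents.
  corners <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h))
  corners <- sweep(corners, 2L, c(w / 2, h / 2))
  rot <- cbind(corners[, 1] * ct - corners[, 2] * st,
               corners[, 1] * st + corners[, 2] * ct) * scale
  out_w <- max(1L, ceiling(diff(range(rot[, 1]))))
  out_h <- max(1L, ceiling(diff(range(rot[, 2]))))
  # Inverse map each output pixel centre to source coordinates.
  xs <- matrix(rep(seq_len(out_w) - 0.5 - out_w / 2, each = out_h),
               out_h, out_w)
  ys <- matrix(rep(seq_len(out_h) - 0.5 - out_h / 2, out_w), out_h, out_w)
  sx <- (xs * ct + ys * st) / scale + w / 2
  sy <- (-xs * st + ys * ct) / scale + h / 2
  sc <- floor(sx) + 1L
  sr <- floor(sy) + 1L
  inside <- sc >= 1L & sc <= w & sr >= 1L & sr <= h
  mask <- matrix(0, out_h, out_w)
  mask[inside] <- patch$mask[cbind(sr[inside], sc[inside])]
  if (sum(mask) == 0L) stopf("degenerate transform: empty warped mask")
  px <- array(0, dim = c(out_h, out_w, 3L))
  for (k in 1:3) {
    plane <- matrix(0, out_h, out_w)
    plane[inside] <- patch$pixels[, , k][cbind(sr[inside], sc[inside])]
    px[, , k] <- plane
  }
  keep_r <- range(which(rowSums(mask) > 0))
  keep_c <- range(which(colSums(mask) > 0))
  list(pixels = px[keep_r[1]:keep_r[2], keep_c[1]:keep_c[2], , drop = FALSE],
       mask = mask[keep_r[1]:keep_r[2], keep_c[1]:keep_c[2], drop = FALSE])
}

#' Copy-paste one object into another image
#'
#' Picks a random annotated object from the source, applies a random
#' rotation and scaling, and pastes it at a random position fully inside the
#' destination image (hard masking: pasted pixels replace destination pixels
#' where the transformed mask is 1). The pasted annotation's box is the
#' transformed mask's tight bounding box. Existing destination annotations
#' are kept untouched, including any the pasted object now occludes.
#'
#' @param src List with `image` (array) and `annotations` (tibble; >= 1 row).
#' @param dst List with `image` and `annotations`.
#' @param rotation_range Rotation range in degrees, default c(-30, 30).
#' @param scale_range Scale factor range, default c(0.7, 1.3).
#' @param n_paste Number of objects to paste.
#' @param seed Optional seed.
#' @return List with `image` and `annotations` (destination annotations plus
#'   the pasted ones; new annotation ids continue from the maximum present).
#' @export
copy_paste_augment <- function(src, dst, rotation_range = c(-30, 30),
                               scale_range = c(0.7, 1.3), n_paste = 1L,
                               seed = NULL) {
  if (nrow(src$annotations) < 1L) stopf("source has no annotations")
  with_seed(seed, {
    image <- dst$image
    anns <- dst$annotations
    H <- dim(image)[1]; W <- dim(image)[2]
    next_id <- if (nrow(anns) > 0L) max(anns$id) + 1L else 1L
    for (p in seq_len(n_paste)) {
      i <- sample.int(nrow(src$annotations), 1L)
      patch0 <- list(
        pixels = crop_box(src$image, src$annotations[i, ]),
        mask = crop_mask(src$annotations[i, ]))
      warped <- warp_patch(patch0,
                           rotation_deg = runif(1, rotation_range[1],
                                                rotation_range[2]),
                           scale = runif(1, scale_range[1], scale_range[2]))
      ph <- dim(warped$mask)[1]; pw <- dim(warped$mask)[2]
      if (ph > H || pw > W) {
        warnf("transformed patch (%dx%d) does not fit, skipped", ph, pw)
        next
      }
      placed <- FALSE
      for (attempt in seq_len(50L)) {
        r0 <- sample.int(H - ph + 1L, 1L) - 1L
        c0 <- sample.int(W - pw + 1L, 1L) - 1L
        placed <- TRUE
        break
      }
      if (!placed) {
        warnf("could not place pasted object, skipped")
        next
      }
      sel <- which(warped$mask > 0)
      rr <- ((sel - 1L) %% ph) + 1L
      cc <- ((sel - 1L) %/% ph) + 1L
      for (k in 1:3) {
        plane <- image[, , k]
        plane[cbind(r0 + rr, c0 + cc)] <- warped$pixels[, , k][sel]
        image[, , k] <- plane
      }
      full_mask <- matrix(0, H, W)
      full_mask[cbind(r0 + rr, c0 + cc)] <- 1
      anns <- dplyr::bind_rows(anns, tibble::tibble(
        id = next_id,
        image_id = if ("image_id" %in% names(anns) && nrow(anns) > 0L)
          anns$image_id[1] else NA_integer_,
        category_id = src$annotations$category_id[i],
        x = min(cc) + c0 - 1, y = min(rr) + r0 - 1,
        w = diff(range(cc)) + 1, h = diff(range(rr)) + 1,
        iscrowd = FALSE,
        mask = list(full_mask)))
      next_id <- next_id + 1L
    }
    list(image = image, annotations = anns)
  })
}

crop_box <- function(image, ann) {
  H <- dim(image)[1]; W <- dim(image)[2]
  x0 <- floor(ann$x); y0 <- floor(ann$y)
  wp <- max(1L, round(ann$w)); hp <- max(1L, round(ann$h))
  image[clamp(y0 + 1L, 1L, H):clamp(y0 + hp, 1L, H),
        clamp(x0 + 1L, 1L, W):clamp(x0 + wp, 1L, W), , drop = FALSE]
}

crop_mask <- function(ann) {
  m <- ann$mask[[1]]
  x0 <- floor(ann$x); y0 <- floor(ann$y)
  wp <- max(1L, round(ann$w)); hp <- max(1L, round(ann$h))
  if (is.null(m)) return(matrix(1, hp, wp))
  H <- dim(m)[1]; W <- dim(m)[2]
  (m[clamp(y0 + 1L, 1L, H):clamp(y0 + hp, 1L, H),
     clamp(x0 + 1L, 1L, W):clamp(x0 + wp, 1L, W), drop = FALSE] > 0) * 1
}

#' Grow a dataset to a target size by copy-paste augmentation
#'
#' Keeps every original image and creates new images by pasting a randomly
#' transformed object from a random source image onto a copy of a random
#' destination image, until the dataset holds `n_target_images` images.
#' Deterministic given `seed`.
#'
#' @param dataset A `detection_dataset` with in-memory pixels and >= 1
#'   annotation.
#' @param n_target_images Target image count (>= current count).
#' @param seed Integer seed.
#' @param rotation_range,scale_range,n_paste Passed to
#'   [copy_paste_augment()].
#' @return The augmented `detection_dataset`; augmented images are flagged in
#'   a logical `augmented` column of `images`.
#' @export
augment_dataset <- function(dataset, n_target_images, seed = 1L,
                            rotation_range = c(-30, 30),
                            scale_range = c(0.7, 1.3), n_paste = 1L) {
  validate_dataset(dataset)
  if (nrow(dataset$annotations) == 0L) stopf("dataset has no annotations")
  n_orig <- nrow(dataset$images)
  if (n_target_images < n_orig) {
    stopf("n_target_images (%d) below current image count (%d)",
          n_target_images, n_orig)
  }
  images <- dplyr::mutate(dataset$images, augmented = FALSE)
  annotations <- dataset$annotations
  pixels <- dataset$pixels
  next_img <- max(images$id) + 1L
  next_ann <- max(annotations$id) + 1L
  ann_by_img <- split(seq_len(nrow(annotations)), annotations$image_id)
  src_pool <- as.integer(names(ann_by_img))
  with_seed(derive_seed(seed, "augment"), {
    while (nrow(images) < n_target_images) {
      src_id <- src_pool[sample.int(length(src_pool), 1L)]
      dst_id <- dataset$images$id[sample.int(n_orig, 1L)]
      src <- list(image = get_image(dataset, src_id),
                  annotations = annotations[ann_by_img[[as.character(src_id)]], ,
                                            drop = FALSE])
      dst_anns <- dataset$annotations[dataset$annotations$image_id == dst_id, ,
                                      drop = FALSE]
      dst <- list(image = get_image(dataset, dst_id), annotations = dst_anns)
      out <- copy_paste_augment(src, dst,
                                rotation_range = rotation_range,
                                scale_range = scale_range, n_paste = n_paste)
      new_anns <- out$annotations
      new_anns$image_id <- next_img
      new_anns$id <- next_ann - 1L + seq_len(nrow(new_anns))
      next_ann <- next_ann + nrow(new_anns)
      dims <- dataset$images[dataset$images$id == dst_id, ]
      images <- dplyr::bind_rows(images, tibble::tibble(
        id = next_img, width = dims$width, height = dims$height,
        file_name = sprintf("aug_%05d.png", next_img), augmented = TRUE))
      annotations <- dplyr::bind_rows(annotations, new_anns)
      pixels[[as.character(next_img)]] <- out$image
      next_img <- next_img + 1L
    }
    detection_dataset(images, annotations, dataset$categories,
                      pixels = pixels, image_dir = dataset$image_dir)
  })
}
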