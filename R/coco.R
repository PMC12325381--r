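#' In-memory detection dataset (COCO detection dialect)
#'
#' A light container mirroring the COCO detection annotation model: an
#' `images` table, an `annotations` table with `[x, y, w, h]` boxes (0-based,
#' origin top-left), and a `categories` table. Pixel data can either live
#' in memory (`pixels`, a named list of H x W x 3 arrays in \[0, 255\], keyed
#' by image id — the form the synthetic generator produces) or on disk under
#' `image_dir` referenced by `file_name`.
#'
#' @param images Data frame with columns `id`, `width`, `height`, `file_name`.
#' @param annotations Data frame with columns `id`, `image_id`,
#'   `category_id`, `x`, `y`, `w`, `h`, and optionally `iscrowd` (0/1 or
#'   logical) and `mask` (list of H x W 0/1 matrices for synthetic objects).
#' @param categories Data frame with columns `id`, `name`.
#' @param pixels Optional named list of image arrays.
#' @param image_dir Optional directory holding the image files.
#' @return A validated `detection_dataset`.
#' @export
detection_dataset <- function(images, annotations, categories,
                              pixels = NULL, image_dir = NULL) {
  images <- tibble::as_tibble(images)
  annotations <- tibble::as_tibble(annotations)
  categories <- tibble::as_tibble(categories)
  if (!"iscrowd" %in% names(annotations)) {
    annotations$iscrowd <- rep(FALSE, nrow(annotations))
  }
  annotations$iscrowd <- as.logical(annotations$iscrowd)
  if (!"mask" %in% names(annotations)) {
    annotations$mask <- rep(list(NULL), nrow(annotations))
  }
  ds <- structure(
    list(images = images, annotations = annotations,
         categories = categories, pixels = pixels, image_dir = image_dir),
    class = "detection_dataset"
  )
  validate_dataset(ds)
  ds
}

#' @export
print.detection_dataset <- function(x, ...) {
  cat(sprintf(
    "<detection_dataset: %d images, %d annotations, %d categories%s>\n",
    nrow(x$images), nrow(x$annotations), nrow(x$categories),
    if (!is.null(x$pixels)) ", pixels in memory" else ""))
  invisible(x)
}

#' @rdname detection_dataset
#' @param dataset A `detection_dataset`.
#' @export
validate_dataset <- function(dataset) {
  im <- dataset$images
  an <- dataset$annotations
  for (col in c("id", "width", "height", "file_name")) {
    if (!col %in% names(im)) stopf("images table missing column '%s'", col)
  }
  for (col in c("id", "image_id", "category_id", "x", "y", "w", "h")) {
    if (!col %in% names(an)) {
      stopf("annotations table missing column '%s'", col)
    }
  }
  if (anyDuplicated(im$id)) stopf("duplicate image ids")
  if (nrow(an) > 0L) {
    if (anyDuplicated(an$id)) {
      stopf("duplicate annotation ids: %s",
            paste(unique(an$id[duplicated(an$id)]), collapse = ", "))
    }
    missing_img <- setdiff(an$image_id, im$id)
    if (length(missing_img) > 0L) {
      stopf("annotations reference missing image id(s): %s",
            paste(missing_img, collapse = ", "))
    }
    dims <- im[match(an$image_id, im$id), c("width", "height")]
    bad <- an$x < 0 | an$y < 0 | an$w <= 0 | an$h <= 0 |
      an$x + an$w > dims$width + 1e-6 | an$y + an$h > dims$height + 1e-6
    if (any(bad)) {
      stopf("out-of-bounds or degenerate bbox for annotation id(s): %s",
            paste(an$id[bad], collapse = ", "))
    }
  }
  invisible(dataset)
}

#' Read a COCO-format annotation file
#'
#' Parses a COCO detection JSON (images / annotations / categories arrays)
#' into a [detection_dataset()] and validates its invariants, reporting
#' offending annotation ids.
#'
#' @param path Path to the JSON annotation file.
#' @param image_dir Optional directory containing the referenced images.
#' @return A `detection_dataset`.
#' @export
read_coco <- function(path, image_dir = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stopf("malformed JSON: %s", e$message))
  for (key in c("images", "annotations", "categories")) {
    if (is.null(js[[key]])) stopf("missing top-level key '%s'", key)
  }
  images <- dplyr::bind_rows(lapply(js$images, function(x) {
    tibble::tibble(id = x$id, width = x$width, height = x$height,
                   file_name = x$file_name %||% NA_character_)
  }))
  annotations <- dplyr::bind_rows(lapply(js$annotations, function(a) {
    bb <- as.numeric(unlist(a$bbox))
    if (length(bb) != 4L) stopf("annotation %s: bbox must have 4 entries", a$id)
    crowd <- isTRUE(a$iscrowd == 1)
    tibble::tibble(id = a$id, image_id = a$image_id,
                   category_id = a$category_id,
                   x = bb[1], y = bb[2], w = bb[3], h = bb[4],
                   iscrowd = crowd)
  }))
  categories <- dplyr::bind_rows(lapply(js$categories, function(x) {
    tibble::tibble(id = x$id, name = x$name %||% NA_character_)
  }))
  if (length(js$annotations) == 0L) {
    annotations <- tibble::tibble(
      id = integer(), image_id = integer(), category_id = integer(),
      x = numeric(), y = numeric(), w = numeric(), h = numeric(),
      iscrowd = logical())
  }
  detection_dataset(images, annotations, categories, image_dir = image_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset as a COCO-format annotation file
#'
#' @param dataset A `detection_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(dataset, path) {
  validate_dataset(dataset)
  an <- dataset$annotations
  js <- list(
    images = purrr::pmap(
      dataset$images[, c("id", "width", "height", "file_name")],
      function(id, width, height, file_name) {
        list(id = id, width = width, height = height, file_name = file_name)
      }),
    annotations = lapply(seq_len(nrow(an)), function(i) {
      list(id = an$id[i], image_id = an$image_id[i],
           category_id = an$category_id[i],
           bbox = c(an$x[i], an$y[i], an$w[i], an$h[i]),
           area = an$w[i] * an$h[i],
           iscrowd = as.integer(an$iscrowd[i]))
    }),
    categories = purrr::pmap(dataset$categories[, c("id", "name")],
                             function(id, name) list(id = id, name = name))
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fetch an image's pixel array
#'
#' @param dataset A `detection_dataset`.
#' @param image_id Image id.
#' @return H x W x 3 array with values in \[0, 255\]. Grayscale files are
#'   replicated to three channels with a warning.
#' @export
get_image <- function(dataset, image_id) {
  key <- as.character(image_id)
  if (!is.null(dataset$pixels) && key %in% names(dataset$pixels)) {
    return(dataset$pixels[[key]])
  }
  row <- dataset$images[dataset$images$id == image_id, , drop = FALSE]
  if (nrow(row) == 0L) stopf("unknown image id %s", key)
  if (is.null(dataset$image_dir)) stopf("image %s: no pixels and no image_dir", key)
  f <- file.path(dataset$image_dir, row$file_name[1])
  if (!file.exists(f)) stopf("image file not found: %s", f)
  img <- png::readPNG(f)
  if (length(dim(img)) == 2L) {
    warnf("grayscale image %s: replicating to 3 channels", key)
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Extract per-object foreground and background pixel regions
#'
#' Rasterizes each annotation's box onto the integer pixel grid (floor of
#' x, y; round of w, h) and returns the box interior as that object's
#' foreground. The background is either the whole image minus the union of
#' all annotated boxes (shared by every object), or, in `local_surround`
#' mode, a 3x-dilated copy of the object's box minus the union of all boxes.
#'
#' @param image H x W x 3 array in \[0, 255\].
#' @param annotations Data frame with columns `x`, `y`, `w`, `h` (and `id`).
#' @param mode `"whole_image_minus_boxes"` or `"local_surround"`.
#' @return List with `foreground` and `background`: parallel lists (one
#'   entry per annotation) of N x 3 pixel matrices. An empty background is
#'   returned as a 0-row matrix, not an error.
#' @export
extract_regions <- function(image, annotations,
                            mode = c("whole_image_minus_boxes",
                                     "local_surround")) {
  mode <- match.arg(mode)
  dm <- dim(image)
  H <- dm[1]; W <- dm[2]
  flat <- matrix(image, ncol = 3L)  # row index r + (c-1)*H
  n <- nrow(annotations)
  boxes <- lapply(seq_len(n), function(j) {
    x0 <- floor(annotations$x[j]); y0 <- floor(annotations$y[j])
    wp <- max(1L, round(annotations$w[j])); hp <- max(1L, round(annotations$h[j]))
    c1 <- clamp(x0 + 1L, 1L, W); c2 <- clamp(x0 + wp, 1L, W)
    r1 <- clamp(y0 + 1L, 1L, H); r2 <- clamp(y0 + hp, 1L, H)
    list(r = r1:r2, c = c1:c2)
  })
  free <- matrix(TRUE, H, W)
  for (b in boxes) free[b$r, b$c] <- FALSE

  fg <- lapply(boxes, function(b) {
    sel <- as.vector(outer(b$r, (b$c - 1L) * H, `+`))
    flat[sel, , drop = FALSE]
  })
  if (mode == "whole_image_minus_boxes") {
    bg_px <- flat[which(free), , drop = FALSE]
    bg <- rep(list(bg_px), n)
  } else {
    bg <- lapply(seq_len(n), function(j) {
      x0 <- annotations$x[j]; y0 <- annotations$y[j]
      w <- annotations$w[j]; h <- annotations$h[j]
      cx <- x0 + w / 2; cy <- y0 + h / 2
      c1 <- clamp(floor(cx - 1.5 * w) + 1L, 1L, W)
      c2 <- clamp(ceiling(cx + 1.5 * w), 1L, W)
      r1 <- clamp(floor(cy - 1.5 * h) + 1L, 1L, H)
      r2 <- clamp(ceiling(cy + 1.5 * h), 1L, H)
      local <- matrix(FALSE, H, W)
      local[r1:r2, c1:c2] <- TRUE
      flat[which(local & free), , drop = FALSE]
    })
  }
  list(foreground = fg, background = bg)
}

#' Hold-out split of a dataset into training and validation parts
#'
#' Splits at the image level (annotations follow their images) so no image
#' leaks across the split. With `ratio = 0.7` this is the 7:3 hold-out used
#' for small pest datasets.
#'
#' @param dataset A `detection_dataset` with at least two images.
#' @param ratio Fraction of images assigned to the training part.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with elements `train` and `val`, both `detection_dataset`s.
#' @export
holdout_split <- function(dataset, ratio = 0.7, seed = 1L) {
  validate_dataset(dataset)
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie in (0, 1)")
  ids <- dataset$images$id
  if (length(ids) < 2L) stopf("need at least 2 images to split")
  n_train <- round(ratio * length(ids))
  n_train <- clamp(n_train, 1L, length(ids) - 1L)
  train_ids <- with_seed(seed, sample(ids, n_train))
  list(
    train = subset_images(dataset, train_ids),
    val = subset_images(dataset, setdiff(ids, train_ids))
  )
}

# Restrict a dataset to a set of image ids.
subset_images <- function(dataset, image_ids) {
  im <- dataset$images[dataset$images$id %in% image_ids, , drop = FALSE]
  an <- dataset$annotations[dataset$annotations$image_id %in% image_ids, ,
                            drop = FALSE]
  px <- NULL
  if (!is.null(dataset$pixels)) {
    px <- dataset$pixels[as.character(im$id)]
  }
  detection_dataset(im, an, dataset$categories, pixels = px,
                    image_dir = dataset$image_dir)
}

#' Write a dataset's images, masks and annotations to a directory
#'
#' Writes each in-memory image as a PNG, each synthetic object mask as a
#' one-channel PNG (`masks/ann_<id>.png`), and the annotations as
#' `annotations.json` in COCO form.
#'
#' @param dataset A `detection_dataset` with in-memory pixels.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  validate_dataset(dataset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(dataset$images))) {
    id <- dataset$images$id[i]
    img <- get_image(dataset, id)
    png::writePNG(clamp(img / 255, 0, 1),
                  file.path(dir, dataset$images$file_name[i]))
  }
  an <- dataset$annotations
  if (any(!vapply(an$mask, is.null, logical(1)))) {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (i in seq_len(nrow(an))) {
      m <- an$mask[[i]]
      if (!is.null(m)) {
        png::writePNG(m, file.path(dir, "masks",
                                   sprintf("ann_%s.png", an$id[i])))
      }
    }
  }
  write_coco(dataset, file.path(dir, "annotations.json"))
  invisible(dir)
}
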