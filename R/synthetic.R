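#' Gaussian-mixture colour palette
#'
#' Scenes are painted by sampling, per pixel, a mixture component and adding
#' Gaussian texture noise around its mean colour. Separate palettes for
#' background (vegetation-like greens by default) and objects (reddish-brown
#' by default, i.e. a disjoint RGB region) let the generator span the range
#' from conspicuous to fully camouflaged.
#'
#' @param means k x 3 matrix of component mean colours in \[0, 255\].
#' @param sds Length-k vector of per-component standard deviations.
#' @param weights Length-k non-negative mixture weights (normalized to sum 1).
#' @return An object of class `camo_palette`.
#' @export
camo_palette <- function(means, sds = rep(10, nrow(means)),
                         weights = rep(1, nrow(means))) {
  means <- matrix(means, ncol = 3L)
  if (any(means < 0 | means > 255)) stopf("palette means must lie in [0, 255]")
  if (any(weights < 0)) stopf("palette weights must be non-negative")
  if (length(sds) != nrow(means) || length(weights) != nrow(means)) {
    stopf("sds and weights must have one entry per component")
  }
  structure(list(means = means, sds = sds,
                 weights = weights / sum(weights)),
            class = "camo_palette")
}

default_background_palette <- function() {
  camo_palette(
    means = rbind(c(70, 110, 45), c(100, 145, 60), c(55, 90, 50)),
    sds = c(12, 12, 12), weights = c(0.4, 0.35, 0.25))
}

default_object_palette <- function() {
  # Disjoint RGB octant from the vegetation palette: warm reds/oranges.
  camo_palette(
    means = rbind(c(205, 70, 50), c(230, 130, 60)),
    sds = c(12, 12), weights = c(0.6, 0.4))
}

#' Blend an object palette toward a background palette
#'
#' Linear interpolation of the component means toward the background palette
#' (component-wise when the component counts match, otherwise toward the
#' background's weighted mean colour). Standard deviations and weights are
#' kept, so texture survives blending: camouflage here is chromatic
#' similarity, which is exactly what the RGB-histogram distance measures.
#'
#' @param object,background `camo_palette` objects.
#' @param alpha Similarity in \[0, 1\]: 0 keeps the object palette, 1 moves
#'   every object mean onto the background's.
#' @return A `camo_palette`.
#' @export
blend_palette <- function(object, background, alpha) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  k <- nrow(object$means)
  target <- if (nrow(background$means) == k) {
    background$means
  } else {
    matrix(rep(colSums(background$means * background$weights), each = k),
           nrow = k)
  }
  camo_palette((1 - alpha) * object$means + alpha * target,
               sds = object$sds, weights = object$weights)
}

#' Specification of a synthetic camouflage scene
#'
#' @param width,height Image size in pixels.
#' @param n_objects Number of objects to place (>= 0).
#' @param shape `"blob"` (radially perturbed ellipse, mimicking an irregular
#'   insect body) or `"ellipse"`.
#' @param alpha Foreground-background similarity in \[0, 1\] passed to
#'   [blend_palette()].
#' @param noise_sd Additional per-pixel Gaussian noise, intensity units.
#' @param size_range Object diameter range in pixels (major axis).
#' @param background,object Palettes; defaults are vegetation greens and a
#'   disjoint warm-coloured object palette.
#' @param allow_overlap Allow objects to overlap (default FALSE: rejection
#'   sampling with up to 100 placement attempts, then skip with a warning).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 128L, height = 128L, n_objects = 2L,
                       shape = c("blob", "ellipse"), alpha = 0.5,
                       noise_sd = 6, size_range = c(20, 40),
                       background = default_background_palette(),
                       object = default_object_palette(),
                       allow_overlap = FALSE) {
  shape <- match.arg(shape)
  if (n_objects < 0L) stopf("n_objects must be >= 0")
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_objects = as.integer(n_objects), shape = shape, alpha = alpha,
         noise_sd = noise_sd, size_range = size_range,
         background = background, object = object,
         allow_overlap = allow_overlap),
    class = "scene_spec"
  )
}

# Sample n pixels from a palette: mixture component per pixel + noise.
sample_palette_pixels <- function(palette, n, noise_sd = 0) {
  comp <- sample.int(nrow(palette$means), n, replace = TRUE,
                     prob = palette$weights)
  px <- palette$means[comp, , drop = FALSE]
  sd_tot <- sqrt(palette$sds[comp]^2 + noise_sd^2)
  px <- px + matrix(rnorm(3L * n, sd = rep(sd_tot, 3L)), ncol = 3L)
  clamp(px, 0, 255)
}

# Rasterize an object mask: ellipse with optional radial perturbation
# (12 control points, linearly interpolated in angle), rotated by theta.
rasterize_shape <- function(a, b, theta, shape, H, W, cx, cy) {
  ct <- cos(theta); st <- sin(theta)
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
  ys <- matrix(rep(seq_len(H) - 0.5, W), H, W) - cy
  u <- (xs * ct + ys * st) / a
  v <- (-xs * st + ys * ct) / b
  r <- sqrt(u^2 + v^2)
  if (shape == "blob") {
    k <- 12L
    bumps <- 1 + runif(k, -0.25, 0.25)
    ang <- atan2(v, u)  # [-pi, pi]
    pos <- (ang + pi) / (2 * pi) * k  # [0, k]
    i0 <- floor(pos) %% k
    frac <- pos - floor(pos)
    rad <- bumps[i0 + 1L] * (1 - frac) + bumps[(i0 + 1L) %% k + 1L] * frac
    mask <- r <= rad
  } else {
    mask <- r <= 1
  }
  mask
}

#' Compose one synthetic annotated scene
#'
#' Paints a textured background from the background palette, then places
#' `n_objects` shapes coloured from the object palette blended toward the
#' background by `alpha`. Each object's mask is the rasterized shape, its
#' box the mask's tight bounding box. Placement is rejection-sampled to keep
#' objects fully inside the image and (by default) non-overlapping.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; the scene is deterministic given the seed.
#' @return List with `image` (H x W x 3, \[0, 255\]) and `annotations`
#'   (tibble with `id`, `category_id`, `x`, `y`, `w`, `h`, `mask`).
#' @export
compose_scene <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    H <- spec$height; W <- spec$width
    if (max(spec$size_range) > min(H, W)) {
      stopf("object size %g exceeds image size %d", max(spec$size_range),
            min(H, W))
    }
    bg_px <- sample_palette_pixels(spec$background, H * W, spec$noise_sd)
    image <- array(bg_px, dim = c(H, W, 3L))
    obj_pal <- blend_palette(spec$object, spec$background, spec$alpha)
    occupied <- matrix(FALSE, H, W)
    anns <- list()
    for (j in seq_len(spec$n_objects)) {
      placed <- FALSE
      for (attempt in seq_len(100L)) {
        d <- runif(1, spec$size_range[1], spec$size_range[2])
        a <- d / 2
        b <- a * runif(1, 0.45, 0.8)   # elongated, insect-like
        theta <- runif(1, 0, pi)
        margin <- 1.3 * a
        if (2 * margin >= W || 2 * margin >= H) next
        cx <- runif(1, margin, W - margin)
        cy <- runif(1, margin, H - margin)
        mask <- rasterize_shape(a, b, theta, spec$shape, H, W, cx, cy)
        if (!any(mask)) next
        if (!spec$allow_overlap && any(mask & occupied)) next
        idx <- which(mask)
        image[cbind(rep(row(mask)[idx], 3L), rep(col(mask)[idx], 3L),
                    rep(1:3, each = length(idx)))] <-
          sample_palette_pixels(obj_pal, length(idx), spec$noise_sd)
        occupied <- occupied | mask
        rr <- range(row(mask)[idx]); cc <- range(col(mask)[idx])
        anns[[length(anns) + 1L]] <- tibble::tibble(
          id = j, category_id = 1L,
          x = cc[1] - 1, y = rr[1] - 1,
          w = cc[2] - cc[1] + 1, h = rr[2] - rr[1] + 1,
          mask = list(mask * 1))
        placed <- TRUE
        break
      }
      if (!placed) warnf("object %d could not be placed without overlap", j)
    }
    annotations <- if (length(anns)) {
      dplyr::bind_rows(anns)
    } else {
      tibble::tibble(id = integer(), category_id = integer(),
                     x = numeric(), y = numeric(), w = numeric(),
                     h = numeric(), mask = list())
    }
    list(image = image, annotations = annotations)
  })
}

#' Generate a synthetic annotated dataset
#'
#' Composes `n_images` scenes (deterministically given `seed`; per-scene
#' seeds are derived from the master seed) and assembles them into an
#' in-memory [detection_dataset()].
#'
#' @param n_images Number of scenes (>= 1).
#' @param spec A [scene_spec()] shared by all scenes.
#' @param seed Master integer seed.
#' @param alpha Optional per-image similarity override: a vector recycled
#'   over images, allowing mixed-camouflage datasets.
#' @return A `detection_dataset` with in-memory pixels and object masks.
#' @export
#' @examples
#' ds <- generate_dataset(2, scene_spec(width = 48, height = 48,
#'                                      n_objects = 1, size_range = c(10, 16)),
#'                        seed = 7)
#' nrow(ds$images)
generate_dataset <- function(n_images, spec = scene_spec(), seed = 1L,
                             alpha = NULL) {
  if (n_images < 1L) stopf("n_images must be >= 1")
  alphas <- if (is.null(alpha)) rep(spec$alpha, n_images) else
    rep_len(alpha, n_images)
  scene_seeds <- vapply(seq_len(n_images),
                        function(i) derive_seed(seed, paste0("scene", i)),
                        integer(1))
  images <- list(); anns <- list(); pixels <- list()
  next_ann <- 1L
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$alpha <- alphas[i]
    sc <- compose_scene(sp, seed = scene_seeds[i])
    images[[i]] <- tibble::tibble(
      id = i, width = spec$width, height = spec$height,
      file_name = sprintf("scene_%04d.png", i))
    if (nrow(sc$annotations) > 0L) {
      a <- sc$annotations
      a$id <- next_ann - 1L + seq_len(nrow(a))
      a$image_id <- i
      next_ann <- next_ann + nrow(a)
      anns[[length(anns) + 1L]] <- a
    }
    pixels[[as.character(i)]] <- sc$image
  }
  annotations <- if (length(anns)) dplyr::bind_rows(anns) else
    tibble::tibble(id = integer(), image_id = integer(),
                   category_id = integer(), x = numeric(), y = numeric(),
                   w = numeric(), h = numeric(), mask = list())
  detection_dataset(
    dplyr::bind_rows(images), annotations,
    tibble::tibble(id = 1L, name = "camo_object"),
    pixels = pixels)
}
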