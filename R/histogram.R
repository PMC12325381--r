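#' Configuration for Camouflage Degree scoring
#'
#' Bundles the tunable parameters of the Camouflage Degree (CD) computation:
#' the histogram bin count, the chi-squared distance threshold separating
#' camouflaged from conspicuous objects, and how the background region of an
#' object is defined.
#'
#' @param n_bins Number of equal-width histogram bins per colour channel over
#'   the intensity range \[0, 256). Default 32: full 256-bin histograms are
#'   unstable for the small bounding boxes typical of pest imagery.
#' @param threshold Threshold on the three-channel chi-squared distance
#'   `tgc`; objects with `tgc < threshold` count as camouflaged. Default 0.9.
#' @param background_mode Either `"whole_image_minus_boxes"` (the background
#'   is the whole image minus the union of all annotated boxes) or
#'   `"local_surround"` (a box dilated to three times its size, minus all
#'   annotated boxes).
#' @return A list of class `cd_config`.
#' @export
#' @examples
#' cd_config(n_bins = 16)
cd_config <- function(n_bins = 32L,
                      threshold = 0.9,
                      background_mode = c("whole_image_minus_boxes",
                                          "local_surround")) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stopf("n_bins must be an integer >= 2")
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("threshold must be > 0")
  }
  background_mode <- match.arg(background_mode)
  structure(
    list(n_bins = n_bins, threshold = threshold,
         background_mode = background_mode),
    class = "cd_config"
  )
}

#' Per-channel normalized RGB histogram of a pixel region
#'
#' Bins each colour channel of a region into `n_bins` equal-width intervals
#' over \[0, 256) and normalizes the counts to probabilities. These
#' per-channel probability vectors are the h(i) terms entering the
#' chi-squared foreground/background distance.
#'
#' @param pixels Numeric matrix with one row per pixel and three columns
#'   (R, G, B) in \[0, 255\]. A single-channel matrix is replicated to three
#'   channels with a warning (grayscale input).
#' @param n_bins Number of bins per channel (>= 2).
#' @return An object of class `region_histogram`: a list with `channels`
#'   (3 x n_bins matrix of probabilities, rows R/G/B), `n_bins` and
#'   `n_pixels`.
#' @export
#' @examples
#' h <- region_histogram(matrix(c(0, 0, 0), 1, 3), n_bins = 4)
#' rowSums(h$channels)
region_histogram <- function(pixels, n_bins = 32L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stopf("n_bins must be an integer >= 2")
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stopf("empty region")
  if (ncol(pixels) == 1L) {
    warnf("grayscale region: replicating single channel to RGB")
    pixels <- pixels[, c(1L, 1L, 1L), drop = FALSE]
  }
  if (ncol(pixels) != 3L) stopf("pixels must have 3 columns (R, G, B)")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stopf("pixel values must lie in [0, 255]")
  }
  # Equal-width bins with edges i * 256 / n_bins, half-open, last bin closed
  # at 255; floor() with a clamp realizes exactly that.
  idx <- pmin(floor(pixels * (n_bins / 256)), n_bins - 1L) + 1L
  channels <- vapply(
    1:3,
    function(ch) tabulate(idx[, ch], nbins = n_bins) / nrow(pixels),
    numeric(n_bins)
  )
  structure(
    list(channels = t(channels), n_bins = n_bins, n_pixels = nrow(pixels)),
    class = "region_histogram"
  )
}

#' @export
print.region_histogram <- function(x, ...) {
  cat(sprintf("<region_histogram: %d bins x 3 channels, %d pixels>\n",
              x$n_bins, x$n_pixels))
  invisible(x)
}

#' Chi-squared foreground/background histogram distance (Tgc)
#'
#' The per-channel chi-squared distance between two normalized histograms,
#' summed over the three colour channels:
#' sum_i (h1(i) - h2(i))^2 / (h1(i) + h2(i)), with bins where both
#' probabilities are zero contributing nothing. The result lies in \[0, 6\]
#' (each channel's distance is bounded by 2). Smaller values mean more
#' similar foreground and background, i.e. stronger camouflage.
#'
#' @param fg,bg `region_histogram` objects with the same bin count.
#' @return A single non-negative number.
#' @export
#' @examples
#' fg <- region_histogram(matrix(rep(c(10, 200, 30), 5), 5, 3, byrow = TRUE))
#' tgc_distance(fg, fg)
tgc_distance <- function(fg, bg) {
  if (!inherits(fg, "region_histogram") || !inherits(bg, "region_histogram")) {
    stopf("fg and bg must be region_histogram objects")
  }
  if (fg$n_bins != bg$n_bins) {
    stopf("bin counts differ: %d vs %d", fg$n_bins, bg$n_bins)
  }
  h1 <- fg$channels
  h2 <- bg$channels
  denom <- h1 + h2
  num <- (h1 - h2)^2
  keep <- denom > 0
  sum(num[keep] / denom[keep])
}

#' Dataset-level Camouflage Degree from per-object scores
#'
#' Counts objects whose chi-squared distance `tgc` falls below the threshold
#' (camouflaged) against those at or above it (conspicuous) and reports the
#' ratio CD = n_below / n_above. CD around or above 1 marks a camouflaged
#' dataset; conventional detection datasets score well below 1.
#'
#' @param scores A data frame with columns `object_id` and `tgc` (one row per
#'   annotated object).
#' @param threshold Threshold on `tgc` (default 0.9).
#' @return An object of class `cd_report`: list with `scores` (tibble with
#'   added `is_camouflaged`), `n_below`, `n_above`, `cd`, `threshold`.
#' @export
#' @examples
#' s <- tibble::tibble(object_id = 1:4, tgc = c(0.2, 0.5, 1.4, 2.0))
#' compute_cd(s)$cd
compute_cd <- function(scores, threshold = 0.9) {
  new_cd_report(scores, threshold, undefined_ok = FALSE)
}

# Shared constructor; score_dataset tolerates an undefined ratio (every
# object camouflaged) with a warning, compute_cd treats it as an error.
new_cd_report <- function(scores, threshold, undefined_ok) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0L) stopf("scores must be non-empty")
  if (!all(c("object_id", "tgc") %in% names(scores))) {
    stopf("scores needs columns object_id and tgc")
  }
  if (any(scores$tgc < 0)) stopf("tgc values must be non-negative")
  scores <- dplyr::mutate(scores, is_camouflaged = .data$tgc < threshold)
  n_below <- sum(scores$is_camouflaged)
  n_above <- sum(!scores$is_camouflaged)
  if (n_above == 0L) {
    msg <- sprintf(
      "CD undefined: no conspicuous objects (n_below = %d, n_above = 0)",
      n_below)
    if (!undefined_ok) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  structure(
    list(scores = scores, n_below = n_below, n_above = n_above,
         cd = if (n_above > 0L) n_below / n_above else NA_real_,
         threshold = threshold),
    class = "cd_report"
  )
}

#' @export
print.cd_report <- function(x, ...) {
  cat(sprintf(
    "<cd_report: %d objects | %d camouflaged (tgc < %.3g), %d conspicuous | CD = %.4f>\n",
    nrow(x$scores), x$n_below, x$threshold, x$n_above, x$cd))
  invisible(x)
}

#' @rdname compute_cd
#' @param x A `cd_report`.
#' @param ... Unused.
#' @export
tidy.cd_report <- function(x, ...) x$scores

#' @rdname compute_cd
#' @export
glance.cd_report <- function(x, ...) {
  tibble::tibble(
    n_objects = nrow(x$scores), n_below = x$n_below, n_above = x$n_above,
    cd = x$cd, threshold = x$threshold
  )
}

#' @rdname compute_cd
#' @param object A `cd_report`.
#' @export
autoplot.cd_report <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$tgc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = expression(T[gc] ~ "(3-channel " * chi^2 * " distance)"),
      y = "objects",
      title = sprintf("Camouflage Degree = %.2f", object$cd)
    )
}

#' Score every annotated object of a dataset for camouflage
#'
#' For each (non-crowd) annotation, builds normalized RGB histograms of the
#' foreground (bounding-box interior) and of the background region defined by
#' `config$background_mode`, computes the chi-squared distance `tgc`, and
#' aggregates the per-object scores into a Camouflage Degree report. Objects
#' whose background region is empty are skipped with a warning and excluded
#' from the counts.
#'
#' @param dataset A `detection_dataset` (see [read_coco()], [generate_dataset()]).
#' @param config A [cd_config()].
#' @return A `cd_report` whose `scores` tibble has one row per scored object
#'   (`object_id`, `image_id`, `tgc`, `is_camouflaged`).
#' @export
score_dataset <- function(dataset, config = cd_config()) {
  stopifnot(inherits(dataset, "detection_dataset"))
  if (!inherits(config, "cd_config")) stopf("config must be a cd_config")
  anns <- dataset$annotations
  anns <- anns[!anns$iscrowd, , drop = FALSE]
  if (nrow(anns) == 0L) stopf("dataset has no (non-crowd) annotations")
  rows <- list()
  for (img_id in unique(anns$image_id)) {
    img <- get_image(dataset, img_id)
    img_anns <- anns[anns$image_id == img_id, , drop = FALSE]
    regions <- extract_regions(img, img_anns, mode = config$background_mode)
    for (j in seq_len(nrow(img_anns))) {
      bg_px <- regions$background[[j]]
      if (is.null(bg_px) || nrow(bg_px) == 0L) {
        warnf("annotation %s: empty background region, skipped",
              img_anns$id[j])
        next
      }
      fg <- region_histogram(regions$foreground[[j]], config$n_bins)
      bg <- region_histogram(bg_px, config$n_bins)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        object_id = img_anns$id[j],
        image_id = img_id,
        tgc = tgc_distance(fg, bg)
      )
    }
  }
  if (length(rows) == 0L) stopf("no scorable annotations")
  new_cd_report(dplyr::bind_rows(rows), threshold = config$threshold,
                undefined_ok = TRUE)
}
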