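#' Per-level backbone activation heatmaps
#'
#' Channel-mean activation of the selected backbone stages (res3/res4/res5,
#' i.e. strides 8/16/32 of the stand-in backbone), min-max normalized to
#' \[0, 1\] and upsampled to the input image size. A constant input yields a
#' constant (all-zero after normalization) heatmap because the stand-in
#' backbone is bias-free.
#'
#' @param model A `keyfg_model` (or `keyfg_fit`).
#' @param image H x W x 3 array in \[0, 255\].
#' @param layers Character subset of `c("res3", "res4", "res5")`.
#' @param out_dir Optional directory: each heatmap is also written as a PNG
#'   overlay (heatmap blended over the image).
#' @return Named list of H x W matrices in \[0, 1\].
#' @export
export_heatmap <- function(model, image, layers = c("res3", "res4", "res5"),
                           out_dir = NULL) {
  if (inherits(model, "keyfg_fit")) model <- model$model
  strides <- c(res3 = 8L, res4 = 16L, res5 = 32L)
  unknown <- setdiff(layers, names(strides))
  if (length(unknown) > 0L) {
    stopf("unknown layer name(s): %s", paste(unknown, collapse = ", "))
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- list()
  for (layer in layers) {
    stats <- block_stats(image, strides[[layer]])
    act <- apply(stats, c(1, 2), mean)
    rng <- range(act)
    norm <- if (diff(rng) > 0) (act - rng[1]) / diff(rng) else act * 0
    up <- norm[clamp(((seq_len(H) - 1L) %/% strides[[layer]]) + 1L, 1L,
                     nrow(norm)),
               clamp(((seq_len(W) - 1L) %/% strides[[layer]]) + 1L, 1L,
                     ncol(norm)), drop = FALSE]
    out[[layer]] <- up
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      overlay <- image / 255 * 0.5
      overlay[, , 1] <- clamp(overlay[, , 1] + 0.5 * up, 0, 1)
      png::writePNG(overlay, file.path(out_dir,
                                       sprintf("heatmap_%s.png", layer)))
    }
  }
  out
}

#' Plot a heatmap matrix
#'
#' @param heatmap H x W matrix in \[0, 1\] from [export_heatmap()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(heatmap) {
  df <- tidyr::expand_grid(y = seq_len(nrow(heatmap)),
                           x = seq_len(ncol(heatmap)))
  df$value <- as.vector(t(heatmap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "activation")
}
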