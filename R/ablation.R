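#' Progressive ablation over the four architectural additions
#'
#' Trains and evaluates the desk-scale detector under the standard
#' progressive flag grid — baseline, +MaskMLP, +denoising, +DropKey, +FGSP —
#' with a shared seed, mirroring how the contribution of each module is
#' usually reported. At desk scale only the direction of the trend is
#' meaningful, not any full-scale margin.
#'
#' @param dataset Training dataset (in-memory pixels).
#' @param epochs Epochs per configuration.
#' @param seed Shared seed.
#' @param eval_dataset Dataset to evaluate on (defaults to `dataset`,
#'   i.e. the overfit regime appropriate for smoke runs).
#' @param out_csv Optional path: results are also written as CSV.
#' @param image_size Passed to [train_config()].
#' @param experiments Subset of `c("EXP_A", ..., "EXP_E")` to run
#'   (default: all five).
#' @param ... Further arguments to [train_config()].
#' @return A tibble with one row per configuration: `experiment`, the four
#'   flags, and the metrics from [evaluate_detections()].
#' @export
ablation_run <- function(dataset, epochs = 20L, seed = 1L,
                         eval_dataset = dataset, out_csv = NULL,
                         image_size = 128L,
                         experiments = paste0("EXP_", LETTERS[1:5]), ...) {
  grid <- tibble::tribble(
    ~experiment, ~maskmlp, ~dn, ~dropkey, ~fgsp,
    "EXP_A", FALSE, FALSE, FALSE, FALSE,
    "EXP_B", TRUE, FALSE, FALSE, FALSE,
    "EXP_C", TRUE, TRUE, FALSE, FALSE,
    "EXP_D", TRUE, TRUE, TRUE, FALSE,
    "EXP_E", TRUE, TRUE, TRUE, TRUE)
  grid <- grid[grid$experiment %in% experiments, , drop = FALSE]
  rows <- purrr::pmap(grid, function(experiment, maskmlp, dn, dropkey,
                                     fgsp) {
    cfg <- train_config(epochs = epochs, seed = seed, maskmlp = maskmlp,
                        dn = dn, dropkey = dropkey, fgsp = fgsp,
                        image_size = image_size, ...)
    fit <- train_detector(dataset, cfg)
    met <- evaluate_detections(predict(fit, eval_dataset), eval_dataset)
    dplyr::bind_cols(
      tibble::tibble(experiment = experiment, maskmlp = maskmlp, dn = dn,
                     dropkey = dropkey, fgsp = fgsp),
      tibble::as_tibble(met))
  })
  res <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}
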