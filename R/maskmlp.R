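# Dual-branch soft-mask module: a spatial branch pools features over
# channels and maps the pooled H*W vector to H*W spatial logits; a channel
# branch pools over space and maps the pooled C vector to C channel logits.
# The two are fused by outer product and a sigmoid, giving a soft mask in
# (0, 1) per (location, channel) that multiplies the features, down-weighting
# occluded or background positions and uninformative channels.

#' Initialize soft-mask module parameters
#'
#' @param h,w,c Feature-map dimensions the module operates on.
#' @param hidden Hidden width of the two branch MLPs.
#' @param seed Integer seed for initialization.
#' @return Parameter list of class `maskmlp_params`.
#' @export
maskmlp_init <- function(h, w, c, hidden = 16L, seed = 1L) {
  structure(
    list(h = h, w = w, c = c,
         spatial = mlp_init(c(h * w, hidden, h * w),
                            seed = derive_seed(seed, "maskmlp_s")),
         channel = mlp_init(c(c, hidden, c),
                            seed = derive_seed(seed, "maskmlp_c"))),
    class = "maskmlp_params")
}

#' Compute the fused soft mask of a feature map
#'
#' @param feature H x W x C array.
#' @param params A [maskmlp_init()] parameter set matching the dimensions.
#' @return An object of class `soft_mask`: list with `spatial_logits`
#'   (H x W), `channel_logits` (C), `mask` (H x W x C array, all values
#'   strictly in (0, 1)), and a `cache` used for backpropagation.
#' @export
maskmlp_mask <- function(feature, params) {
  dm <- dim(feature)
  if (dm[1] != params$h || dm[2] != params$w || dm[3] != params$c) {
    stopf("feature dims (%d,%d,%d) do not match module (%d,%d,%d)",
          dm[1], dm[2], dm[3], params$h, params$w, params$c)
  }
  flat <- matrix(feature, ncol = dm[3])
  s_pool <- matrix(rowMeans(flat), 1L)   # pooled over channels
  c_pool <- matrix(colMeans(flat), 1L)   # pooled over space
  fs <- mlp_forward(params$spatial, s_pool)
  fc <- mlp_forward(params$channel, c_pool)
  ws <- matrix(fs$out, dm[1], dm[2])
  wc <- as.vector(fc$out)
  fused_logit <- outer(as.vector(ws), wc)              # (H*W) x C
  mask <- array(sigmoid(fused_logit), dim = dm)
  structure(
    list(spatial_logits = ws, channel_logits = wc, mask = mask,
         cache = list(fs = fs, fc = fc, fused_logit = fused_logit)),
    class = "soft_mask")
}

#' @rdname maskmlp_mask
#' @param mask A `soft_mask`.
#' @export
apply_soft_mask <- function(feature, mask) {
  feature * mask$mask
}

# BCE supervision of the fused mask against a ground-truth H x W mask
# (broadcast across channels). Returns the loss value and parameter
# gradients for both branches.
maskmlp_loss_grad <- function(params, soft_mask, gt_mask) {
  dm <- dim(soft_mask$mask)
  target <- array(rep(as.vector(gt_mask), dm[3]), dim = dm)
  bce <- bce_loss(as.vector(soft_mask$mask), as.vector(target))
  # d mask / d logit = mask * (1 - mask)
  dlogit <- matrix(bce$grad * as.vector(soft_mask$mask) *
                     (1 - as.vector(soft_mask$mask)),
                   dm[1] * dm[2], dm[3])
  # fused_logit = outer(ws, wc): d/dws = dlogit %*% wc ; d/dwc = t(dlogit) %*% ws
  d_ws <- dlogit %*% soft_mask$channel_logits
  d_wc <- crossprod(dlogit, as.vector(soft_mask$spatial_logits))
  gs <- mlp_backward(params$spatial, soft_mask$cache$fs$cache, t(d_ws))
  gc <- mlp_backward(params$channel, soft_mask$cache$fc$cache, t(d_wc))
  list(value = bce$value,
       grads = list(spatial = gs[c("W", "b")], channel = gc[c("W", "b")]))
}
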