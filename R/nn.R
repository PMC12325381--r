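# Minimal dense-network machinery for the trainable parts of the desk-scale
# detector (prediction heads and the soft-mask module). Forward passes cache
# activations; backward passes return analytic gradients, which the test
# suite checks against numerical differentiation.

mlp_init <- function(sizes, seed = 1L, act = "relu") {
  with_seed(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      s <- sqrt(2 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = s),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b, act = act, sizes = sizes)
  })
}

# X: n x d_in. Returns list(out = n x d_out, cache).
mlp_forward <- function(p, X) {
  X <- as.matrix(X)
  L <- length(p$W)
  hs <- vector("list", L + 1L)
  hs[[1L]] <- X
  for (l in seq_len(L)) {
    z <- hs[[l]] %*% p$W[[l]] + matrix(p$b[[l]], nrow(X), length(p$b[[l]]),
                                       byrow = TRUE)
    hs[[l + 1L]] <- if (l < L && p$act == "relu") pmax(z, 0) else z
  }
  list(out = hs[[L + 1L]], cache = hs)
}

# dOut: n x d_out gradient of the loss wrt the output.
mlp_backward <- function(p, cache, dOut) {
  L <- length(p$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  d <- as.matrix(dOut)
  for (l in rev(seq_len(L))) {
    if (l < L && p$act == "relu") d <- d * (cache[[l + 1L]] > 0)
    gW[[l]] <- crossprod(cache[[l]], d)
    gb[[l]] <- colSums(d)
    d <- d %*% t(p$W[[l]])
  }
  list(W = gW, b = gb, dX = d)
}

# Flatten/unflatten parameter lists so one Adam state covers all heads.
flatten_params <- function(p) {
  unlist(c(lapply(p$W, as.vector), lapply(p$b, as.vector)))
}

unflatten_params <- function(p, v) {
  off <- 0L
  for (l in seq_along(p$W)) {
    n <- length(p$W[[l]])
    p$W[[l]][] <- v[off + seq_len(n)]
    off <- off + n
  }
  for (l in seq_along(p$b)) {
    n <- length(p$b[[l]])
    p$b[[l]][] <- v[off + seq_len(n)]
    off <- off + n
  }
  p
}

adam_init <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  if (weight_decay > 0) grad <- grad + weight_decay * theta
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Sigmoid focal loss (alpha-balanced), summed; returns value and d/dlogits.
focal_loss <- function(logits, targets, alpha = 0.25, gamma = 2,
                       reduce = TRUE) {
  p <- sigmoid(logits)
  pt <- ifelse(targets == 1, p, 1 - p)
  at <- ifelse(targets == 1, alpha, 1 - alpha)
  eps <- 1e-12
  loss <- -at * (1 - pt)^gamma * log(pmax(pt, eps))
  # d loss / d logit, with dp/dlogit = p(1-p), dpt/dlogit = +-p(1-p)
  sgn <- ifelse(targets == 1, 1, -1)
  dpt <- at * (gamma * (1 - pt)^(gamma - 1) * log(pmax(pt, eps)) -
                 (1 - pt)^gamma / pmax(pt, eps))
  dlogit <- dpt * sgn * p * (1 - p)
  if (reduce) list(value = sum(loss), grad = dlogit)
  else list(value = loss, grad = dlogit)
}

# Binary cross-entropy on probabilities in (0,1); returns value (mean) and
# gradient wrt the probabilities.
bce_loss <- function(prob, target) {
  eps <- 1e-9
  p <- clamp(prob, eps, 1 - eps)
  n <- length(p)
  list(value = -mean(target * log(p) + (1 - target) * log(1 - p)),
       grad = (-(target / p) + (1 - target) / (1 - p)) / n)
}
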