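# Independent reference implementations used to cross-check the package's
# vectorized code, plus small fixture builders.

# Scalar bilinear interpolation with zero padding, written as the textbook
# four-corner sum.
oracle_bilinear <- function(level, x, y) {
  H <- dim(level)[1]; W <- dim(level)[2]; C <- dim(level)[3]
  out <- rep(0, C)
  x0 <- floor(x); y0 <- floor(y)
  for (dx in 0:1) {
    for (dy in 0:1) {
      cx <- x0 + dx; cy <- y0 + dy
      wx <- if (dx == 0) 1 - (x - x0) else x - x0
      wy <- if (dy == 0) 1 - (y - y0) else y - y0
      if (cx >= 1 && cx <= W && cy >= 1 && cy <= H && wx * wy > 0) {
        out <- out + level[cy, cx, ] * wx * wy
      }
    }
  }
  out
}

# Dense loop over heads, levels, points and queries — the brute-force
# counterpart of ms_deform_attn().
oracle_ms_deform_attn <- function(pyramid, reference, offsets, weights,
                                  value_proj, output_proj) {
  Q <- nrow(reference); C <- dim(pyramid[[1]])[3]
  M <- dim(weights)[1]; L <- dim(weights)[2]; K <- dim(weights)[4]
  out <- matrix(0, Q, C)
  for (q in seq_len(Q)) {
    for (m in seq_len(M)) {
      acc <- rep(0, ncol(value_proj[[m]]))
      for (l in seq_len(L)) {
        H <- dim(pyramid[[l]])[1]; W <- dim(pyramid[[l]])[2]
        for (k in seq_len(K)) {
          sx <- reference[q, 1] * W + 0.5 + offsets[m, l, q, k, 1]
          sy <- reference[q, 2] * H + 0.5 + offsets[m, l, q, k, 2]
          samp <- oracle_bilinear(pyramid[[l]], sx, sy)
          acc <- acc + weights[m, l, q, k] *
            as.vector(samp %*% value_proj[[m]])
        }
      }
      out[q, ] <- out[q, ] + as.vector(acc %*% output_proj[[m]])
    }
  }
  out
}

# Random deformable-attention instance at a given size.
random_msda_instance <- function(C = 4L, M = 2L, L = 2L, K = 2L, Q = 3L) {
  pyramid <- list(array(rnorm(4 * 4 * C), c(4, 4, C)),
                  array(rnorm(2 * 2 * C), c(2, 2, C)))[seq_len(L)]
  reference <- matrix(runif(Q * 2), Q)
  offsets <- array(rnorm(M * L * Q * K * 2), c(M, L, Q, K, 2))
  weights <- array(runif(M * L * Q * K), c(M, L, Q, K))
  for (m in seq_len(M)) {
    for (q in seq_len(Q)) {
      weights[m, , q, ] <- weights[m, , q, ] / sum(weights[m, , q, ])
    }
  }
  ch <- max(1L, C %/% M)
  list(pyramid = pyramid, reference = reference, offsets = offsets,
       weights = weights,
       value_proj = lapply(seq_len(M), function(m)
         matrix(rnorm(C * ch), C, ch)),
       output_proj = lapply(seq_len(M), function(m)
         matrix(rnorm(ch * C), ch, C)))
}

# Exhaustive minimum assignment cost by recursion over injections.
oracle_min_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  rec <- function(j, used, acc) {
    if (acc >= best) return()
    if (j > m) {
      best <<- min(best, acc)
      return()
    }
    for (i in setdiff(seq_len(n), used)) rec(j + 1L, c(used, i),
                                             acc + cost[i, j])
  }
  rec(1L, integer(0), 0)
  best
}

# Central-difference numerical gradient of f at x.
numerical_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# A tiny two-image in-memory dataset with hand-placed solid-colour boxes.
tiny_dataset <- function() {
  mk <- function(bg, boxes) {
    img <- array(0, c(40, 40, 3))
    for (k in 1:3) img[, , k] <- bg[k]
    for (b in boxes) {
      img[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w), 1] <- b$col[1]
      img[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w), 2] <- b$col[2]
      img[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w), 3] <- b$col[3]
    }
    img
  }
  b1 <- list(x = 4, y = 6, w = 10, h = 8, col = c(200, 40, 30))
  b2 <- list(x = 22, y = 20, w = 8, h = 10, col = c(220, 120, 40))
  b3 <- list(x = 10, y = 24, w = 9, h = 7, col = c(180, 60, 60))
  detection_dataset(
    images = tibble::tibble(id = 1:2, width = 40, height = 40,
                            file_name = c("a.png", "b.png")),
    annotations = tibble::tibble(
      id = 1:3, image_id = c(1L, 1L, 2L), category_id = 1L,
      x = c(b1$x, b2$x, b3$x), y = c(b1$y, b2$y, b3$y),
      w = c(b1$w, b2$w, b3$w), h = c(b1$h, b2$h, b3$h)),
    categories = tibble::tibble(id = 1L, name = "pest"),
    pixels = list(`1` = mk(c(60, 110, 50), list(b1, b2)),
                  `2` = mk(c(60, 110, 50), list(b3))))
}

# Desk-scale synthetic training set shared by the heavier tests.
overfit_dataset <- function(n_images = 5L, seed = 21L) {
  generate_dataset(
    n_images,
    scene_spec(width = 128, height = 128, n_objects = 2, alpha = 0.5,
               size_range = c(20, 40)),
    seed = seed)
}
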