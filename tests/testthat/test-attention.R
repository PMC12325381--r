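test_that("deformable attention collapses correctly in degenerate settings", {
  # single pixel, single head/level/point, identity projections
  v <- c(3.5, -1.25)
  pyramid <- list(array(rep(v, each = 1), c(1, 1, 2)))
  offsets <- array(0, c(1, 1, 1, 1, 2))
  weights <- array(1, c(1, 1, 1, 1))
  out <- ms_deform_attn(pyramid, matrix(c(0.5, 0.5), 1), offsets, weights)
  expect_equal(as.vector(out), v)

  # constant maps: any normalized weights give the constant (convexity)
  pyr <- list(array(2.5, c(4, 4, 3)), array(2.5, c(2, 2, 3)))
  w <- array(runif(2 * 2 * 1 * 2), c(2, 2, 1, 2))
  for (m in 1:2) w[m, , 1, ] <- w[m, , 1, ] / sum(w[m, , 1, ])
  off <- array(runif(2 * 2 * 1 * 2 * 2, -0.4, 0.4), c(2, 2, 1, 2, 2))
  out2 <- ms_deform_attn(pyr, matrix(c(0.5, 0.5), 1), off, w)
  expect_equal(as.vector(out2), rep(2 * 2.5, 3))  # two heads, identity proj
})

test_that("deformable attention rejects invalid weights and offsets", {
  pyr <- list(array(1, c(2, 2, 2)))
  off <- array(0, c(1, 1, 1, 1, 2))
  w_bad <- array(0.5, c(1, 1, 1, 1))
  expect_error(ms_deform_attn(pyr, matrix(c(0.5, 0.5), 1), off, w_bad),
               "sum to 1")
  off_bad <- off; off_bad[1, 1, 1, 1, 1] <- NaN
  expect_error(ms_deform_attn(pyr, matrix(c(0.5, 0.5), 1), off_bad,
                              array(1, c(1, 1, 1, 1))), "non-finite")
})

test_that("deformable attention matches the dense brute-force oracle", {
  set.seed(29)
  for (i in 1:30) {
    inst <- random_msda_instance(C = 4, M = sample(1:2, 1),
                                 L = sample(1:2, 1), K = sample(1:3, 1),
                                 Q = sample(1:4, 1))
    fast <- ms_deform_attn(inst$pyramid, inst$reference, inst$offsets,
                           inst$weights, inst$value_proj, inst$output_proj)
    slow <- oracle_ms_deform_attn(inst$pyramid, inst$reference,
                                  inst$offsets, inst$weights,
                                  inst$value_proj, inst$output_proj)
    expect_lt(max(abs(fast - slow)), 1e-5)
  }
})

test_that("samples outside a feature map contribute zero", {
  pyr <- list(array(7, c(2, 2, 1)))
  off <- array(100, c(1, 1, 1, 1, 2))  # far outside
  out <- ms_deform_attn(pyr, matrix(c(0.5, 0.5), 1), off,
                        array(1, c(1, 1, 1, 1)))
  expect_equal(as.vector(out), 0)
})

test_that("DropKey at ratio zero equals standard attention", {
  set.seed(5)
  Q <- matrix(rnorm(12), 3); K <- matrix(rnorm(16), 4)
  V <- matrix(rnorm(8), 4)
  a <- dropkey_attention(Q, K, V, drop_ratio = 0, training = TRUE)
  logits <- Q %*% t(K) / sqrt(ncol(Q))
  ref <- t(apply(logits, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(a$weights, ref, tolerance = 1e-12)
  expect_equal(a$output, ref %*% V)
  # inference never drops regardless of ratio
  b <- dropkey_attention(Q, K, V, drop_ratio = 0.9, training = FALSE)
  expect_equal(b$weights, ref, tolerance = 1e-12)
})

test_that("DropKey rows stay convex and masks block attention", {
  set.seed(6)
  Q <- matrix(rnorm(40), 10); K <- matrix(rnorm(48), 12)
  V <- matrix(rnorm(24), 12)
  a <- dropkey_attention(Q, K, V, drop_ratio = 0.3, training = TRUE)
  expect_equal(rowSums(a$weights), rep(1, 10), tolerance = 1e-6)
  expect_true(all(a$weights >= 0))
  mask <- matrix(FALSE, 10, 12); mask[, 1:6] <- TRUE
  b <- dropkey_attention(Q, K, V, drop_ratio = 0, training = TRUE,
                         attn_mask = mask)
  expect_true(all(b$weights[, 1:6] == 0))
  expect_equal(rowSums(b$weights), rep(1, 10), tolerance = 1e-6)
})

test_that("rows that lose every key fall back to undropped attention", {
  set.seed(8)
  Q <- matrix(rnorm(40), 20); K <- matrix(rnorm(2), 1)
  V <- matrix(rnorm(2), 1)
  # with a single key and high ratio, many rows lose all keys
  expect_message(
    a <- dropkey_attention(Q, K, V, drop_ratio = 0.9, training = TRUE),
    "falling back")
  expect_equal(rowSums(a$weights), rep(1, 20), tolerance = 1e-6)
})

test_that("the empirical DropKey rate matches the requested ratio", {
  set.seed(9)
  n <- 300; k <- 40  # 12000 logits per call
  drops <- replicate(9, {
    Q <- matrix(rnorm(n * 4), n); K <- matrix(rnorm(k * 4), k)
    V <- matrix(rnorm(k), k)
    a <- dropkey_attention(Q, K, V, drop_ratio = 0.1, training = TRUE)
    mean(a$weights == 0)
  })
  expect_lt(abs(mean(drops) - 0.1), 0.005)
})
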