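test_that("loss breakdown weights and sums its five components", {
  comp <- c(match = 0.2, dn = 0.3, mask = 0.1, fg = 0.25, enc = 0.15)
  lb <- loss_breakdown(comp, loss_weights())
  expect_equal(attr(lb, "total"), 1)
  expect_equal(attr(loss_breakdown(comp, loss_weights(0, 0, 0, 0, 0)),
                    "total"), 0)
  only_match <- loss_breakdown(comp, loss_weights(1, 0, 0, 0, 0))
  expect_equal(attr(only_match, "total"), comp[["match"]])
  expect_error(loss_weights(match = -1), "non-negative")
  g <- glance(lb)
  expect_equal(g$total, 1)
  expect_equal(g$dn, 0.3)
})

test_that("composite_loss treats missing components as zero", {
  lb <- composite_loss(list(match = 0.5, fg = 0.25))
  expect_equal(attr(lb, "total"), 0.75)
})

test_that("focal loss gradient matches numerical differentiation", {
  set.seed(2)
  logits <- matrix(rnorm(12), 4)
  targets <- matrix(sample(0:1, 12, replace = TRUE), 4)
  fl <- camodet:::focal_loss(logits, targets)
  num <- numerical_grad(function(x)
    camodet:::focal_loss(matrix(x, 4), targets)$value, as.vector(logits))
  expect_equal(as.vector(fl$grad), num, tolerance = 1e-5)
})

test_that("the matched set loss and its gradients are consistent", {
  set.seed(3)
  n <- 6; K <- 2
  logits <- matrix(rnorm(n * K), n)
  boxes <- cbind(runif(n, 0.2, 0.8), runif(n, 0.2, 0.8),
                 runif(n, 0.1, 0.3), runif(n, 0.1, 0.3))
  gt <- rbind(c(0.4, 0.4, 0.2, 0.2), c(0.7, 0.6, 0.15, 0.25))
  labels <- c(1L, 2L)
  idx <- c(2L, 5L)
  sl <- camodet:::set_loss_grad(logits, boxes, gt, labels, idx)
  # gradient wrt logits
  num_l <- numerical_grad(function(x)
    camodet:::set_loss_grad(matrix(x, n), boxes, gt, labels, idx)$value,
    as.vector(logits))
  expect_equal(as.vector(sl$g_logits), num_l, tolerance = 1e-5)
  # gradient wrt boxes
  num_b <- numerical_grad(function(x)
    camodet:::set_loss_grad(logits, matrix(x, n), gt, labels, idx)$value,
    as.vector(boxes))
  expect_equal(as.vector(sl$g_boxes), num_b, tolerance = 1e-4)
  # with no ground truth the loss reduces to all-negative focal
  sl0 <- camodet:::set_loss_grad(logits, boxes, matrix(numeric(0), 0, 4),
                                 integer(0), integer(0))
  expect_equal(sl0$value, camodet:::focal_loss(logits, matrix(0, n, K))$value)
})

test_that("MLP backpropagation matches numerical gradients", {
  set.seed(5)
  p <- camodet:::mlp_init(c(3, 7, 2), seed = 11)
  X <- matrix(rnorm(12), 4)
  target <- matrix(rnorm(8), 4)
  loss_at <- function(theta) {
    q <- camodet:::unflatten_params(p, theta)
    sum((camodet:::mlp_forward(q, X)$out - target)^2)
  }
  fwd <- camodet:::mlp_forward(p, X)
  bk <- camodet:::mlp_backward(p, fwd$cache, 2 * (fwd$out - target))
  ana <- camodet:::flatten_grads(bk)
  num <- numerical_grad(loss_at, camodet:::flatten_params(p))
  expect_equal(ana, num, tolerance = 1e-5)
})
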