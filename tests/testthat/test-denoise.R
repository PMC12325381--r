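test_that("zero noise and zero flips reproduce the ground truth", {
  gt <- rbind(c(0.3, 0.4, 0.2, 0.1), c(0.7, 0.6, 0.15, 0.2))
  dn <- build_denoising_queries(gt, c(1L, 2L), n_classes = 3,
                                n_matching = 10, n_groups = 4,
                                box_noise_scale = 0, label_flip_prob = 0,
                                seed = 1)
  expect_equal(dn$n_dn, 8)
  expect_equal(dn$boxes, gt[dn$gt_index, ])
  expect_equal(dn$labels, c(1L, 2L)[dn$gt_index])
})

test_that("the attention mask isolates matching queries and groups", {
  gt <- rbind(c(0.3, 0.4, 0.2, 0.1), c(0.7, 0.6, 0.15, 0.2))
  dn <- build_denoising_queries(gt, c(1L, 1L), n_classes = 2,
                                n_matching = 5, n_groups = 3, seed = 2)
  m <- dn$attn_mask
  n_dn <- dn$n_dn
  # every matching-query -> denoising-query entry blocked
  expect_true(all(m[n_dn + seq_len(5), seq_len(n_dn)]))
  # matching queries see each other
  expect_false(any(m[n_dn + seq_len(5), n_dn + seq_len(5)]))
  # cross-group blocked, within-group open
  for (g in seq_len(3)) {
    own <- which(dn$group == g)
    other <- which(dn$group != g)
    expect_false(any(m[own, own]))
    expect_true(all(m[own, other]))
  }
})

test_that("noised boxes stay in the unit square and sizes stay bounded", {
  set.seed(3)
  gt <- cbind(runif(5, 0.1, 0.9), runif(5, 0.1, 0.9),
              runif(5, 0.1, 0.4), runif(5, 0.1, 0.4))
  dn <- build_denoising_queries(gt, rep(1L, 5), n_classes = 1,
                                n_matching = 10, n_groups = 5,
                                box_noise_scale = 0.4, seed = 4)
  xy <- box_cxcywh_to_xyxy(dn$boxes)
  expect_true(all(xy >= -1e-9 & xy <= 1 + 1e-9))
  base <- gt[dn$gt_index, ]
  expect_true(all(dn$boxes[, 3] <= base[, 3] * 1.4 + 1e-9))
})

test_that("label flips hit the requested rate and never keep the class", {
  gt <- matrix(rep(c(0.5, 0.5, 0.2, 0.2), 50), ncol = 4, byrow = TRUE)
  labels <- rep(1L, 50)
  dn <- build_denoising_queries(gt, labels, n_classes = 4, n_matching = 0,
                                n_groups = 40, box_noise_scale = 0,
                                label_flip_prob = 0.5, seed = 5)
  flipped <- dn$labels != labels[dn$gt_index]
  expect_equal(mean(flipped), 0.5, tolerance = 0.05)
  expect_true(all(dn$labels[flipped] != 1L))
})

test_that("zero ground truths give an empty denoising part", {
  dn <- build_denoising_queries(matrix(numeric(0), 0, 4), integer(0),
                                n_classes = 2, n_matching = 6)
  expect_equal(dn$n_dn, 0)
  expect_equal(dim(dn$attn_mask), c(6, 6))
  expect_false(any(dn$attn_mask))
})
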