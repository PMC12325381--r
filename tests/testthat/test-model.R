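test_that("the backbone shape chain reproduces the stride arithmetic", {
  s <- backbone_stage_shapes(1333, 800)
  expect_equal(s$height, c(667, 334, 334, 167, 84, 42))
  expect_equal(s$width, c(400, 200, 200, 100, 50, 25))
  expect_equal(s$channels, c(64, 64, 256, 512, 1024, 2048))
  s224 <- backbone_stage_shapes(224, 224)
  expect_equal(s224$height[6], 7)
  expect_equal(s224$width[6], 7)
  s32 <- backbone_stage_shapes(32, 32)
  expect_equal(s32$height[6], 1)
  expect_error(backbone_stage_shapes(16, 100), "at least 32x32")
})

test_that("fine-grained scores multiply class and foreground probabilities", {
  logit <- function(p) log(p / (1 - p))
  sc <- fgsp_scores(matrix(logit(c(1 - 1e-12, 0.8)), 2, 1),
                    c(logit(1 - 1e-12), logit(0.5)))
  expect_equal(sc$score[1], 1, tolerance = 1e-9)
  expect_equal(sc$score[2], 0.4, tolerance = 1e-9)
  # confident-but-background tokens rank below balanced foreground tokens
  sc2 <- fgsp_scores(matrix(logit(c(0.9, 0.99)), 2, 1),
                     c(logit(0.9), logit(0.1)))
  expect_equal(sc2$score, c(0.81, 0.099), tolerance = 1e-9)
  expect_gt(sc2$score[1], sc2$score[2])
  expect_true(all(sc2$score <= pmin(sc2$class_prob, sc2$fg_prob)))
})

test_that("token selection keeps the top fraction with stable ties", {
  sc <- tibble::tibble(score = rep(0.5, 10))
  expect_equal(select_foreground_tokens(sc, 0.3), 1:3)
  expect_equal(select_foreground_tokens(sc, 1), 1:10)
  sc2 <- tibble::tibble(score = c(0.1, 0.9, 0.2, 0.8, 0.05, 0.3, 0.25,
                                  0.15, 0.02, 0.6))
  expect_equal(select_foreground_tokens(sc2, 0.3), sort(c(2L, 4L, 10L)))
  expect_error(select_foreground_tokens(sc2, 0), "keep_ratio")
  expect_error(select_foreground_tokens(sc2[0, ], 0.5), "empty")
})

test_that("the baseline configuration strips every added module", {
  ds <- overfit_dataset(1)
  img <- get_image(ds, 1)
  anns <- ds$annotations[ds$annotations$image_id == 1, ]
  base_cfg <- keyfg_config(maskmlp = FALSE, dn = FALSE, dropkey = FALSE,
                           fgsp = FALSE)
  model <- keyfg_model(base_cfg, n_classes = 1, seed = 4)
  fwd_train <- keyfg_forward(model, img, annotations = anns,
                             training = TRUE)
  fwd_eval <- keyfg_forward(model, img, annotations = anns,
                            training = FALSE)
  # no soft mask, no denoising queries
  expect_null(fwd_train$soft_mask)
  expect_equal(fwd_train$n_dn, 0)
  # with DropKey off and no denoising noise, training and inference forward
  # passes coincide: a plain deformable-DETR-style pass
  expect_equal(fwd_train$query_boxes, fwd_eval$query_boxes)
  expect_equal(fwd_train$query_logits, fwd_eval$query_logits)
  # selection falls back to the class probability alone
  rank_eval <- order(-fwd_eval$scores$class_prob,
                     seq_along(fwd_eval$scores$class_prob))
  expect_setequal(fwd_eval$selected,
                  rank_eval[seq_along(fwd_eval$selected)])
})

test_that("the full model produces masks, denoising queries and scores", {
  ds <- overfit_dataset(1)
  img <- get_image(ds, 1)
  anns <- ds$annotations[ds$annotations$image_id == 1, ]
  model <- keyfg_model(keyfg_config(), n_classes = 1, seed = 4)
  set.seed(1)
  fwd <- keyfg_forward(model, img, annotations = anns, training = TRUE)
  expect_s3_class(fwd$soft_mask, "soft_mask")
  expect_true(all(fwd$soft_mask$mask > 0 & fwd$soft_mask$mask < 1))
  expect_equal(fwd$n_dn, 3 * nrow(anns))
  expect_equal(nrow(fwd$query_boxes), 20)
  # boxes are normalized cxcywh
  expect_true(all(fwd$query_boxes[, 3:4] > 0 & fwd$query_boxes[, 3:4] <= 1))
})

test_that("one gradient step on a single image strictly decreases the loss", {
  ds <- overfit_dataset(1)
  img <- get_image(ds, 1)
  anns <- ds$annotations[ds$annotations$image_id == 1, ]
  # deterministic sub-model so the loss is comparable across evaluations
  cfg <- keyfg_config(dn = FALSE, dropkey = FALSE)
  model <- keyfg_model(cfg, n_classes = 1, seed = 8)
  enc <- camodet:::keyfg_encode(model, img)
  loss_of <- function(m) {
    fwd <- camodet:::keyfg_head_forward(m, enc, annotations = anns,
                                        training = TRUE)
    camodet:::image_loss_grads(m, fwd)
  }
  before <- loss_of(model)
  theta <- camodet:::get_model_params(model)
  model2 <- camodet:::set_model_params(model,
                                       theta - 1e-4 * sign(before$grad))
  after <- loss_of(model2)
  expect_lt(after$total, before$total)
})

test_that("constant images yield constant heatmaps at every level", {
  model <- keyfg_model(keyfg_config(), n_classes = 1, seed = 2)
  img <- array(117, c(128, 128, 3))
  hm <- export_heatmap(model, img)
  expect_named(hm, c("res3", "res4", "res5"))
  for (h in hm) {
    expect_equal(dim(h), c(128, 128))
    expect_true(all(h >= 0 & h <= 1))
    expect_equal(max(h) - min(h), 0)
  }
  ds <- overfit_dataset(1)
  hm2 <- export_heatmap(model, get_image(ds, 1), layers = "res4")
  expect_equal(dim(hm2$res4), c(128, 128))
  expect_true(max(hm2$res4) - min(hm2$res4) > 0)
  expect_error(export_heatmap(model, img, layers = "res9"),
               "unknown layer")
})
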