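test_that("identity copy-paste reproduces the source patch under its mask", {
  ds <- tiny_dataset()
  src <- list(image = get_image(ds, 1),
              annotations = ds$annotations[ds$annotations$image_id == 1, ])
  dst <- list(image = get_image(ds, 2),
              annotations = ds$annotations[ds$annotations$image_id == 2, ])
  out <- copy_paste_augment(src, dst, rotation_range = c(0, 0),
                            scale_range = c(1, 1), seed = 42)
  expect_equal(nrow(out$annotations), nrow(dst$annotations) + 1)
  new_ann <- out$annotations[nrow(out$annotations), ]
  # the pasted region is pixel-identical to one of the source boxes
  crop <- out$image[(new_ann$y + 1):(new_ann$y + new_ann$h),
                    (new_ann$x + 1):(new_ann$x + new_ann$w), , drop = FALSE]
  src_anns <- src$annotations
  matches <- vapply(seq_len(nrow(src_anns)), function(i) {
    a <- src_anns[i, ]
    if (a$w != new_ann$w || a$h != new_ann$h) return(FALSE)
    ref <- src$image[(a$y + 1):(a$y + a$h), (a$x + 1):(a$x + a$w), ,
                     drop = FALSE]
    all(ref == crop)
  }, logical(1))
  expect_true(any(matches))
  # destination annotations untouched
  expect_identical(out$annotations[seq_len(nrow(dst$annotations)),
                                   c("x", "y", "w", "h")],
                   dst$annotations[, c("x", "y", "w", "h")])
  # category preserved
  expect_true(new_ann$category_id %in% src_anns$category_id)
})

test_that("scaling a mask scales its area quadratically", {
  patch <- list(pixels = array(runif(300, 0, 255), c(10, 10, 3)),
                mask = matrix(1, 10, 10))
  w <- camodet:::warp_patch(patch, rotation_deg = 0, scale = 2)
  expect_gte(sum(w$mask), 380)
  expect_lte(sum(w$mask), 420)
  # rotation by 90 degrees preserves area of a square mask
  r <- camodet:::warp_patch(patch, rotation_deg = 90, scale = 1)
  expect_equal(sum(r$mask), 100, tolerance = 0.1)
})

test_that("augment_dataset reaches the target count with valid output", {
  ds <- generate_dataset(4, scene_spec(width = 48, height = 48,
                                       n_objects = 1,
                                       size_range = c(10, 16)), seed = 3)
  aug <- augment_dataset(ds, 7, seed = 11)
  expect_equal(nrow(aug$images), 7)
  expect_equal(sum(aug$images$augmented), 3)
  expect_silent(validate_dataset(aug))
  # original annotations retained verbatim
  expect_identical(aug$annotations[seq_len(nrow(ds$annotations)),
                                   c("x", "y", "w", "h")],
                   ds$annotations[, c("x", "y", "w", "h")])
  # augmented images carry at least the destination's annotations
  expect_gte(nrow(aug$annotations), nrow(ds$annotations) + 3)
  # determinism
  aug2 <- augment_dataset(ds, 7, seed = 11)
  expect_identical(aug$annotations[, c("x", "y", "w", "h")],
                   aug2$annotations[, c("x", "y", "w", "h")])
  # no-op when the target equals the current size
  same <- augment_dataset(ds, 4, seed = 11)
  expect_equal(nrow(same$images), 4)
  expect_error(augment_dataset(ds, 2, seed = 1), "below current")
})

test_that("augmented datasets survive COCO validation on re-read", {
  ds <- generate_dataset(3, scene_spec(width = 48, height = 48,
                                       n_objects = 2,
                                       size_range = c(10, 14)), seed = 19)
  aug <- augment_dataset(ds, 5, seed = 23)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(aug, path)
  expect_s3_class(read_coco(path), "detection_dataset")
})
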