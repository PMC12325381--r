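test_that("palette blending interpolates means and keeps texture", {
  obj <- camo_palette(rbind(c(200, 60, 50), c(230, 120, 60)),
                      sds = c(8, 8), weights = c(0.5, 0.5))
  bg <- camo_palette(rbind(c(70, 110, 45), c(100, 145, 60)),
                     sds = c(12, 12), weights = c(0.5, 0.5))
  full <- blend_palette(obj, bg, 1)
  expect_equal(full$means, bg$means)
  expect_equal(full$sds, obj$sds)
  none <- blend_palette(obj, bg, 0)
  expect_equal(none$means, obj$means)
  half <- blend_palette(obj, bg, 0.5)
  expect_equal(half$means, (obj$means + bg$means) / 2)
  expect_error(blend_palette(obj, bg, 1.5), "alpha")
})

test_that("composed scenes have tight boxes containing their masks", {
  spec <- scene_spec(width = 64, height = 64, n_objects = 2,
                     size_range = c(12, 20))
  for (s in 1:5) {
    sc <- compose_scene(spec, seed = s)
    expect_true(all(dim(sc$image) == c(64, 64, 3)))
    for (j in seq_len(nrow(sc$annotations))) {
      a <- sc$annotations[j, ]
      m <- a$mask[[1]]
      idx <- which(m > 0, arr.ind = TRUE)
      expect_equal(min(idx[, 2]) - 1, a$x)
      expect_equal(min(idx[, 1]) - 1, a$y)
      expect_equal(max(idx[, 2]) - min(idx[, 2]) + 1, a$w)
      expect_equal(max(idx[, 1]) - min(idx[, 1]) + 1, a$h)
    }
  }
  expect_error(
    compose_scene(scene_spec(width = 16, height = 16,
                             size_range = c(20, 30)), seed = 1),
    "exceeds image size")
})

test_that("generated datasets are deterministic given the seed", {
  spec <- scene_spec(width = 48, height = 48, n_objects = 1,
                     size_range = c(10, 16))
  d1 <- generate_dataset(4, spec, seed = 7)
  d2 <- generate_dataset(4, spec, seed = 7)
  expect_identical(d1$annotations[, c("x", "y", "w", "h")],
                   d2$annotations[, c("x", "y", "w", "h")])
  expect_identical(d1$pixels, d2$pixels)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_coco(d1, p1); write_coco(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
  d3 <- generate_dataset(4, spec, seed = 8)
  expect_false(identical(d1$pixels, d3$pixels))
})

test_that("mean tgc decreases as the similarity alpha rises", {
  spec <- scene_spec(width = 64, height = 64, n_objects = 1,
                     size_range = c(16, 26))
  means <- vapply(c(0, 0.5, 1), function(a) {
    ds <- generate_dataset(20, spec, seed = 101, alpha = a)
    mean(suppressWarnings(tidy(score_dataset(ds))$tgc))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("half-camouflaged datasets dial CD near one", {
  spec <- scene_spec(width = 64, height = 64, n_objects = 1,
                     size_range = c(16, 26))
  ds <- generate_dataset(200, spec, seed = 55, alpha = c(0, 1))
  rep <- score_dataset(ds)
  expect_equal(nrow(tidy(rep)), 200)
  expect_gte(rep$cd, 0.8)
  expect_lte(rep$cd, 1.25)
})
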