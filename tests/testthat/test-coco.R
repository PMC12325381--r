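test_that("COCO JSON round trip preserves the data model", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(ds, path)
  back <- read_coco(path)
  expect_equal(nrow(back$images), 2)
  expect_equal(nrow(back$annotations), 3)
  expect_identical(back$annotations[, c("x", "y", "w", "h")],
                   ds$annotations[, c("x", "y", "w", "h")])
  expect_identical(back$categories$name, ds$categories$name)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_coco(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("empty-annotation datasets survive the round trip", {
  ds <- detection_dataset(
    images = tibble::tibble(id = 1L, width = 8, height = 8,
                            file_name = "x.png"),
    annotations = tibble::tibble(id = integer(), image_id = integer(),
                                 category_id = integer(), x = numeric(),
                                 y = numeric(), w = numeric(),
                                 h = numeric()),
    categories = tibble::tibble(id = 1L, name = "c"))
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(ds, path)
  expect_equal(nrow(read_coco(path)$annotations), 0)
})

test_that("validation reports offending annotation and image ids", {
  ds <- tiny_dataset()
  bad <- ds
  bad$annotations$image_id[2] <- 99L
  expect_error(validate_dataset(bad), "99")
  bad2 <- ds
  bad2$annotations$w[1] <- 100
  expect_error(validate_dataset(bad2), "1")
  bad3 <- ds
  bad3$annotations$id[2] <- bad3$annotations$id[1]
  expect_error(validate_dataset(bad3), "duplicate annotation")
  expect_error(read_coco(withr::local_tempfile(fileext = ".json")),
               "no such file")
})

test_that("extract_regions partitions foreground and background pixels", {
  img <- array(runif(100 * 100 * 3, 0, 255), c(100, 100, 3))
  one <- tibble::tibble(id = 1L, x = 10, y = 20, w = 10, h = 10)
  r <- extract_regions(img, one)
  expect_equal(nrow(r$foreground[[1]]), 100)
  expect_equal(nrow(r$background[[1]]), 9900)

  two <- tibble::tibble(id = 1:2, x = c(0, 50), y = c(0, 50),
                        w = c(10, 10), h = c(10, 10))
  r2 <- extract_regions(img, two)
  expect_equal(nrow(r2$background[[1]]), 9800)
  expect_equal(nrow(r2$foreground[[1]]) + nrow(r2$foreground[[2]]) +
                 nrow(r2$background[[1]]), 100 * 100)

  # fully overlapping boxes: the union, not the sum, is excluded
  overlap <- tibble::tibble(id = 1:2, x = c(10, 10), y = c(10, 10),
                            w = c(10, 10), h = c(10, 10))
  r3 <- extract_regions(img, overlap)
  expect_equal(nrow(r3$background[[1]]), 9900)

  # local surround: 3x-dilated box minus the box itself
  r4 <- extract_regions(img, one, mode = "local_surround")
  expect_lt(nrow(r4$background[[1]]), 9900)
  expect_gt(nrow(r4$background[[1]]), 0)
})

test_that("hold-out split is image-level, exact and deterministic", {
  ds <- generate_dataset(10, scene_spec(width = 48, height = 48,
                                        n_objects = 1,
                                        size_range = c(10, 16)), seed = 9)
  sp <- holdout_split(ds, ratio = 0.7, seed = 5)
  expect_equal(nrow(sp$train$images), 7)
  expect_equal(nrow(sp$val$images), 3)
  expect_length(intersect(sp$train$images$id, sp$val$images$id), 0)
  expect_setequal(c(sp$train$images$id, sp$val$images$id), ds$images$id)
  # annotations follow their images
  expect_setequal(sp$train$annotations$image_id, sp$train$images$id)
  sp2 <- holdout_split(ds, ratio = 0.7, seed = 5)
  expect_identical(sp$train$images$id, sp2$train$images$id)
  sp3 <- holdout_split(ds, ratio = 0.7, seed = 6)
  expect_false(identical(sort(sp$train$images$id),
                         sort(sp3$train$images$id)) &&
                 identical(sp$train$images$id, sp3$train$images$id))
  expect_error(holdout_split(ds, ratio = 1.2), "ratio")
})

test_that("write_dataset emits readable images, masks and annotations", {
  ds <- generate_dataset(2, scene_spec(width = 48, height = 48,
                                       n_objects = 1,
                                       size_range = c(10, 16)), seed = 13)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "annotations.json")))
  back <- read_coco(file.path(dir, "annotations.json"), image_dir = dir)
  expect_equal(nrow(back$images), 2)
  img <- get_image(back, back$images$id[1])
  expect_equal(dim(img), c(48, 48, 3))
  expect_true(all(abs(img - get_image(ds, back$images$id[1])) <= 0.5))
  mask_files <- list.files(file.path(dir, "masks"))
  expect_equal(length(mask_files), nrow(ds$annotations))
})
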