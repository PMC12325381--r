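test_that("region histograms bin and normalize correctly", {
  h <- region_histogram(matrix(0, 100, 3), n_bins = 32)
  expect_equal(unname(h$channels[, 1]), rep(1, 3))
  expect_equal(sum(h$channels), 3)

  px <- matrix(c(0, 0, 0, 255, 0, 0, 0, 0, 0, 255, 0, 0),
               ncol = 3, byrow = TRUE)
  h2 <- region_histogram(px, n_bins = 2)
  expect_equal(unname(h2$channels[1, ]), c(0.5, 0.5))

  set.seed(4)
  patch <- matrix(runif(300, 0, 255), 100, 3)
  h3 <- region_histogram(patch, n_bins = 32)
  expect_equal(unname(rowSums(h3$channels)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(h3$channels >= 0))

  expect_error(region_histogram(matrix(numeric(0), 0, 3)), "empty region")
  expect_error(region_histogram(patch, n_bins = 1), "n_bins")
  expect_warning(region_histogram(matrix(10, 5, 1)), "grayscale")
})

test_that("the 255 boundary falls in the last bin for any bin count", {
  for (b in c(2, 3, 32, 256)) {
    h <- region_histogram(matrix(255, 10, 3), n_bins = b)
    expect_equal(unname(h$channels[, b]), rep(1, 3))
  }
})

test_that("tgc distance matches hand evaluation and its bounds", {
  mk <- function(chan) {
    structure(list(channels = chan, n_bins = ncol(chan), n_pixels = 10L),
              class = "region_histogram")
  }
  flat <- matrix(rep(c(0.5, 0.5, 0, 0), 3), 3, 4, byrow = TRUE)
  expect_equal(tgc_distance(mk(flat), mk(flat)), 0)

  # One channel differs: term-by-term (0.25^2/0.75)*2 + (0.25^2/0.25)*2
  other <- flat
  other[1, ] <- c(0.25, 0.25, 0.25, 0.25)
  expect_equal(tgc_distance(mk(flat), mk(other)), 2 / 3, tolerance = 1e-4)

  # Disjoint support on all channels forces the maximum of 6.
  a <- matrix(rep(c(1, 0), 3), 3, 2, byrow = TRUE)
  b <- matrix(rep(c(0, 1), 3), 3, 2, byrow = TRUE)
  expect_equal(tgc_distance(mk(a), mk(b)), 6)

  expect_error(tgc_distance(mk(a), region_histogram(matrix(0, 4, 3), 8)),
               "bin counts differ")
})

test_that("tgc is symmetric, bounded, and permutation invariant", {
  set.seed(11)
  mk <- function(chan) {
    structure(list(channels = chan, n_bins = ncol(chan), n_pixels = 50L),
              class = "region_histogram")
  }
  for (i in 1:25) {
    c1 <- t(apply(matrix(rexp(3 * 8), 3), 1, function(r) r / sum(r)))
    c2 <- t(apply(matrix(rexp(3 * 8), 3), 1, function(r) r / sum(r)))
    d12 <- tgc_distance(mk(c1), mk(c2))
    expect_equal(d12, tgc_distance(mk(c2), mk(c1)))
    expect_gte(d12, 0)
    expect_lte(d12, 6)
    perm <- sample(8)
    expect_equal(d12, tgc_distance(mk(c1[, perm]), mk(c2[, perm])))
  }
})

test_that("camouflage degree counts and ratio follow the threshold", {
  s <- tibble::tibble(object_id = 1:10,
                      tgc = c(rep(0.3, 4), rep(1.2, 6)))
  rep <- compute_cd(s, threshold = 0.9)
  expect_equal(rep$n_below, 4)
  expect_equal(rep$n_above, 6)
  expect_equal(rep$cd, 4 / 6)
  expect_identical(tidy(rep)$is_camouflaged, s$tgc < 0.9)
  expect_equal(glance(rep)$cd, 4 / 6)

  sym <- tibble::tibble(object_id = 1:8, tgc = c(rep(0.1, 4), rep(2, 4)))
  expect_equal(compute_cd(sym)$cd, 1)

  all_low <- tibble::tibble(object_id = 1:3, tgc = rep(0.1, 3))
  expect_error(compute_cd(all_low), "CD undefined")
  expect_error(compute_cd(tibble::tibble(object_id = 1, tgc = -1)),
               "non-negative")
})

test_that("score_dataset scores every annotation against the background", {
  ds <- tiny_dataset()
  rep <- score_dataset(ds, cd_config())
  expect_s3_class(rep, "cd_report")
  expect_equal(nrow(tidy(rep)), 3)
  # Solid, chromatically disjoint boxes on a green background: far distances.
  expect_true(all(tidy(rep)$tgc >= 0.9))
  # local_surround mode also runs and yields valid distances
  rep2 <- score_dataset(ds, cd_config(background_mode = "local_surround"))
  expect_true(all(tidy(rep2)$tgc >= 0 & tidy(rep2)$tgc <= 6))
})

test_that("synthetic scenes score camouflaged or conspicuous as composed", {
  spec_hi <- scene_spec(width = 64, height = 64, n_objects = 1, alpha = 1,
                        size_range = c(16, 26))
  spec_lo <- scene_spec(width = 64, height = 64, n_objects = 1, alpha = 0,
                        size_range = c(16, 26))
  ds_hi <- generate_dataset(6, spec_hi, seed = 31)
  ds_lo <- generate_dataset(6, spec_lo, seed = 32)
  tgc_hi <- suppressWarnings(tidy(score_dataset(ds_hi))$tgc)
  tgc_lo <- tidy(score_dataset(ds_lo))$tgc
  expect_true(mean(tgc_hi) < mean(tgc_lo))
  expect_true(all(tgc_hi < 0.9))
  expect_true(all(tgc_lo >= 0.9))
})
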