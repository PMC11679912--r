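test_that("slice_mae matches a brute-force double loop", {
  expect_equal(slice_mae(matrix(5, 4, 4), matrix(5, 4, 4)), 0)
  expect_equal(slice_mae(matrix(0, 2, 2), matrix(c(4, 0, 0, 0), 2, 2)), 1.0)

  set.seed(42)
  gt <- matrix(rnorm(256, sd = 200), 16, 16)
  sct <- matrix(rnorm(256, sd = 200), 16, 16)
  acc <- 0
  for (i in 1:16) for (j in 1:16) acc <- acc + abs(gt[i, j] - sct[i, j])
  expect_equal(slice_mae(gt, sct), acc / 256, tolerance = 1e-12)

  expect_error(slice_mae(matrix(0, 2, 2), matrix(0, 3, 3)), "shape mismatch")
  expect_error(slice_mae(matrix(c(1, NA, 1, 1), 2, 2), matrix(0, 2, 2)),
               "non-finite")
})

test_that("slice_mae is symmetric, metric-like, and closed-form on offsets", {
  set.seed(7)
  a <- matrix(rnorm(64), 8, 8); b <- matrix(rnorm(64), 8, 8)
  c_ <- matrix(rnorm(64), 8, 8)
  expect_equal(slice_mae(a, b), slice_mae(b, a))
  expect_lte(slice_mae(a, c_), slice_mae(a, b) + slice_mae(b, c_) + 1e-12)
  for (off in c(-3.5, 0, 12)) expect_equal(slice_mae(a, a + off), abs(off))
  # identical spatial flips of both slices leave the label unchanged
  expect_equal(slice_mae(a[, 8:1], b[, 8:1]), slice_mae(a, b))
})

test_that("saturation clips above the bound, flags, and is idempotent", {
  s <- saturate_mae(120, 100)
  expect_equal(as.numeric(s), 100)
  expect_true(attr(s, "saturated"))
  s2 <- saturate_mae(63, 100)
  expect_equal(as.numeric(s2), 63)
  expect_false(attr(s2, "saturated"))
  s3 <- saturate_mae(70, 70)
  expect_equal(as.numeric(s3), 70)
  expect_false(attr(s3, "saturated"))  # boundary is not clipping
  expect_equal(as.numeric(saturate_mae(saturate_mae(130, 70), 70)), 70)
  expect_error(saturate_mae(-1, 100), "nonnegative")
  expect_error(saturate_mae(10, 0), "positive")
})

test_that("HU clamping warns and bounds values", {
  x <- c(-2000, 0, 5000)
  expect_warning(y <- clamp_hu(x), "clamped")
  expect_equal(y, c(-1024, 0, 3071))
  expect_silent(clamp_hu(c(-1024, 3071)))
})

test_that("build_corpus labels every retained slice with Eq-style MAE", {
  p1 <- tiny_pair(seed = 5)
  p2 <- tiny_pair(seed = 6)
  corpus <- build_corpus(list(p1$pair, p2$pair), min_body_fraction = 0)
  expect_equal(nrow(corpus), 12L)
  # labels equal independent recomputation from the stored volumes
  for (r in seq_len(nrow(corpus))) {
    pair <- if (corpus$patient_id[r] == p1$pair$patient_id) p1$pair else p2$pair
    i <- corpus$slice_index[r]
    expect_equal(corpus$mae_gt[r],
                 slice_mae(unclass(pair$gt)[, , i], unclass(pair$sct)[, , i]),
                 tolerance = 1e-12)
  }
  # ordered by patient then slice
  expect_identical(corpus$slice_index,
                   unlist(lapply(split(corpus$slice_index, corpus$patient_id),
                                 sort), use.names = FALSE))
})

test_that("all-air slices are excluded by the body-fraction rule", {
  gt <- array(-1000, c(32, 32, 3))
  gt[10:20, 10:20, 2:3] <- 40  # anatomy only on slices 2 and 3
  pair <- volume_pair(hu_volume(gt), hu_volume(gt), patient_id = "A")
  corpus <- build_corpus(pair)
  expect_identical(corpus$slice_index, c(2L, 3L))

  all_air <- volume_pair(hu_volume(array(-1000, c(32, 32, 2))),
                         hu_volume(array(-1000, c(32, 32, 2))))
  expect_error(build_corpus(all_air), "empty corpus")
})

test_that("corpus saturation and manifest writing behave", {
  p <- tiny_pair(seed = 8, targets = c(10, 40, 80, 120, 20, 60))
  corpus <- build_corpus(p$pair, saturation = 100, min_body_fraction = 0)
  expect_true(all(corpus$mae_gt <= 100))
  expect_equal(sum(corpus$saturated), 1L)
  expect_equal(corpus$mae_raw[corpus$saturated], 120, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus_manifest(corpus, path)
  man <- read.csv(path)
  expect_setequal(setdiff(names(corpus), "image"), names(man))
  expect_equal(man$mae_gt, corpus$mae_gt, tolerance = 1e-6)
})
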