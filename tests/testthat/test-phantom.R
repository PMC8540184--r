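test_that("generation is bitwise deterministic and leaves the RNG alone", {
  p <- tiny_params(seed = 33)
  set.seed(999)
  before <- .Random.seed
  s1 <- generate_sample(p)
  expect_identical(.Random.seed, before)
  s2 <- generate_sample(p)
  expect_identical(s1, s2)
  # a different seed changes the image
  p2 <- tiny_params(seed = 34)
  expect_false(identical(generate_sample(p2)$image, s1$image))
})

test_that("mask has exactly 3 instances ordered top to bottom", {
  for (seed in c(1, 17, 60)) {
    s <- generate_sample(tiny_params(seed))
    expect_setequal(unique(as.vector(s$mask)), c(0L, 1L, 2L, 3L))
    lab <- connected_components(s$mask != 0)
    expect_equal(max(lab), 3)
    # stored labels equal the top-to-bottom relabeling (round trip)
    expect_identical(lab, relabel_top_to_bottom(s$mask))
    H <- nrow(s$mask)
    cent <- sapply(1:3, function(k) mean((which(s$mask == k) - 1) %% H + 1))
    expect_true(all(diff(cent) > 0))
  }
})

test_that("noise-free image carries exact configured intensities", {
  p <- tiny_params(seed = 5, noise_sd = 0, bias_amplitude = 0)
  s <- generate_sample(p)
  expect_true(all(s$image[s$mask != 0] == p$intensities$disc))
  expect_true(any(s$image == p$intensities$vertebra))
  expect_true(any(s$image == p$intensities$background))
})

test_that("distractor discs exist, match target intensity, never touch the mask", {
  p <- tiny_params(seed = 8, noise_sd = 0, bias_amplitude = 0)
  s <- generate_sample(p)
  disc_blobs <- connected_components(s$image == p$intensities$disc)
  n_blobs <- max(disc_blobs)
  expect_gte(n_blobs - 3, 1)  # at least one distractor
  # every disc blob is either exactly a mask instance or fully outside it
  for (k in seq_len(n_blobs)) {
    inside <- s$mask[disc_blobs == k] != 0
    expect_true(all(inside) || all(!inside))
  }
  # target blobs overlap their mask instance completely (>= 95% contract)
  for (k in 1:3) {
    expect_true(all(s$image[s$mask == k] == p$intensities$disc))
  }
})

test_that("infeasible geometry and invalid targets raise typed errors", {
  p <- tiny_params(seed = 1)
  p$disc_axis_lengths <- c(10, 12, 20, 30)  # discs taller than their slots
  expect_error(generate_sample(p), class = "discseg_geometry_error")
  expect_error(phantom_params(target_disc_indices = c(1, 4, 6)))  # out of range
  expect_error(phantom_params(target_disc_indices = c(1, 3, 5)))  # pair not adjacent
  expect_error(phantom_params(target_disc_indices = c(2, 4, 5)))  # gap < 2
  expect_error(phantom_params(n_vertebrae = 6, n_discs = 6))
})

test_that("spec example: 6 discs with targets (0,4,5) yields 3 instances", {
  p <- tiny_params(seed = 2)
  p$target_disc_indices <- c(0L, 4L, 5L)
  s <- generate_sample(p)
  expect_equal(count_instances(s$mask != 0), 3)
})

test_that("generate_dataset writes pairs + manifest, reproducibly", {
  dir1 <- file.path(tempdir(), "ph1")
  dir2 <- file.path(tempdir(), "ph2")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE), add = TRUE)
  p <- tiny_params(seed = 12)
  man <- generate_dataset(10, p, dir1)
  expect_equal(nrow(man), 10)
  expect_true(all(file.exists(man$path_image)))
  expect_true(all(file.exists(man$path_mask)))
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  # same master seed, same bytes
  man2 <- generate_dataset(10, p, dir2)
  for (i in 1:10) {
    expect_identical(readBin(man$path_image[i], "raw", 1e6),
                     readBin(man2$path_image[i], "raw", 1e6))
    expect_identical(readBin(man$path_mask[i], "raw", 1e6),
                     readBin(man2$path_mask[i], "raw", 1e6))
  }
  # loading round-trips masks exactly
  loaded <- load_dataset(file.path(dir1, "manifest.csv"))
  expect_equal(length(loaded), 10)
  ref <- generate_samples(1, p)[[1]]
  expect_identical(loaded[[1]]$mask, matrix(as.integer(ref$mask), 64, 64))
  expect_error(generate_dataset(0, p, dir1))
})
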