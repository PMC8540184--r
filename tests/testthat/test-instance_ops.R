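test_that("connected_components handles empty masks and labels top to bottom", {
  expect_equal(max(connected_components(matrix(FALSE, 5, 5))), 0)
  m <- matrix(FALSE, 12, 6)
  m[2:3, 2:4] <- TRUE    # top blob
  m[6:7, 2:4] <- TRUE    # middle
  m[10:11, 2:4] <- TRUE  # bottom
  lab <- connected_components(m)
  expect_equal(max(lab), 3)
  expect_true(all(lab[2:3, 2:4] == 1))
  expect_true(all(lab[6:7, 2:4] == 2))
  expect_true(all(lab[10:11, 2:4] == 3))
})

test_that("diagonal touching distinguishes 4- from 8-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE
  expect_equal(max(connected_components(m, 8)), 1)
  expect_equal(max(connected_components(m, 4)), 2)
})

test_that("connected_components agrees with a scalar BFS oracle", {
  set.seed(42)
  for (i in 1:50) {
    m <- random_mask(32, 32, p = runif(1, 0.2, 0.6))
    conn <- if (i %% 2 == 0) 8 else 4
    expect_identical(canonical_labels(connected_components(m, conn)),
                     canonical_labels(cc_oracle(m, conn)))
  }
})

test_that("relabel_top_to_bottom sorts by centroid row and is idempotent", {
  set.seed(7)
  H <- 40; W <- 40
  lab <- matrix(0L, H, W)
  # three blobs in scrambled label order
  lab[30:33, 5:10] <- 5L
  lab[2:5, 20:25] <- 9L
  lab[15:18, 12:17] <- 2L
  out <- relabel_top_to_bottom(lab)
  # brute-force expected order from pixel lists
  cent <- sapply(c(5L, 9L, 2L), function(v) mean((which(lab == v) - 1) %% H + 1))
  expected_order <- c(5L, 9L, 2L)[order(cent)]
  for (k in 1:3) {
    expect_true(all(out[lab == expected_order[k]] == k))
  }
  expect_identical(relabel_top_to_bottom(out), out)
})

test_that("relabel swaps vertically exchanged labels and conserves pixel counts", {
  lab <- matrix(0L, 20, 10)
  lab[12:14, 3:6] <- 1L  # label 1 is BELOW label 2
  lab[2:4, 3:6] <- 2L
  out <- relabel_top_to_bottom(lab)
  expect_true(all(out[2:4, 3:6] == 1))
  expect_true(all(out[12:14, 3:6] == 2))
  expect_equal(sort(as.integer(table(out[out > 0]))),
               sort(as.integer(table(lab[lab > 0]))))
})

test_that("centroid-row ties break on centroid column", {
  lab <- matrix(0L, 6, 12)
  lab[3, 9:10] <- 1L   # right blob, same centroid row
  lab[3, 2:3] <- 2L    # left blob
  out <- relabel_top_to_bottom(lab)
  expect_true(all(out[3, 2:3] == 1))
  expect_true(all(out[3, 9:10] == 2))
})

test_that("count_instances counts blobs", {
  expect_equal(count_instances(matrix(FALSE, 4, 4)), 0)
  s <- fixture_sample()
  expect_equal(count_instances(s$mask != 0), 3)
  m <- s$mask != 0
  m[1:2, 1:2] <- TRUE  # one extra blob in a far corner
  expect_equal(count_instances(m), 4)
})

test_that("lower_disc_crop reproduces the hand-computed window", {
  lab <- matrix(0L, 200, 200)
  lab[81:95, 41:70] <- 2L    # 0-based half-open rows [80,95), cols [40,70)
  lab[101:115, 41:70] <- 3L  # rows [100,115)
  w <- lower_disc_crop(lab, margin_frac = 0.1)
  expect_equal(c(w$row_start, w$row_end, w$col_start, w$col_end),
               c(76L, 119L, 37L, 73L))
  # margin 0 gives the tight half-open bounding box
  w0 <- lower_disc_crop(lab, margin_frac = 0)
  expect_equal(c(w0$row_start, w0$row_end, w0$col_start, w0$col_end),
               c(80L, 115L, 40L, 70L))
  lab[lab == 3L] <- 0L
  expect_error(lower_disc_crop(lab), class = "discseg_missing_instance")
})

test_that("apply_crop / paste_back round-trip exactly", {
  s <- fixture_sample()
  w <- lower_disc_crop(s$mask)
  cropped <- apply_crop(s$mask, w)
  back <- paste_back(cropped, w, dim(s$mask))
  expect_equal(back[back != 0], s$mask[s$mask %in% c(2L, 3L)])
  expect_true(all(back[s$mask == 2L] == 2))
  expect_true(all(back[s$mask == 3L] == 3))
  # 1-pixel window extracts a scalar
  w1 <- crop_window(3, 4, 5, 6)
  expect_equal(dim(apply_crop(s$image, w1)), c(1L, 1L))
  expect_equal(apply_crop(s$image, w1)[1, 1], s$image[4, 6])
  # all-zero input stays all-zero
  expect_true(all(paste_back(apply_crop(matrix(0, 10, 10), w1), w1,
                             c(10, 10)) == 0))
  expect_error(apply_crop(matrix(0, 3, 3), w1), class = "discseg_shape_error")
})

test_that("labels of different components are never adjacent", {
  set.seed(11)
  m <- random_mask(24, 24, 0.4)
  lab <- connected_components(m, 8)
  H <- nrow(lab)
  idx <- which(lab > 0)
  for (d in list(c(-1, 0), c(0, -1), c(-1, -1), c(-1, 1))) {
    r <- (idx - 1) %% H + 1 + d[1]
    cc <- (idx - 1) %/% H + 1 + d[2]
    ok <- r >= 1 & r <= H & cc >= 1 & cc <= ncol(lab)
    nb <- lab[cbind(r[ok], cc[ok])]
    expect_true(all(nb == 0 | nb == lab[idx[ok]]))
  }
})
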