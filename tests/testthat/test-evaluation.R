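test_that("iou covers identity, disjoint, overlap and empty conventions", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  expect_equal(iou(a, a), 1)
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(iou(a, b), 0)
  # 2x2 square against itself shifted right by one: 2 / 6
  sh <- matrix(FALSE, 6, 6); sh[2:3, 3:4] <- TRUE
  expect_equal(iou(a, sh), 2 / 6)
  e <- matrix(FALSE, 6, 6)
  expect_equal(iou(e, e), 1)   # agreement on absence
  expect_equal(iou(a, e), 0)
  expect_error(iou(a, matrix(FALSE, 3, 3)), class = "discseg_shape_error")
})

test_that("discrimination is coverage of the standard mask only", {
  S <- matrix(FALSE, 8, 8); S[2:3, 2:6] <- TRUE  # 10 pixels
  R_sup <- S; R_sup[5:8, 1:8] <- TRUE            # superset
  expect_equal(discrimination(R_sup, S), 1)
  expect_equal(discrimination(matrix(FALSE, 8, 8), S), 0)
  R7 <- matrix(FALSE, 8, 8)
  R7[2:3, 2:4] <- TRUE; R7[2, 5] <- TRUE         # covers 7 of 10
  R7[7:8, 7:8] <- TRUE                           # extra pixels outside S
  expect_equal(discrimination(R7, S), 0.7)
  expect_error(discrimination(R7, matrix(FALSE, 8, 8)),
               class = "discseg_empty_mask")
})

test_that("iou is symmetric, discrimination is not", {
  set.seed(3)
  X <- random_mask(10, 10, 0.4); Y <- random_mask(10, 10, 0.4)
  X[1, 1] <- TRUE; Y[1, 1] <- TRUE
  expect_equal(iou(X, Y), iou(Y, X))
  # containment counter-example
  S <- matrix(FALSE, 5, 5); S[2:3, 2:3] <- TRUE
  R <- S; R[4, 4] <- TRUE
  expect_equal(discrimination(R, S), 1)
  expect_lt(discrimination(S, R), 1)
})

test_that("iou and discrimination agree with brute-force pixel counting", {
  set.seed(9)
  for (i in 1:25) {
    X <- random_mask(12, 12, runif(1, 0.2, 0.7))
    Y <- random_mask(12, 12, runif(1, 0.2, 0.7))
    n_int <- sum(X & Y); n_uni <- sum(X | Y)
    if (n_uni > 0) expect_equal(iou(X, Y), n_int / n_uni)
    if (sum(Y) > 0) expect_equal(discrimination(X, Y), n_int / sum(Y))
  }
})

test_that("image_correct applies the count rule and the 70% cutoff", {
  cfg <- eval_config()
  expect_equal(image_correct(3, c(0.9, 0.8, 0.71), cfg), 1L)
  expect_equal(image_correct(4, c(1, 1, 1), cfg), 0L)
  expect_equal(image_correct(2, c(1, 1, 1), cfg), 0L)
  expect_equal(image_correct(3, c(0.9, 0.69, 0.9), cfg), 0L)
  expect_equal(image_correct(3, c(0.7, 0.7, 0.7), cfg), 1L)  # boundary is >=
})

test_that("accuracy reproduces ratio arithmetic", {
  b <- c(rep(1, 289), rep(0, 308 - 289))
  acc <- accuracy(b)
  expect_equal(acc$B, 289L)
  expect_equal(round(acc$A, 3), 0.938)
  expect_equal(accuracy(rep(0, 10))$A, 0)
  expect_error(accuracy(integer(0)))
})

test_that("match_instances pairs by top-to-bottom rank", {
  s <- fixture_sample()
  pairing <- match_instances(s$mask, s$mask)
  for (k in 1:3) {
    expect_equal(discrimination(pairing$R[[k]], pairing$S[[k]]), 1)
  }
  # label-permuted prediction restores correspondence by rank
  perm <- matrix(0L, nrow(s$mask), ncol(s$mask))
  perm[s$mask == 1L] <- 3L; perm[s$mask == 2L] <- 1L; perm[s$mask == 3L] <- 2L
  pairing2 <- match_instances(perm, s$mask)
  for (k in 1:3) {
    expect_equal(discrimination(pairing2$R[[k]], pairing2$S[[k]]), 1)
  }
  # wrong instance count: no pairing
  two <- s$mask; two[two == 1L] <- 0L
  expect_null(match_instances(two, s$mask))
})

test_that("evaluate_dataset aggregates records and handles failures", {
  s1 <- fixture_sample(1)
  s2 <- fixture_sample(2)
  rep_perfect <- evaluate_dataset(list(s1$mask, s2$mask),
                                  list(s1$mask, s2$mask))
  expect_equal(rep_perfect$A, 1)
  expect_equal(rep_perfect$mean_iou, 1)
  # one failed image out of two
  empty <- matrix(0L, 64, 64)
  rep_half <- evaluate_dataset(list(s1$mask, empty),
                               list(s1$mask, s2$mask))
  expect_equal(rep_half$A, 0.5)
  expect_equal(rep_half$B, sum(sapply(rep_half$records, `[[`, "b_i")))
  expect_equal(rep_half$mean_iou, (1 + 0) / 2)
  expect_true(rep_half$A * rep_half$T == round(rep_half$A * rep_half$T))
  expect_error(evaluate_dataset(list(s1$mask), list(s1$mask, s2$mask)))
})

test_that("failed segmentation_result forces b_i = 0 but keeps its IoU", {
  s <- fixture_sample()
  r <- structure(list(mask = s$mask, failed = TRUE),
                 class = "segmentation_result")
  rec <- evaluate_record(r, s$mask)
  expect_equal(rec$b_i, 0L)
  expect_equal(rec$iou_i, 1)
})

test_that("report serialization writes JSON aggregates and per-image CSV", {
  s <- fixture_sample()
  report <- evaluate_dataset(list(s$mask), list(s$mask))
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  df <- write_eval_report(report, jp, cp)
  agg <- jsonlite::read_json(jp)
  expect_equal(agg$A, 1)
  expect_equal(agg$T, 1)
  back <- utils::read.csv(cp)
  expect_equal(nrow(back), 1)
  expect_equal(back$b_i, 1)
  expect_equal(names(back),
               c("id", "P_i", "C_i1", "C_i2", "C_i3", "b_i", "iou_i"))
})

test_that("conservative_sample_size reproduces the textbook formula", {
  expect_equal(conservative_sample_size(0.95, sd = 0.01, margin = 0.0004),
               2401L)
  # margin = z * sd collapses to n = 1
  expect_equal(conservative_sample_size(0.95, sd = 0.01, margin = 1.96 * 0.01),
               1L)
  # doubling sd quadruples n (before the ceiling)
  n1 <- conservative_sample_size(0.95, sd = 0.01, margin = 0.0004)
  n2 <- conservative_sample_size(0.95, sd = 0.02, margin = 0.0004)
  expect_equal(n2, 4L * n1)
  expect_error(conservative_sample_size(0.95, sd = 0.01, margin = 0))
})
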