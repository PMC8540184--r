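# Synthetic sagittal-spine phantom.
#
# Emulates the structure of a midsagittal lumbar MRI slice at desk scale: a
# roughly vertical, gently curved column of bright vertebral bodies (rounded
# rectangles) separated by elliptical intervertebral discs. Only three
# designated discs — one isolated upper disc and two adjacent lower discs,
# mirroring L1/L2, L4/L5 and L5/S1 — are foreground in the reference mask;
# the remaining discs are distractors with identical intensity statistics,
# which is exactly the confusability that motivates the two-stage cascade.
# Additive Gaussian noise and a smooth polynomial bias field complete the
# image model.

#' Phantom generation parameters
#'
#' @param image_size side of the square image in pixels (default 128; use 64
#'   for fast tests, up to 512).
#' @param n_vertebrae number of vertebral bodies (must be `n_discs + 1`).
#' @param n_discs number of discs, one between each consecutive vertebra pair.
#' @param target_disc_indices three strictly increasing 0-based disc ordinals:
#'   one isolated upper disc, then two adjacent lower discs separated from it
#'   by at least two distractor discs.
#' @param disc_axis_lengths optional `c(a_min, a_max, b_min, b_max)` pixel
#'   ranges for the disc ellipse semi-axes (horizontal `a`, vertical `b`);
#'   `NULL` scales them from the image size.
#' @param column_curvature amplitude in pixels of the smooth lateral bend of
#'   the spinal column; `NULL` gives 4% of the image size.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param bias_amplitude peak amplitude of the smooth polynomial bias field.
#' @param seed integer seed; generation is bitwise deterministic given it.
#' @param intensities named list of the flat intensities for `background`,
#'   `vertebra` and `disc` (distractor discs share the disc intensity).
#' @return a validated `phantom_params` list.
#' @export
phantom_params <- function(image_size = 128L,
                           n_vertebrae = 7L,
                           n_discs = 6L,
                           target_disc_indices = c(1L, 4L, 5L),
                           disc_axis_lengths = NULL,
                           column_curvature = NULL,
                           noise_sd = 0.03,
                           bias_amplitude = 0.08,
                           seed = 1L,
                           intensities = list(background = 0.2,
                                              vertebra = 0.5,
                                              disc = 0.8)) {
  assert_that(image_size >= 32, "image_size must be at least 32 pixels")
  assert_that(n_discs == n_vertebrae - 1,
              "n_discs must equal n_vertebrae - 1 (discs sit between vertebrae)")
  t <- sort(as.integer(target_disc_indices))
  assert_that(length(t) == 3 && all(diff(t) > 0),
              "target_disc_indices must be 3 strictly increasing ordinals")
  assert_that(all(t >= 0) && all(t < n_discs),
              "target_disc_indices must lie in [0, n_discs)")
  assert_that(t[3] - t[2] == 1,
              "the lower two target discs must be adjacent (consecutive ordinals)")
  assert_that(t[2] - t[1] >= 3,
              "the upper target disc must be separated from the lower pair by >= 2 distractors")
  assert_that(noise_sd >= 0 && bias_amplitude >= 0,
              "noise_sd and bias_amplitude must be non-negative")
  if (!is.null(disc_axis_lengths)) {
    assert_that(length(disc_axis_lengths) == 4 &&
                  all(disc_axis_lengths > 0) &&
                  disc_axis_lengths[1] <= disc_axis_lengths[2] &&
                  disc_axis_lengths[3] <= disc_axis_lengths[4],
                "disc_axis_lengths must be c(a_min, a_max, b_min, b_max) > 0")
  }
  structure(list(
    image_size = as.integer(image_size),
    n_vertebrae = as.integer(n_vertebrae),
    n_discs = as.integer(n_discs),
    target_disc_indices = t,
    disc_axis_lengths = disc_axis_lengths,
    column_curvature = column_curvature,
    noise_sd = noise_sd,
    bias_amplitude = bias_amplitude,
    seed = as.integer(seed),
    intensities = intensities
  ), class = "phantom_params")
}

# pixel set of a rotated superellipse |u/a|^p + |v/b|^p <= 1 centred at
# (row0, col0); p = 2 gives an ellipse, larger p a rounded rectangle
superellipse_mask <- function(H, W, row0, col0, a, b, theta = 0, p = 2) {
  r <- matrix(seq_len(H), H, W) - row0
  cl <- matrix(seq_len(W), H, W, byrow = TRUE) - col0
  u <- cos(theta) * cl + sin(theta) * r
  v <- -sin(theta) * cl + cos(theta) * r
  (abs(u / a)^p + abs(v / b)^p) <= 1
}

#' Generate one phantom sample
#'
#' @param params a [phantom_params()] object.
#' @return a `phantom_sample` list: `image` (matrix in \[0, 1\]), `mask`
#'   (integer matrix, labels 1..3 top to bottom for the three target discs),
#'   and `meta` (the parameters plus derived geometry).
#' @export
generate_sample <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, generate_sample_impl(params))
}

generate_sample_impl <- function(params) {
  S <- params$image_size
  nv <- params$n_vertebrae
  nd <- params$n_discs
  margin <- 0.06 * S
  usable <- S - 2 * margin
  hd <- usable / (2.1 * nv + nd)   # disc slot height; vertebrae are 2.1x
  hv <- 2.1 * hd

  # curved centreline of the column
  amp <- params$column_curvature %||% (0.04 * S)
  phase <- stats::runif(1, 0, 2 * pi)
  offset <- S / 2 + stats::runif(1, -0.03, 0.03) * S
  centre_col <- function(row) {
    offset + amp * sin(2 * pi * (row - margin) / usable * 0.8 + phase)
  }
  centre_slope <- function(row) {
    amp * cos(2 * pi * (row - margin) / usable * 0.8 + phase) *
      2 * pi * 0.8 / usable
  }

  axl <- params$disc_axis_lengths %||%
    c(0.085 * S, 0.115 * S, 0.30 * hd, 0.42 * hd)

  img <- matrix(params$intensities$background, S, S)

  # vertebral bodies
  v_top <- margin + (seq_len(nv) - 1) * (hv + hd)
  for (i in seq_len(nv)) {
    vr <- v_top[i] + hv / 2 + stats::runif(1, -0.08, 0.08) * hd
    wv <- 0.20 * S * stats::runif(1, 0.9, 1.1)
    vm <- superellipse_mask(S, S, vr, centre_col(vr),
                            a = wv / 2, b = hv / 2 * 0.92,
                            theta = atan(centre_slope(vr)), p = 4)
    img[vm] <- params$intensities$vertebra
  }

  # all discs (targets + distractors)
  disc_masks <- vector("list", nd)
  for (j in seq_len(nd)) {
    dr <- v_top[j] + hv + hd / 2 + stats::runif(1, -0.12, 0.12) * hd
    dc <- centre_col(dr) + stats::runif(1, -0.015, 0.015) * S
    a <- stats::runif(1, axl[1], axl[2])
    b <- stats::runif(1, axl[3], axl[4])
    disc_masks[[j]] <- superellipse_mask(S, S, dr, dc, a, b,
                                         theta = atan(centre_slope(dr)))
  }
  # discs must not overlap (adjacent target discs must stay separate blobs)
  for (j in seq_len(nd - 1)) {
    if (any(disc_masks[[j]] & disc_masks[[j + 1]])) {
      abort_discseg(
        "generate_sample: disc geometry infeasible (adjacent discs overlap); reduce disc_axis_lengths",
        "discseg_geometry_error"
      )
    }
  }
  for (dm in disc_masks) img[dm] <- params$intensities$disc

  # reference mask: the three designated discs, labelled top to bottom
  mask <- matrix(0L, S, S)
  for (k in 1:3) {
    mask[disc_masks[[params$target_disc_indices[k] + 1L]]] <- k
  }
  lab <- connected_components(mask != 0)
  if (max(lab) != 3L || !identical(relabel_top_to_bottom(mask), lab)) {
    abort_discseg(
      "generate_sample: target discs merge or vanish at this geometry",
      "discseg_geometry_error"
    )
  }

  # smooth polynomial bias field, scaled to the requested peak amplitude
  if (params$bias_amplitude > 0) {
    u <- matrix(seq(-1, 1, length.out = S), S, S, byrow = TRUE)
    v <- matrix(seq(-1, 1, length.out = S), S, S)
    co <- stats::runif(5, -1, 1)
    p <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
    img <- img + params$bias_amplitude * p / max(abs(p))
  }
  if (params$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(S * S, 0, params$noise_sd), S, S)
  }
  img <- clamp01(img)

  structure(list(
    image = img,
    mask = mask,
    meta = list(params = params, seed = params$seed,
                slot_heights = c(vertebra = hv, disc = hd))
  ), class = "phantom_sample")
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask BMP pairs plus a CSV manifest
#' (`path_image, path_mask, seed`); per-sample seeds are derived
#' reproducibly from `params$seed`, so regeneration with the same master
#' seed gives identical files.
#'
#' @param n number of samples (>= 1).
#' @param params a [phantom_params()]; its `seed` is the master seed.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data frame (also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n, params, out_dir) {
  assert_that(n >= 1, "generate_dataset: n must be >= 1")
  stopifnot(inherits(params, "phantom_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir),
              paste("generate_dataset: cannot create", out_dir),
              "discseg_io_error")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- derive_seed(params$seed, i)
    p_i <- params
    p_i$seed <- seed_i
    smp <- generate_sample(p_i)
    img_path <- file.path(out_dir, sprintf("image_%04d.bmp", i))
    msk_path <- file.path(out_dir, sprintf("mask_%04d.bmp", i))
    write_image(smp$image, img_path)
    write_mask(smp$mask, msk_path)
    rows[[i]] <- data.frame(path_image = img_path, path_mask = msk_path,
                            seed = seed_i)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param manifest_path path to a manifest CSV.
#' @return list of `phantom_sample`-like lists (`image`, `mask`).
#' @export
load_dataset <- function(manifest_path) {
  assert_that(file.exists(manifest_path),
              paste("manifest not found:", manifest_path), "discseg_io_error")
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  lapply(seq_len(nrow(man)), function(i) {
    list(image = read_image(resolve(man$path_image[i])),
         mask = read_mask(resolve(man$path_mask[i])),
         seed = man$seed[i])
  })
}
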