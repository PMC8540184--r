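# Euclidean distance-transform features for the second cascade stage.
#
# The exact (not chamfer) Euclidean distance transform is computed with the
# two-pass lower-envelope-of-parabolas algorithm: a first pass finds, per
# column, the squared distance to the nearest source row; a second pass
# minimises (c - c')^2 + g(r, c') along each row. One map is computed per
# lower disc so the relative-position cue keeps the discs' identities, and
# both maps are fused with the raw image into a three-channel input.

# squared distances standing in for +Inf; larger than any image diagonal^2
.DT_BIG <- 1e12

# 1D squared-distance transform: d(p) = min_q (p-q)^2 + f(q)
dt1d_sq <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L); d <- numeric(n)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# per-column distance (in rows) to the nearest source row, vectorized
nearest_1d <- function(src_rows, n) {
  if (!length(src_rows)) return(rep(sqrt(.DT_BIG), n))
  q <- seq_len(n)
  i <- findInterval(q, src_rows)
  lo <- src_rows[pmax(i, 1L)]
  hi <- src_rows[pmin(i + 1L, length(src_rows))]
  pmin(abs(q - lo), abs(q - hi))
}

#' Exact Euclidean distance transform
#'
#' For every pixel, the Euclidean distance (between pixel centres) to the
#' nearest foreground pixel of `source`; zero inside the source.
#'
#' @param source binary mask marking the source region; must be non-empty.
#' @return numeric matrix of distances in pixel units.
#' @export
distance_transform <- function(source) {
  m <- as_binary(source)
  assert_that(any(m), "distance_transform: source region is empty",
              "discseg_empty_mask")
  H <- nrow(m); W <- ncol(m)
  g2 <- matrix(0, H, W)
  for (j in seq_len(W)) {
    g2[, j] <- nearest_1d(which(m[, j]), H)^2
  }
  g2[g2 > .DT_BIG] <- .DT_BIG
  d2 <- matrix(0, H, W)
  for (i in seq_len(H)) {
    d2[i, ] <- dt1d_sq(g2[i, ])
  }
  sqrt(d2)
}

#' Normalize a distance map to \[0, 1\]
#'
#' `min(d / scale, 1)`; monotone in `d`.
#'
#' @param map distance map (non-negative matrix).
#' @param scale positive length in pixels mapped to 1.
#' @return matrix with values in \[0, 1\].
#' @export
normalize_distance <- function(map, scale) {
  assert_that(length(scale) == 1 && scale > 0, "scale must be positive")
  pmin(map / scale, 1)
}

#' Fuse image and per-disc distance maps into the stage-2 input
#'
#' Channel order is fixed: (image, distance to disc 2, distance to disc 3).
#' Distance channels are normalized by `scale` (default: the image diagonal,
#' which keeps features in \[0, 1\] for any image size); the image channel is
#' clamped to \[0, 1\].
#'
#' @param image grayscale image in \[0, 1\].
#' @param d2,d3 distance maps of the upper and lower of the two lower discs.
#' @param scale normalization length (default image diagonal).
#' @return `H x W x 3` array, all channels in \[0, 1\].
#' @export
fuse_channels <- function(image, d2, d3, scale = NULL) {
  assert_that(all(dim(image) == dim(d2)) && all(dim(image) == dim(d3)),
              "fuse_channels: channel shapes differ", "discseg_shape_error")
  scale <- scale %||% sqrt(nrow(image)^2 + ncol(image)^2)
  out <- array(0, dim = c(nrow(image), ncol(image), 3L))
  out[, , 1L] <- clamp01(image)
  out[, , 2L] <- normalize_distance(d2, scale)
  out[, , 3L] <- normalize_distance(d3, scale)
  attr(out, "channel_semantics") <-
    c("image", "distance-to-disc-2", "distance-to-disc-3")
  out
}
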