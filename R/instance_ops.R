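# Connected-component instance operations: labeling, top-to-bottom ordering,
# counting, and the lower-disc crop used to build stage-1 training data.
#
# Conventions: masks are matrices indexed [row, col]; instance labels are
# consecutive integers 1..K ordered by increasing centroid row (disc 1 is the
# uppermost); crop windows are 0-based, row-major, half-open ranges.

#' Connected-component labeling of a binary mask
#'
#' Partitions the foreground into maximal connected regions and labels them
#' 1..K from top to bottom (by centroid row; see
#' [relabel_top_to_bottom()] for the tie-break rule).
#'
#' @param mask logical or 0/1 matrix; nonzero pixels are foreground.
#' @param connectivity 4 or 8 (default 8, standard for rounded blobs).
#' @return integer matrix with 0 background and labels 1..K.
#' @export
connected_components <- function(mask, connectivity = 8) {
  assert_that(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  m <- as_binary(mask)
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  fg <- which(m)
  if (!length(fg)) return(lab)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  visited <- logical(H * W)
  cur <- 0L
  for (p in fg) {
    if (visited[p]) next
    cur <- cur + 1L
    visited[p] <- TRUE
    lab[p] <- cur
    frontier <- p
    while (length(frontier)) {
      r <- (frontier - 1L) %% H + 1L
      cl <- (frontier - 1L) %/% H + 1L
      nb <- integer(0)
      for (o in offs) {
        rr <- r + o[1L]; cc <- cl + o[2L]
        ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        nb <- c(nb, (cc[ok] - 1L) * H + rr[ok])
      }
      nb <- unique(nb)
      nb <- nb[m[nb] & !visited[nb]]
      visited[nb] <- TRUE
      lab[nb] <- cur
      frontier <- nb
    }
  }
  relabel_top_to_bottom(lab)
}

#' Reorder instance labels from top to bottom
#'
#' Permutes label identities so that centroid rows strictly increase with the
#' label value. Ties on centroid row are broken by smaller centroid column,
#' then by smaller minimum pixel index in row-major scan order; the result is
#' a total order, so this never fails. Idempotent.
#'
#' @param lab integer labeled mask (0 background, positive instance labels;
#'   labels need not be consecutive on input).
#' @return labeled mask with consecutive labels 1..K, top to bottom.
#' @export
relabel_top_to_bottom <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0)
  if (!length(idx)) return(matrix(0L, H, W))
  vals <- lab[idx]
  r <- (idx - 1L) %% H + 1L
  cl <- (idx - 1L) %/% H + 1L
  rowmajor <- (r - 1L) * W + cl
  crow <- tapply(r, vals, mean)
  ccol <- tapply(cl, vals, mean)
  cmin <- tapply(rowmajor, vals, min)
  ord <- order(crow, ccol, cmin)
  old_labels <- as.integer(names(crow))[ord]
  out <- matrix(0L, H, W)
  for (k in seq_along(old_labels)) out[lab == old_labels[k]] <- k
  out
}

#' Count foreground instances of a binary mask
#'
#' @inheritParams connected_components
#' @return number of connected foreground regions.
#' @export
count_instances <- function(mask, connectivity = 8) {
  lab <- connected_components(mask, connectivity)
  if (!length(lab)) 0L else as.integer(max(lab))
}

#' Crop window (0-based, half-open)
#'
#' @param row_start,row_end,col_start,col_end 0-based half-open pixel ranges.
#' @return a `crop_window` list.
#' @export
crop_window <- function(row_start, row_end, col_start, col_end) {
  assert_that(row_start >= 0 && row_start < row_end,
              "crop_window: need 0 <= row_start < row_end")
  assert_that(col_start >= 0 && col_start < col_end,
              "crop_window: need 0 <= col_start < col_end")
  structure(list(row_start = as.integer(row_start),
                 row_end = as.integer(row_end),
                 col_start = as.integer(col_start),
                 col_end = as.integer(col_end)),
            class = "crop_window")
}

#' Bounding window of the lower two discs
#'
#' The tight bounding box of instances 2 and 3 (the lower adjacent discs),
#' expanded on each side by `margin_frac` of the box extent in that
#' direction, then clipped to the image. The expanded start is floored and
#' the expanded end is ceiled, so the window never shrinks below the
#' requested margin.
#'
#' @param labels labeled mask containing instances 2 and 3.
#' @param margin_frac fractional context margin (default 0.25).
#' @return a [crop_window()].
#' @export
lower_disc_crop <- function(labels, margin_frac = 0.25) {
  assert_that(margin_frac >= 0, "margin_frac must be non-negative")
  H <- nrow(labels); W <- ncol(labels)
  idx <- which(labels == 2L | labels == 3L)
  if (!any(labels == 2L) || !any(labels == 3L)) {
    abort_discseg("lower_disc_crop: mask lacks instance 2 or 3",
                  "discseg_missing_instance")
  }
  r <- (idx - 1L) %% H + 1L
  cl <- (idx - 1L) %/% H + 1L
  # 0-based half-open bounds of the union box
  r0 <- min(r) - 1L; r1 <- max(r)
  c0 <- min(cl) - 1L; c1 <- max(cl)
  mh <- margin_frac * (r1 - r0)
  mw <- margin_frac * (c1 - c0)
  crop_window(
    max(0L, floor(r0 - mh)), min(H, ceiling(r1 + mh)),
    max(0L, floor(c0 - mw)), min(W, ceiling(c1 + mw))
  )
}

#' Extract a window from an image or mask
#'
#' @param x matrix (image or mask).
#' @param window a [crop_window()] within the bounds of `x`.
#' @return the cropped matrix.
#' @export
apply_crop <- function(x, window) {
  assert_that(window$row_end <= nrow(x) && window$col_end <= ncol(x),
              "apply_crop: window exceeds array bounds", "discseg_shape_error")
  x[(window$row_start + 1L):window$row_end,
    (window$col_start + 1L):window$col_end, drop = FALSE]
}

#' Paste a cropped array back onto a blank canvas
#'
#' Inverse of [apply_crop()]: the window region holds `cropped`, everything
#' else is `fill` (background).
#'
#' @param cropped matrix previously extracted with the same `window`.
#' @param window a [crop_window()].
#' @param canvas_size integer `c(height, width)` of the full canvas.
#' @param fill background value (default 0).
#' @return full-size matrix.
#' @export
paste_back <- function(cropped, window, canvas_size, fill = 0L) {
  assert_that(
    nrow(cropped) == window$row_end - window$row_start &&
      ncol(cropped) == window$col_end - window$col_start,
    "paste_back: cropped shape does not match window", "discseg_shape_error"
  )
  assert_that(window$row_end <= canvas_size[1] && window$col_end <= canvas_size[2],
              "paste_back: window exceeds canvas", "discseg_shape_error")
  out <- matrix(fill, canvas_size[1], canvas_size[2])
  out[(window$row_start + 1L):window$row_end,
      (window$col_start + 1L):window$col_end] <- cropped
  out
}
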