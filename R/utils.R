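# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_discseg <- function(msg, class) {
  stop(structure(
    class = c(class, "discseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "discseg_invalid_argument") {
  if (!isTRUE(cond)) abort_discseg(msg, class)
  invisible(TRUE)
}

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic generators do not disturb user code.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Reproducible fan-out of one master seed into per-purpose child seeds.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 9973) %% 2147483629)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Resize a 2D field
#'
#' Bilinear interpolation for intensity images, nearest neighbour for label
#' masks (which must not invent intermediate label values). Pixel centres are
#' aligned so that the corner pixels of input and output correspond.
#'
#' @param x numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return resized matrix.
#' @keywords internal
resize_bilinear <- function(x, out_h, out_w) {
  h <- nrow(x); w <- ncol(x)
  if (h == out_h && w == out_w) return(x)
  ry <- if (out_h == 1) rep(1, out_h) else seq(1, h, length.out = out_h)
  rx <- if (out_w == 1) rep(1, out_w) else seq(1, w, length.out = out_w)
  y0 <- pmin(floor(ry), h - 1L); y1 <- y0 + 1; fy <- ry - y0
  x0 <- pmin(floor(rx), w - 1L); x1 <- x0 + 1; fx <- rx - x0
  if (h == 1) { y0 <- y1 <- rep(1, out_h); fy <- rep(0, out_h) }
  if (w == 1) { x0 <- x1 <- rep(1, out_w); fx <- rep(0, out_w) }
  a <- x[y0, x0, drop = FALSE]; b <- x[y0, x1, drop = FALSE]
  c <- x[y1, x0, drop = FALSE]; d <- x[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c * wy * (1 - wx) + d * wy * wx
}

#' @rdname resize_bilinear
#' @keywords internal
resize_nearest <- function(x, out_h, out_w) {
  h <- nrow(x); w <- ncol(x)
  if (h == out_h && w == out_w) return(x)
  ry <- pmin(pmax(round(seq(1, h, length.out = out_h)), 1), h)
  rx <- pmin(pmax(round(seq(1, w, length.out = out_w)), 1), w)
  x[ry, rx, drop = FALSE]
}

is_binary_mask <- function(x) {
  is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))
}

as_binary <- function(x) {
  if (is.logical(x)) return(x)
  x != 0
}
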