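# Minimal CPU neural-network layer stack.
#
# No deep-learning framework is assumed: convolutions are expressed as
# im2col gathers followed by BLAS matrix products, which is fast enough for
# the desk-scale networks this package trains. A feature batch is a single
# (n*H*W) x C matrix whose rows are sample-major, column-major pixels, with
# the geometry carried in attribute "gdim" = c(n, H, W). Each layer is an
# environment exposing forward/backward closures; parameters are
# environments holding value, grad and Adam state.

.geom_cache <- new.env(parent = emptyenv())

gdim <- function(x) attr(x, "gdim")

set_gdim <- function(x, g) {
  attr(x, "gdim") <- g
  x
}

# scale / shift columns of a batch matrix by a per-channel vector
colscale <- function(x, v) x * rep(v, each = nrow(x))
colshift <- function(x, v) x + rep(v, each = nrow(x))

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- 0
  p$v <- 0
  p
}

collect_params <- function(mod) {
  out <- mod$params %||% list()
  for (ch in mod$children %||% list()) out <- c(out, collect_params(ch))
  out
}

# --- cached pixel-index geometry ---------------------------------------------

geom_key <- function(...) paste(..., sep = "x")

# indices of the 3x3 neighbourhood of every pixel inside a zero-padded
# (H+2) x (W+2) layout, plus the positions of the unpadded pixels
idx_conv3 <- function(n, H, W) {
  key <- geom_key("c3", n, H, W)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  s <- rep(seq_len(n) - 1L, each = H * W)
  c0 <- rep(rep(seq_len(W) - 1L, each = H), times = n)
  r <- rep(seq_len(H), times = W * n)
  base <- s * (Hp * Wp)
  shifts <- vector("list", 9L)
  o <- 0L
  for (dc in -1L:1L) {
    for (dr in -1L:1L) {
      o <- o + 1L
      shifts[[o]] <- base + (c0 + 1L + dc) * Hp + (r + dr + 1L)
    }
  }
  g <- list(inner = base + (c0 + 1L) * Hp + r + 1L,
            shifts = shifts, npad = n * Hp * Wp)
  .geom_cache[[key]] <- g
  g
}

# parent-row indices of the four children of every 2x2 pooling window
idx_pool2 <- function(n, H, W) {
  key <- geom_key("p2", n, H, W)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  H2 <- H %/% 2L; W2 <- W %/% 2L
  s <- rep(seq_len(n) - 1L, each = H2 * W2)
  oc <- rep(rep(seq_len(W2), each = H2), times = n)
  or <- rep(seq_len(H2), times = W2 * n)
  base <- s * (H * W)
  g <- list()
  k <- 0L
  for (b in 0L:1L) {
    for (a in 0L:1L) {
      k <- k + 1L
      g[[k]] <- base + (2L * oc - 2L + b) * H + (2L * or - 1L + a)
    }
  }
  .geom_cache[[key]] <- g
  g
}

# child-row indices written by a 2x2 stride-2 transposed convolution
idx_up2 <- function(n, H, W) {
  key <- geom_key("u2", n, H, W)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  s <- rep(seq_len(n) - 1L, each = H * W)
  c0 <- rep(rep(seq_len(W) - 1L, each = H), times = n)
  r <- rep(seq_len(H), times = W * n)
  base <- s * (4L * H * W)
  g <- list()
  k <- 0L
  for (db in 0L:1L) {
    for (da in 0L:1L) {
      k <- k + 1L
      g[[k]] <- base + (2L * c0 + db) * (2L * H) + (2L * r - 1L + da)
    }
  }
  .geom_cache[[key]] <- g
  g
}

im2col3 <- function(x) {
  g <- gdim(x)
  ix <- idx_conv3(g[1], g[2], g[3])
  C <- ncol(x)
  padded <- matrix(0, ix$npad, C)
  padded[ix$inner, ] <- x
  do.call(cbind, lapply(ix$shifts, function(i) padded[i, , drop = FALSE]))
}

# --- layers ------------------------------------------------------------------

conv_mod <- function(cin, cout, k = 3L) {
  stopifnot(k %in% c(1L, 3L))
  m <- new.env()
  m$k <- k
  m$cin <- cin
  m$cout <- cout
  m$W <- new_param(matrix(stats::rnorm(k * k * cin * cout,
                                       sd = sqrt(2 / (k * k * cin))),
                          k * k * cin, cout))
  m$b <- new_param(numeric(cout))
  m$params <- list(m$W, m$b)
  m$forward <- function(x, training = FALSE) {
    m$x <- x
    g <- gdim(x)
    if (k == 3L) {
      set_gdim(.conv3_fwd(x, m$W$value, m$b$value, g[1], g[2], g[3]), g)
    } else {
      set_gdim(colshift(x %*% m$W$value, m$b$value), g)
    }
  }
  m$backward <- function(dy) {
    x <- m$x
    g <- gdim(x)
    if (k == 1L) {
      m$b$grad <- colSums(dy)
      m$W$grad <- crossprod(x, dy)
      return(set_gdim(dy %*% t(m$W$value), g))
    }
    r <- .conv3_bwd(x, m$W$value, dy, g[1], g[2], g[3])
    m$W$grad <- r$dW
    m$b$grad <- as.vector(r$db)
    set_gdim(r$dx, g)
  }
  m
}

# pure-R reference 3x3 convolution via im2col; the independent check the
# compiled kernel is tested against
conv3_fwd_ref <- function(x, W, b) {
  set_gdim(colshift(im2col3(x) %*% W, b), gdim(x))
}

bn_mod <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- new.env()
  m$gamma <- new_param(rep(1, C))
  m$beta <- new_param(numeric(C))
  m$params <- list(m$gamma, m$beta)
  m$run_mean <- numeric(C)
  m$run_var <- rep(1, C)
  m$forward <- function(x, training = FALSE) {
    if (training) {
      mu <- colMeans(x)
      v <- pmax(colMeans(x * x) - mu * mu, 0)
      m$run_mean <- (1 - momentum) * m$run_mean + momentum * mu
      m$run_var <- (1 - momentum) * m$run_var + momentum * v
      m$invstd <- 1 / sqrt(v + eps)
      mu_use <- mu
      invstd_use <- m$invstd
    } else {
      mu_use <- m$run_mean
      invstd_use <- 1 / sqrt(m$run_var + eps)
    }
    r <- .bn_fwd(x, invstd_use, mu_use, m$gamma$value, m$beta$value)
    m$xhat <- r$xhat
    set_gdim(r$y, gdim(x))
  }
  m$backward <- function(dy) {
    r <- .bn_bwd(dy, m$xhat, m$gamma$value, m$invstd)
    m$gamma$grad <- as.vector(r$dgamma)
    m$beta$grad <- as.vector(r$dbeta)
    set_gdim(r$dx, gdim(dy))
  }
  m
}

relu_mod <- function() {
  m <- new.env()
  m$forward <- function(x, training = FALSE) {
    m$pos <- x > 0
    set_gdim(x * m$pos, gdim(x))
  }
  m$backward <- function(dy) set_gdim(dy * m$pos, gdim(dy))
  m
}

pool_mod <- function() {
  m <- new.env()
  m$forward <- function(x, training = FALSE) {
    g <- gdim(x)
    stopifnot(g[2] %% 2L == 0L, g[3] %% 2L == 0L)
    ix <- idx_pool2(g[1], g[2], g[3])
    C <- ncol(x)
    best <- x[ix[[1]], , drop = FALSE]
    widx <- matrix(ix[[1]], nrow(best), C)
    for (k in 2:4) {
      cand <- x[ix[[k]], , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      widx[upd] <- matrix(ix[[k]], nrow(best), C)[upd]
    }
    m$widx <- widx
    m$parent_rows <- nrow(x)
    set_gdim(best, c(g[1], g[2] %/% 2L, g[3] %/% 2L))
  }
  m$backward <- function(dy) {
    g <- gdim(dy)
    C <- ncol(dy)
    dxv <- numeric(m$parent_rows * C)
    lin <- as.vector(m$widx + rep(0:(C - 1L), each = nrow(dy)) * m$parent_rows)
    dxv[lin] <- as.vector(dy)
    set_gdim(matrix(dxv, m$parent_rows, C), c(g[1], g[2] * 2L, g[3] * 2L))
  }
  m
}

upconv_mod <- function(cin, cout) {
  m <- new.env()
  m$cout <- cout
  m$W <- new_param(matrix(stats::rnorm(cin * 4L * cout, sd = sqrt(2 / cin)),
                          cin, 4L * cout))
  m$b <- new_param(numeric(cout))
  m$params <- list(m$W, m$b)
  m$forward <- function(x, training = FALSE) {
    g <- gdim(x)
    m$x <- x
    y4 <- x %*% m$W$value
    ix <- idx_up2(g[1], g[2], g[3])
    y <- matrix(0, nrow(x) * 4L, cout)
    for (o in 1:4) {
      y[ix[[o]], ] <- y4[, ((o - 1L) * cout + 1L):(o * cout), drop = FALSE]
    }
    set_gdim(colshift(y, m$b$value), c(g[1], g[2] * 2L, g[3] * 2L))
  }
  m$backward <- function(dy) {
    g <- gdim(m$x)
    ix <- idx_up2(g[1], g[2], g[3])
    dy4 <- do.call(cbind, lapply(1:4, function(o) dy[ix[[o]], , drop = FALSE]))
    m$W$grad <- crossprod(m$x, dy4)
    m$b$grad <- colSums(dy)
    set_gdim(dy4 %*% t(m$W$value), g)
  }
  m
}

seq_mod <- function(...) {
  mods <- list(...)
  m <- new.env()
  m$children <- mods
  m$forward <- function(x, training = FALSE) {
    for (mm in mods) x <- mm$forward(x, training)
    x
  }
  m$backward <- function(dy) {
    for (mm in rev(mods)) dy <- mm$backward(dy)
    dy
  }
  m
}

# --- optimiser ---------------------------------------------------------------

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
}

# --- batch packing -----------------------------------------------------------

# inputs: list of H x W matrices or H x W x C arrays (equal shapes)
batch_from_arrays <- function(inputs) {
  d <- dim(inputs[[1]])
  H <- d[1]; W <- d[2]
  C <- if (length(d) == 3L) d[3] else 1L
  n <- length(inputs)
  X <- matrix(0, n * H * W, C)
  for (s in seq_len(n)) {
    rows <- ((s - 1L) * H * W + 1L):(s * H * W)
    a <- inputs[[s]]
    if (length(dim(a)) == 3L) {
      for (ch in seq_len(C)) X[rows, ch] <- as.vector(a[, , ch])
    } else {
      X[rows, 1L] <- as.vector(a)
    }
  }
  set_gdim(X, c(n, H, W))
}

# split a single-channel batch back into H x W matrices
batch_to_matrices <- function(x) {
  g <- gdim(x)
  lapply(seq_len(g[1]), function(s) {
    rows <- ((s - 1L) * g[2] * g[3] + 1L):(s * g[2] * g[3])
    matrix(x[rows, 1L], g[2], g[3])
  })
}
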