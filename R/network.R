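# MultiResUNet encoder-decoder and the focal loss.
#
# The architecture follows the MultiResUNet family: at every level the
# classic double convolution is replaced by a MultiRes block — three chained
# 3x3 convolutions whose outputs are concatenated and fused with a
# 1x1-convolved residual shortcut — and every skip connection is replaced by
# a Res path, a chain of 3x3 convolutions with 1x1 residual shortcuts whose
# length shrinks with depth. The level width W = alpha * base_width * 2^level
# is split across the three branches approximately 1/6 : 1/3 : 1/2. A final
# 1x1 convolution plus sigmoid yields a per-pixel foreground probability;
# instances are recovered afterwards by connected-component labeling.

#' Network configuration
#'
#' @param input_channels 1 for stage 1 (grayscale crop), 3 for stage 2
#'   (image + two distance maps).
#' @param n_levels number of down/up-sampling stages (default 4).
#' @param base_width filters at the first level before the alpha scaling
#'   (>= 4).
#' @param alpha MultiRes width-scaling factor (default 1.67, the reference
#'   convention).
#' @param output_classes number of foreground classes (1: foreground vs
#'   background).
#' @param seed seed for weight initialisation.
#' @return a `network_config` list.
#' @export
network_config <- function(input_channels = 1L, n_levels = 4L, base_width = 8L,
                           alpha = 1.67, output_classes = 1L, seed = 42L) {
  assert_that(n_levels >= 1, "n_levels must be >= 1")
  assert_that(base_width >= 4, "base_width must be >= 4")
  assert_that(alpha > 0, "alpha must be positive")
  assert_that(output_classes == 1L, "only single-foreground-class output is supported")
  structure(list(input_channels = as.integer(input_channels),
                 n_levels = as.integer(n_levels),
                 base_width = as.integer(base_width),
                 alpha = alpha,
                 output_classes = as.integer(output_classes),
                 seed = as.integer(seed)),
            class = "network_config")
}

# branch widths 1/6 : 1/3 : 1/2 of W, round-to-nearest, remainder to the
# widest branch
split_widths <- function(W) {
  total <- round(W)
  w1 <- round(W / 6)
  w2 <- round(W / 3)
  w3 <- total - w1 - w2
  if (w1 < 1 || w2 < 1 || w3 < 1) {
    abort_discseg(
      sprintf("MultiRes branch widths round to zero channels (W = %.2f); increase base_width or alpha", W),
      "discseg_config_error"
    )
  }
  c(w1, w2, w3)
}

conv_bn_relu <- function(cin, cout, k = 3L) {
  seq_mod(conv_mod(cin, cout, k), bn_mod(cout), relu_mod())
}

multires_block <- function(cin, W) {
  ws <- split_widths(W)
  m <- new.env()
  m$widths <- ws
  m$out_channels <- sum(ws)
  m$ca <- conv_bn_relu(cin, ws[1])
  m$cb <- conv_bn_relu(ws[1], ws[2])
  m$cc <- conv_bn_relu(ws[2], ws[3])
  m$shortcut <- seq_mod(conv_mod(cin, sum(ws), 1L), bn_mod(sum(ws)))
  m$out_relu <- relu_mod()
  m$out_bn <- bn_mod(sum(ws))
  m$children <- list(m$ca, m$cb, m$cc, m$shortcut, m$out_relu, m$out_bn)
  m$forward <- function(x, training = FALSE) {
    a <- m$ca$forward(x, training)
    b <- m$cb$forward(a, training)
    cc <- m$cc$forward(b, training)
    cat <- set_gdim(cbind(a, b, cc), gdim(x))
    s <- m$shortcut$forward(x, training)
    m$out_bn$forward(m$out_relu$forward(set_gdim(cat + s, gdim(x)), training),
                     training)
  }
  m$backward <- function(dy) {
    dz <- m$out_relu$backward(m$out_bn$backward(dy))
    ws <- m$widths
    da <- dz[, seq_len(ws[1]), drop = FALSE]
    db <- dz[, ws[1] + seq_len(ws[2]), drop = FALSE]
    dc <- dz[, ws[1] + ws[2] + seq_len(ws[3]), drop = FALSE]
    g <- gdim(dy)
    db <- db + m$cc$backward(set_gdim(dc, g))
    da <- da + m$cb$backward(set_gdim(db, g))
    dx <- m$ca$backward(set_gdim(da, g)) + m$shortcut$backward(set_gdim(dz, g))
    set_gdim(dx, g)
  }
  m
}

res_path_unit <- function(C) {
  m <- new.env()
  m$conv3 <- seq_mod(conv_mod(C, C, 3L), bn_mod(C))
  m$conv1 <- seq_mod(conv_mod(C, C, 1L), bn_mod(C))
  m$out_relu <- relu_mod()
  m$children <- list(m$conv3, m$conv1, m$out_relu)
  m$forward <- function(x, training = FALSE) {
    m$out_relu$forward(
      set_gdim(m$conv3$forward(x, training) + m$conv1$forward(x, training),
               gdim(x)),
      training
    )
  }
  m$backward <- function(dy) {
    dz <- m$out_relu$backward(dy)
    set_gdim(m$conv3$backward(dz) + m$conv1$backward(dz), gdim(dy))
  }
  m
}

res_path <- function(C, length) {
  do.call(seq_mod, lapply(seq_len(length), function(i) res_path_unit(C)))
}

sigmoid_mod <- function() {
  m <- new.env()
  m$forward <- function(x, training = FALSE) {
    m$p <- set_gdim(1 / (1 + exp(-x)), gdim(x))
    m$p
  }
  m$backward <- function(dp) set_gdim(dp * m$p * (1 - m$p), gdim(dp))
  m
}

#' Build a MultiResUNet model
#'
#' @param config a [network_config()].
#' @return a model handle (environment) usable with [train_network()] and
#'   [predict_network()].
#' @export
build_multiresunet <- function(config) {
  stopifnot(inherits(config, "network_config"))
  with_seed(config$seed, build_multiresunet_impl(config))
}

build_multiresunet_impl <- function(config) {
  L <- config$n_levels
  level_W <- config$alpha * config$base_width * 2^(0:L)
  model <- new.env()
  model$config <- config
  enc <- vector("list", L)
  pools <- vector("list", L)
  paths <- vector("list", L)
  ups <- vector("list", L)
  dec <- vector("list", L)
  cin <- config$input_channels
  U <- integer(L + 1L)
  for (l in seq_len(L)) {
    enc[[l]] <- multires_block(cin, level_W[l])
    U[l] <- enc[[l]]$out_channels
    pools[[l]] <- pool_mod()
    paths[[l]] <- res_path(U[l], L - l + 1L)
    cin <- U[l]
  }
  bott <- multires_block(cin, level_W[L + 1L])
  U[L + 1L] <- bott$out_channels
  for (l in L:1) {
    up_in <- if (l == L) U[L + 1L] else dec[[l + 1L]]$out_channels
    ups[[l]] <- upconv_mod(up_in, U[l])
    dec[[l]] <- multires_block(2L * U[l], level_W[l])
  }
  head <- conv_mod(dec[[1L]]$out_channels, config$output_classes, 1L)
  out <- sigmoid_mod()
  model$enc <- enc; model$pools <- pools; model$paths <- paths
  model$bott <- bott; model$ups <- ups; model$dec <- dec
  model$head <- head; model$out <- out
  model$children <- c(enc, pools, paths, list(bott), ups, dec,
                      list(head, out))
  model$param_list <- collect_params(model)
  model$adam_t <- 0L

  model$forward <- function(x, training = FALSE) {
    g <- gdim(x)
    assert_that(ncol(x) == config$input_channels,
                sprintf("input has %d channels, model expects %d",
                        ncol(x), config$input_channels),
                "discseg_shape_error")
    assert_that(g[2] %% 2^L == 0L && g[3] %% 2^L == 0L,
                sprintf("input sides must be divisible by 2^%d", L),
                "discseg_shape_error")
    skips <- vector("list", L)
    for (l in seq_len(L)) {
      x <- enc[[l]]$forward(x, training)
      skips[[l]] <- paths[[l]]$forward(x, training)
      x <- pools[[l]]$forward(x, training)
    }
    x <- bott$forward(x, training)
    for (l in L:1) {
      u <- ups[[l]]$forward(x, training)
      x <- dec[[l]]$forward(set_gdim(cbind(u, skips[[l]]), gdim(u)), training)
    }
    out$forward(head$forward(x, training), training)
  }

  model$backward <- function(dp) {
    dy <- head$backward(out$backward(dp))
    dskips <- vector("list", L)
    for (l in 1:L) {
      dcat <- dec[[l]]$backward(dy)
      Ul <- U[l]
      du <- set_gdim(dcat[, seq_len(Ul), drop = FALSE], gdim(dcat))
      dskips[[l]] <- set_gdim(dcat[, Ul + seq_len(Ul), drop = FALSE],
                              gdim(dcat))
      dy <- ups[[l]]$backward(du)
    }
    dy <- bott$backward(dy)
    for (l in L:1) {
      dy <- pools[[l]]$backward(dy)
      dy <- set_gdim(dy + paths[[l]]$backward(dskips[[l]]), gdim(dy))
      dy <- enc[[l]]$backward(dy)
    }
    dy
  }
  model
}

#' Number of trainable parameters of a model
#'
#' @param model a model handle from [build_multiresunet()].
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$param_list, function(p) length(p$value), numeric(1)))
}

#' Focal loss for binary per-pixel classification
#'
#' `FL(p_t) = -alpha * (1 - p_t)^gamma * log(p_t)` averaged over pixels,
#' with `p_t` the predicted probability of the true class (`prob` on
#' foreground pixels, `1 - prob` on background). With `gamma = 0` and
#' `alpha = 1` this reduces to mean binary cross-entropy.
#'
#' @param prob predicted foreground probabilities (any numeric array).
#' @param target binary mask of the same shape.
#' @param focal_alpha loss weight in (0, 1].
#' @param focal_gamma focusing exponent >= 0.
#' @param eps clamping epsilon for numerical safety.
#' @return non-negative scalar loss.
#' @export
focal_loss <- function(prob, target, focal_alpha = 0.25, focal_gamma = 2,
                       eps = 1e-7) {
  assert_that(length(prob) == length(target),
              "focal_loss: prob and target shapes differ",
              "discseg_shape_error")
  p <- pmin(pmax(as.vector(prob), eps), 1 - eps)
  t <- as.vector(as_binary(target))
  pt <- ifelse(t, p, 1 - p)
  mean(-focal_alpha * (1 - pt)^focal_gamma * log(pt))
}

# gradient of the mean focal loss w.r.t. prob (same shape as prob)
focal_loss_grad <- function(prob, target, focal_alpha, focal_gamma,
                            eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  t <- as_binary(target)
  pt <- ifelse(t, p, 1 - p)
  term <- (1 - pt)^focal_gamma / pt
  if (focal_gamma > 0) {
    term <- term - focal_gamma * (1 - pt)^(focal_gamma - 1) * log(pt)
  }
  dpt <- -focal_alpha * term
  sign <- ifelse(t, 1, -1)
  dpt * sign / length(p)
}

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param focal_alpha,focal_gamma focal-loss hyperparameters (reference
#'   defaults 0.25 and 2).
#' @param seed seed for shuffling (weight init is seeded by
#'   [network_config()]).
#' @param binarize_threshold probability cutoff used by [binarize()].
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 60L, batch_size = 8L, learning_rate = 1e-3,
                         focal_alpha = 0.25, focal_gamma = 2, seed = 42L,
                         binarize_threshold = 0.5) {
  assert_that(epochs >= 1 && batch_size >= 1 && learning_rate > 0,
              "epochs, batch_size and learning_rate must be positive")
  assert_that(focal_alpha > 0 && focal_alpha <= 1,
              "focal_alpha must be in (0, 1]")
  assert_that(focal_gamma >= 0, "focal_gamma must be >= 0")
  assert_that(binarize_threshold > 0 && binarize_threshold < 1,
              "binarize_threshold must be in (0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 seed = as.integer(seed),
                 binarize_threshold = binarize_threshold),
            class = "train_config")
}

#' Train a model with Adam on the focal loss
#'
#' @param model a model handle from [build_multiresunet()] (updated in
#'   place).
#' @param dataset non-empty list of `list(input =, target =)` pairs, where
#'   `input` is an `H x W` matrix or `H x W x C` array and `target` a binary
#'   `H x W` mask.
#' @param cfg a [train_config()].
#' @param verbose print the per-epoch loss.
#' @return the model, with `$loss_trace` holding the per-epoch mean loss.
#' @export
train_network <- function(model, dataset, cfg = train_config(),
                          verbose = FALSE) {
  assert_that(length(dataset) > 0, "train_network: empty dataset")
  with_seed(cfg$seed, {
    n <- length(dataset)
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      tot <- 0
      starts <- seq(1L, n, by = cfg$batch_size)
      for (st in starts) {
        sel <- perm[st:min(st + cfg$batch_size - 1L, n)]
        X <- batch_from_arrays(lapply(dataset[sel], `[[`, "input"))
        tvec <- unlist(lapply(dataset[sel],
                              function(d) as.vector(as_binary(d$target))))
        prob <- model$forward(X, training = TRUE)
        loss <- focal_loss(prob, tvec, cfg$focal_alpha, cfg$focal_gamma)
        if (!is.finite(loss)) {
          abort_discseg(sprintf(
            "training diverged: non-finite loss at epoch %d", ep),
            "discseg_divergence")
        }
        dp <- matrix(focal_loss_grad(prob[, 1L], tvec,
                                     cfg$focal_alpha, cfg$focal_gamma),
                     ncol = 1L)
        model$backward(set_gdim(dp, gdim(prob)))
        model$adam_t <- model$adam_t + 1L
        adam_step(model$param_list, cfg$learning_rate, model$adam_t)
        tot <- tot + loss * length(sel)
      }
      trace[ep] <- tot / n
      if (verbose) message(sprintf("epoch %3d  loss %.6f", ep, trace[ep]))
    }
    model$loss_trace <- c(model$loss_trace, trace)
  })
  invisible(model)
}

#' Predict a per-pixel foreground probability field
#'
#' @param model a trained model handle.
#' @param input `H x W` matrix or `H x W x C` array matching the model's
#'   input channel count.
#' @return `H x W` matrix of probabilities in (0, 1).
#' @export
predict_network <- function(model, input) {
  X <- batch_from_arrays(list(input))
  prob <- model$forward(X, training = FALSE)
  batch_to_matrices(prob)[[1L]]
}

#' Binarize a probability field
#'
#' Marks pixels with probability `>= threshold` as foreground; monotone in
#' the threshold (higher threshold, smaller foreground).
#'
#' @param prob probability matrix.
#' @param threshold cutoff in (0, 1) (values outside are allowed and give
#'   all-foreground / all-background).
#' @return logical mask.
#' @export
binarize <- function(prob, threshold = 0.5) {
  prob >= threshold
}

#' Save / load a model checkpoint
#'
#' Weights, batch-norm running statistics and the Adam step counter go to a
#' single file; the architecture configuration is serialized alongside as
#' JSON (`<path>.json`), so a checkpoint is self-describing.
#'
#' @param model a model handle.
#' @param path checkpoint file path.
#' @return `load_model`: a reconstructed model handle.
#' @export
save_model <- function(model, path) {
  state <- list(
    values = lapply(model$param_list, function(p) p$value),
    bn = lapply(collect_bn(model), function(b) list(b$run_mean, b$run_var)),
    adam_t = model$adam_t,
    loss_trace = model$loss_trace
  )
  saveRDS(state, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfgl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- do.call(network_config, cfgl)
  model <- build_multiresunet(config)
  state <- readRDS(path)
  stopifnot(length(state$values) == length(model$param_list))
  for (i in seq_along(state$values)) {
    model$param_list[[i]]$value <- state$values[[i]]
  }
  bns <- collect_bn(model)
  stopifnot(length(state$bn) == length(bns))
  for (i in seq_along(bns)) {
    bns[[i]]$run_mean <- state$bn[[i]][[1L]]
    bns[[i]]$run_var <- state$bn[[i]][[2L]]
  }
  model$adam_t <- state$adam_t
  model$loss_trace <- state$loss_trace
  model
}

collect_bn <- function(mod) {
  out <- list()
  if (!is.null(mod$run_mean)) out <- list(mod)
  for (ch in mod$children %||% list()) out <- c(out, collect_bn(ch))
  out
}
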