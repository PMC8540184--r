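# Two-stage cascade orchestration.
#
# Stage 1 learns the lower two discs from fixed-size native-resolution
# windows cut around them in the training images; stage 2 learns the upper disc from the full image fused
# with Euclidean distance maps of the lower discs (teacher forcing by
# default). At inference, stage 1 runs on the full image and the two
# bottom-most instances are retained (the training-time crop has no
# ground-truth box at test time, and bottom-two filtering is itself the
# noise-suppression step that removes redundant discs); their distance maps
# condition stage 2, whose top-most instance becomes disc 1.

#' Pipeline configuration
#'
#' Defaults are sized for the 64x64 phantom world (tiny networks trainable
#' on one CPU); scale `base_width`, `epochs` and `stage1_input_size` up for
#' larger images.
#'
#' @param seed master seed; fans out to phantom generation, weight
#'   initialisation and shuffling.
#' @param margin_frac stage-1 crop margin (fraction of the lower-disc box).
#' @param stage1_input_size side of the fixed square window the stage-1
#'   training crops are cut at (native resolution; resized only if the
#'   lower-disc box cannot fit).
#' @param stage1_network,stage2_network [network_config()]s for the two
#'   stages (stage 1 has 1 input channel, stage 2 has 3).
#' @param stage1_train,stage2_train [train_config()]s for the two stages.
#' @param use_ground_truth_lower teacher forcing: build stage-2 training
#'   distance maps from reference lower discs (default) rather than stage-1
#'   predictions.
#' @param min_instance_area predicted instances smaller than this many
#'   pixels are dropped before instance counting (speckle guard; applied
#'   identically to the cascade and the single-stage baseline).
#' @param include_single_stage also train a capacity-matched single-stage
#'   baseline that segments all three discs directly.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            margin_frac = 0.25,
                            stage1_input_size = 32L,
                            stage1_network = network_config(
                              input_channels = 1L, n_levels = 2L,
                              base_width = 6L),
                            stage2_network = network_config(
                              input_channels = 3L, n_levels = 2L,
                              base_width = 6L),
                            stage1_train = train_config(epochs = 40L),
                            stage2_train = train_config(epochs = 40L),
                            use_ground_truth_lower = TRUE,
                            min_instance_area = 4L,
                            include_single_stage = FALSE) {
  assert_that(margin_frac >= 0, "margin_frac must be non-negative")
  assert_that(stage1_network$input_channels == 1L,
              "stage 1 takes the grayscale image (1 channel)")
  assert_that(stage2_network$input_channels == 3L,
              "stage 2 takes image + two distance maps (3 channels)")
  structure(list(seed = as.integer(seed), margin_frac = margin_frac,
                 stage1_input_size = as.integer(stage1_input_size),
                 stage1_network = stage1_network,
                 stage2_network = stage2_network,
                 stage1_train = stage1_train, stage2_train = stage2_train,
                 use_ground_truth_lower = use_ground_truth_lower,
                 min_instance_area = as.integer(min_instance_area),
                 include_single_stage = include_single_stage),
            class = "pipeline_config")
}

#' Build stage-1 training pairs (cropped lower-disc windows)
#'
#' Cuts a fixed-size window around the reference lower-disc pair (instances
#' 2 and 3) at native resolution, so the training scale matches full-image
#' inference. The window is centred on the expanded lower-disc bounding box
#' with a small random placement jitter (deterministic per sample), which
#' prevents the network from learning "discs sit at the window centre".
#' Only when the box does not fit the window is the crop resized instead
#' (bilinear image, nearest mask).
#'
#' @param samples list of samples with `$image` and labeled `$mask`.
#' @param margin_frac crop margin (see [lower_disc_crop()]).
#' @param input_size square network input size.
#' @param jitter_seed seed for the placement jitter (`NULL` disables it).
#' @return list of `list(input, target, window)` pairs; `window` is the
#'   [crop_window()] actually cut.
#' @export
make_stage1_training_pairs <- function(samples, margin_frac = 0.25,
                                       input_size = 32L, jitter_seed = 1L) {
  lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    box <- lower_disc_crop(s$mask, margin_frac)
    H <- nrow(s$image); W <- ncol(s$image)
    bh <- box$row_end - box$row_start
    bw <- box$col_end - box$col_start
    if (bh <= input_size && bw <= input_size &&
        H >= input_size && W >= input_size) {
      jr <- jc <- 0
      if (!is.null(jitter_seed)) {
        j <- with_seed(derive_seed(jitter_seed, i),
                       stats::runif(2, -input_size / 4, input_size / 4))
        jr <- j[1]; jc <- j[2]
      }
      r0 <- round((box$row_start + box$row_end - input_size) / 2 + jr)
      c0 <- round((box$col_start + box$col_end - input_size) / 2 + jc)
      r0 <- min(max(r0, 0L), H - input_size)
      c0 <- min(max(c0, 0L), W - input_size)
      w <- crop_window(r0, r0 + input_size, c0, c0 + input_size)
      img <- apply_crop(s$image, w)
      tgt <- apply_crop(s$mask == 2L | s$mask == 3L, w)
    } else {
      w <- box
      img <- resize_bilinear(apply_crop(s$image, w), input_size, input_size)
      tgt <- resize_nearest(apply_crop((s$mask == 2L) + (s$mask == 3L), w),
                            input_size, input_size) != 0
    }
    list(input = img, target = tgt, window = w)
  })
}

#' Build stage-2 training pairs (image + distance maps, upper-disc target)
#'
#' @param samples list of samples with `$image` and labeled `$mask` (labels
#'   1..3 complete).
#' @param use_ground_truth_lower distance maps from reference lower discs
#'   (teacher forcing, default); otherwise from stage-1 predictions.
#' @param stage1_model,threshold needed when
#'   `use_ground_truth_lower = FALSE`.
#' @return list of `list(input = HxWx3 array, target)` pairs.
#' @export
make_stage2_training_pairs <- function(samples, use_ground_truth_lower = TRUE,
                                       stage1_model = NULL, threshold = 0.5) {
  lapply(samples, function(s) {
    if (use_ground_truth_lower) {
      m2 <- s$mask == 2L
      m3 <- s$mask == 3L
    } else {
      st1 <- stage1_lower_instances(s$image, stage1_model, threshold)
      assert_that(!st1$failed,
                  "stage-1 prediction found < 2 lower discs for a training image",
                  "discseg_empty_mask")
      m2 <- st1$mask2
      m3 <- st1$mask3
    }
    fused <- fuse_channels(s$image, distance_transform(m2),
                           distance_transform(m3))
    list(input = fused, target = s$mask == 1L)
  })
}

# run a stage model (or an oracle function) on an input
predict_stage <- function(model, input) {
  if (is.function(model)) model(input) else predict_network(model, input)
}

# drop instances below min_area pixels and relabel top-to-bottom
filter_small_instances <- function(lab, min_area) {
  if (min_area <= 1L || !any(lab > 0)) return(lab)
  counts <- tabulate(lab[lab > 0])
  drop <- which(counts < min_area)
  if (!length(drop)) return(lab)
  lab[lab %in% drop] <- 0L
  relabel_top_to_bottom(lab)
}

# stage-1 inference on the full image: binarize, label, keep the two
# bottom-most instances
stage1_lower_instances <- function(image, model, threshold = 0.5,
                                   min_area = 1L) {
  lab <- connected_components(binarize(predict_stage(model, image), threshold))
  lab <- filter_small_instances(lab, min_area)
  n <- if (length(lab)) max(lab) else 0L
  if (n < 2L) {
    return(list(failed = TRUE, n_instances = n, labels = lab))
  }
  # labels are already ordered top-to-bottom, so the bottom two are n-1, n
  list(failed = FALSE, n_instances = n, labels = lab,
       mask2 = lab == n - 1L, mask3 = lab == n)
}

#' Two-stage inference on one image
#'
#' Stage 1 predicts lower-disc foreground on the full image; if more than
#' two instances emerge, the two bottom-most (by centroid row) are retained.
#' Their distance maps are fused with the image for stage 2; if stage 2
#' yields several instances, the top-most is retained. A stage-1 result with
#' fewer than two instances, or an empty stage-2 result, flags the image as
#' a failed prediction (never an error): it is evaluated as-is with
#' `b_i = 0`.
#'
#' Both models may be replaced by functions `input -> probability matrix`
#' (oracle mode), which is used to test that the pipeline plumbing is
#' distortion-free.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param stage1_model,stage2_model trained models (or oracle functions).
#' @param cfg a [pipeline_config()].
#' @return a `segmentation_result`: `mask` (labels 1..3), `failed`, `flags`
#'   (per-stage raw instance counts), `provenance`.
#' @export
infer <- function(image, stage1_model, stage2_model, cfg = pipeline_config()) {
  thr1 <- cfg$stage1_train$binarize_threshold
  thr2 <- cfg$stage2_train$binarize_threshold
  st1 <- stage1_lower_instances(image, stage1_model, thr1,
                                cfg$min_instance_area)
  H <- nrow(image); W <- ncol(image)
  mask <- matrix(0L, H, W)
  failed <- st1$failed
  n2_raw <- NA_integer_
  if (!st1$failed) {
    fused <- fuse_channels(image, distance_transform(st1$mask2),
                           distance_transform(st1$mask3))
    lab2 <- connected_components(binarize(predict_stage(stage2_model, fused),
                                          thr2))
    n2_raw <- if (length(lab2)) as.integer(max(lab2)) else 0L
    if (n2_raw == 0L) {
      failed <- TRUE
    } else {
      mask[lab2 == 1L] <- 1L          # top-most stage-2 instance
    }
    mask[st1$mask2] <- 2L
    mask[st1$mask3] <- 3L
  } else if (st1$n_instances > 0L) {
    mask[st1$labels == 1L] <- 2L      # best effort for the record
  }
  out <- relabel_top_to_bottom(mask)
  structure(list(
    mask = out, failed = failed,
    flags = list(stage1_instances = st1$n_instances,
                 stage2_instances = n2_raw,
                 stage1_filtered = isTRUE(st1$n_instances > 2L)),
    provenance = list(upper = "stage2", lower = "stage1")
  ), class = "segmentation_result")
}

#' Single-stage inference (baseline): all three discs directly
#'
#' @param image grayscale matrix.
#' @param model model trained on all-disc foreground targets.
#' @param threshold binarization cutoff.
#' @param min_area speckle guard, as in [pipeline_config()].
#' @return a `segmentation_result` (no bottom-two/top-most filtering;
#'   `failed` when no foreground at all).
#' @export
infer_single_stage <- function(image, model, threshold = 0.5,
                               min_area = 1L) {
  lab <- connected_components(binarize(predict_stage(model, image), threshold))
  lab <- filter_small_instances(lab, min_area)
  n <- if (length(lab)) max(lab) else 0L
  structure(list(mask = lab, failed = n == 0L,
                 flags = list(instances = n), provenance = "single-stage"),
            class = "segmentation_result")
}

#' Train the two-stage cascade
#'
#' @param samples training samples (`$image`, labeled `$mask`).
#' @param cfg a [pipeline_config()]; per-stage seeds are derived from
#'   `cfg$seed`.
#' @param verbose print per-epoch losses.
#' @return list with `stage1`, `stage2` model handles.
#' @export
train_two_stage <- function(samples, cfg = pipeline_config(),
                            verbose = FALSE) {
  pairs1 <- make_stage1_training_pairs(samples, cfg$margin_frac,
                                       cfg$stage1_input_size,
                                       jitter_seed = derive_seed(cfg$seed, 10L))
  net1 <- cfg$stage1_network; net1$seed <- derive_seed(cfg$seed, 11L)
  tr1 <- cfg$stage1_train; tr1$seed <- derive_seed(cfg$seed, 12L)
  stage1 <- build_multiresunet(net1)
  train_network(stage1, pairs1, tr1, verbose)

  pairs2 <- make_stage2_training_pairs(
    samples, cfg$use_ground_truth_lower, stage1,
    cfg$stage1_train$binarize_threshold
  )
  net2 <- cfg$stage2_network; net2$seed <- derive_seed(cfg$seed, 21L)
  tr2 <- cfg$stage2_train; tr2$seed <- derive_seed(cfg$seed, 22L)
  stage2 <- build_multiresunet(net2)
  train_network(stage2, pairs2, tr2, verbose)
  list(stage1 = stage1, stage2 = stage2)
}

#' Train the capacity-matched single-stage baseline
#'
#' Same architecture family, width and training budget as stage 2, but
#' trained to segment all three discs directly from the raw image.
#'
#' @inheritParams train_two_stage
#' @return a model handle.
#' @export
train_single_stage <- function(samples, cfg = pipeline_config(),
                               verbose = FALSE) {
  ds <- lapply(samples, function(s) list(input = s$image,
                                         target = s$mask != 0L))
  net <- cfg$stage2_network
  net$input_channels <- 1L
  net$seed <- derive_seed(cfg$seed, 31L)
  tr <- cfg$stage2_train; tr$seed <- derive_seed(cfg$seed, 32L)
  model <- build_multiresunet(net)
  train_network(model, ds, tr, verbose)
  model
}

#' Run a full experiment: train both stages, infer, evaluate
#'
#' @param train_samples,test_samples in-memory sample lists, or paths to
#'   manifest CSVs written by [generate_dataset()].
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for artifacts (report JSON/CSV and
#'   predicted masks as BMP).
#' @param verbose print progress.
#' @return list with `report` (two-stage [evaluate_dataset()] result),
#'   `single_report` (when `cfg$include_single_stage`), `models`, `results`.
#' @export
run_experiment <- function(train_samples, test_samples,
                           cfg = pipeline_config(), out_dir = NULL,
                           verbose = FALSE) {
  if (is.character(train_samples)) train_samples <- load_dataset(train_samples)
  if (is.character(test_samples)) test_samples <- load_dataset(test_samples)
  assert_that(length(train_samples) > 0 && length(test_samples) > 0,
              "run_experiment: empty train or test set")
  models <- train_two_stage(train_samples, cfg, verbose)
  results <- lapply(test_samples, function(s) {
    infer(s$image, models$stage1, models$stage2, cfg)
  })
  refs <- lapply(test_samples, `[[`, "mask")
  report <- evaluate_dataset(results, refs)

  single_report <- NULL
  single_model <- NULL
  if (isTRUE(cfg$include_single_stage)) {
    single_model <- train_single_stage(train_samples, cfg, verbose)
    single_results <- lapply(test_samples, function(s) {
      infer_single_stage(s$image, single_model,
                         cfg$stage2_train$binarize_threshold,
                         cfg$min_instance_area)
    })
    single_report <- evaluate_dataset(single_results, refs)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_eval_report(report, file.path(out_dir, "report.json"),
                      file.path(out_dir, "report.csv"))
    if (!is.null(single_report)) {
      write_eval_report(single_report,
                        file.path(out_dir, "report_single_stage.json"),
                        file.path(out_dir, "report_single_stage.csv"))
    }
    for (i in seq_along(results)) {
      write_mask(results[[i]]$mask,
                 file.path(out_dir, sprintf("pred_%04d.bmp", i)))
    }
  }
  list(report = report, single_report = single_report,
       models = c(models, list(single = single_model)), results = results)
}

#' Generate phantom samples in memory
#'
#' Convenience wrapper deriving one seed per sample from the master seed,
#' mirroring [generate_dataset()] without touching disk.
#'
#' @param n number of samples.
#' @param params a [phantom_params()]; `params$seed` is the master seed.
#' @param offset seed-derivation offset, so that disjoint sets (train/test)
#'   can share a master seed.
#' @return list of `phantom_sample`s.
#' @export
generate_samples <- function(n, params, offset = 0L) {
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, offset + i)
    generate_sample(p)
  })
}
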