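# Instance-aware evaluation protocol for three-disc segmentation.
#
# A predicted image is correct (b_i = 1) only when its connected-component
# instance count P_i equals the standard count L (three discs) AND every
# per-disc discrimination criterion C_ik = |R_ik n S_ik| / |S_ik| reaches the
# cutoff (default 70%). Accuracy A = B / T aggregates the b_i over the test
# set; mean IoU averages the binary foreground IoU over ALL test images,
# failed predictions included.

#' Evaluation configuration
#'
#' @param L standard number of disc instances per image (default 3).
#' @param c_threshold per-disc discrimination cutoff; an image with any
#'   `C_ik < c_threshold` is an error prediction. Images at exactly the
#'   threshold count as correct (the comparison is `>=`).
#' @return an `eval_config` list.
#' @export
eval_config <- function(L = 3L, c_threshold = 0.70) {
  assert_that(length(L) == 1 && L >= 1, "L must be a positive count")
  assert_that(
    length(c_threshold) == 1 && c_threshold > 0 && c_threshold <= 1,
    "c_threshold must lie in (0, 1]"
  )
  structure(list(L = as.integer(L), c_threshold = c_threshold),
            class = "eval_config")
}

#' Intersection over union (Jaccard index) of two binary masks
#'
#' `|X & Y| / |X | Y|`. Two empty masks agree perfectly and score 1; exactly
#' one empty mask scores 0.
#'
#' @param X,Y binary masks (logical or 0/1 matrices) of identical shape.
#' @return a fraction in \[0, 1\].
#' @export
iou <- function(X, Y) {
  assert_that(all(dim(X) == dim(Y)), "iou: mask shapes differ",
              "discseg_shape_error")
  x <- as_binary(X); y <- as_binary(Y)
  u <- sum(x | y)
  if (u == 0) return(1)
  sum(x & y) / u
}

#' Discrimination criterion of a predicted region against a standard mask
#'
#' The fraction of the standard (reference) disc area covered by the
#' prediction: `|R & S| / |S|`. Over-segmentation outside `S` does not lower
#' the score; the instance-count check catches spurious regions instead.
#'
#' @param R predicted binary region.
#' @param S standard (reference) binary region; must be non-empty.
#' @return a fraction in \[0, 1\].
#' @export
discrimination <- function(R, S) {
  assert_that(all(dim(R) == dim(S)), "discrimination: mask shapes differ",
              "discseg_shape_error")
  s <- as_binary(S)
  n_s <- sum(s)
  assert_that(n_s > 0, "discrimination: standard mask is empty",
              "discseg_empty_mask")
  sum(as_binary(R) & s) / n_s
}

#' Image-level correctness indicator
#'
#' @param P_i predicted instance count of the image.
#' @param C_i numeric vector of per-disc discrimination criteria (length
#'   `cfg$L` when `P_i == cfg$L`; ignored otherwise).
#' @param cfg an [eval_config()].
#' @return 1 if `P_i == L` and every `C_ik >= c_threshold`, else 0.
#' @export
image_correct <- function(P_i, C_i, cfg = eval_config()) {
  if (P_i != cfg$L) return(0L)
  assert_that(length(C_i) == cfg$L,
              "image_correct: need one criterion per standard disc")
  if (all(C_i >= cfg$c_threshold)) 1L else 0L
}

#' Accuracy from per-image correctness indicators
#'
#' @param b vector of 0/1 indicators, one per test image.
#' @return list with `B` (number correct) and `A = B / T`.
#' @export
accuracy <- function(b) {
  assert_that(length(b) > 0, "accuracy: empty indicator list")
  assert_that(all(b %in% c(0, 1)), "accuracy: indicators must be 0/1")
  B <- as.integer(sum(b))
  list(B = B, A = B / length(b))
}

#' Pair predicted and reference disc instances
#'
#' Correspondence is by top-to-bottom rank on both sides, matching the
#' labeling convention (disc 1 uppermost). Pairing is only defined when the
#' prediction has exactly `L` instances; otherwise the image is already an
#' error and no pairing is returned.
#'
#' @param pred,ref labeled instance masks (integer matrices, 0 = background,
#'   instances labeled 1..K top to bottom).
#' @param cfg an [eval_config()].
#' @return `NULL` when the instance counts do not allow a pairing, else a
#'   list with per-disc binary masks `R` (predicted) and `S` (reference).
#' @export
match_instances <- function(pred, ref, cfg = eval_config()) {
  L <- cfg$L
  assert_that(n_labels(ref) == L,
              "match_instances: reference must have exactly L instances")
  pred <- relabel_top_to_bottom(pred)
  ref <- relabel_top_to_bottom(ref)
  if (n_labels(pred) != L) return(NULL)
  list(
    R = lapply(seq_len(L), function(k) pred == k),
    S = lapply(seq_len(L), function(k) ref == k)
  )
}

n_labels <- function(lab) {
  if (!length(lab) || all(lab == 0)) 0L else as.integer(max(lab))
}

#' Evaluate one predicted mask against its reference
#'
#' @param pred a labeled mask or a `segmentation_result` (whose `failed`
#'   flag forces `b_i = 0`).
#' @param ref labeled reference mask with exactly `cfg$L` instances.
#' @param cfg an [eval_config()].
#' @param id image identifier carried into the record.
#' @return an `eval_record` list: `id`, `P_i`, `C_i`, `b_i`, `iou_i`
#'   (binary-foreground IoU) and `iou_disc` (per-disc IoU, NA when unpaired).
#' @export
evaluate_record <- function(pred, ref, cfg = eval_config(), id = NA) {
  failed <- FALSE
  if (inherits(pred, "segmentation_result")) {
    failed <- isTRUE(pred$failed)
    pred <- pred$mask
  }
  assert_that(all(dim(pred) == dim(ref)), "evaluate_record: shapes differ",
              "discseg_shape_error")
  L <- cfg$L
  P_i <- count_instances(pred != 0)
  pairing <- if (!failed && P_i == L) match_instances(pred, ref, cfg) else NULL
  if (!is.null(pairing)) {
    C_i <- vapply(seq_len(L), function(k) {
      discrimination(pairing$R[[k]], pairing$S[[k]])
    }, numeric(1))
    iou_disc <- vapply(seq_len(L), function(k) {
      iou(pairing$R[[k]], pairing$S[[k]])
    }, numeric(1))
    b_i <- image_correct(P_i, C_i, cfg)
  } else {
    C_i <- rep(NA_real_, L)
    iou_disc <- rep(NA_real_, L)
    b_i <- 0L
  }
  structure(list(
    id = id, P_i = P_i, C_i = C_i, b_i = b_i,
    iou_i = iou(pred != 0, ref != 0), iou_disc = iou_disc,
    failed = failed
  ), class = "eval_record")
}

#' Evaluate a dataset of predictions
#'
#' Every image contributes: failed or miscounted predictions get `b_i = 0`
#' and still contribute their (possibly low) foreground IoU to the mean.
#'
#' @param preds list of labeled masks or `segmentation_result`s.
#' @param refs list of labeled reference masks, same length.
#' @param cfg an [eval_config()].
#' @param ids optional image identifiers.
#' @return an `eval_report`: `T`, `B`, `A`, `mean_iou`, `records`.
#' @export
evaluate_dataset <- function(preds, refs, cfg = eval_config(), ids = NULL) {
  assert_that(length(preds) == length(refs),
              "evaluate_dataset: preds and refs lengths differ")
  assert_that(length(preds) > 0, "evaluate_dataset: empty dataset")
  ids <- ids %||% seq_along(preds)
  records <- Map(function(p, r, id) evaluate_record(p, r, cfg, id),
                 preds, refs, ids)
  b <- vapply(records, `[[`, integer(1), "b_i")
  acc <- accuracy(b)
  structure(list(
    T = length(records), B = acc$B, A = acc$A,
    mean_iou = mean(vapply(records, `[[`, numeric(1), "iou_i")),
    records = records
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over T = %d images\n", x$T))
  cat(sprintf("  correct images B = %d\n", x$B))
  cat(sprintf("  accuracy A = %.3f\n", x$A))
  cat(sprintf("  mean IoU = %.3f\n", x$mean_iou))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Aggregates go to JSON, per-image records to CSV
#' (id, P_i, C_i1..C_iL, b_i, iou_i).
#'
#' @param report an `eval_report`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the per-image data frame.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  L <- length(report$records[[1]]$C_i)
  df <- do.call(rbind, lapply(report$records, function(r) {
    row <- data.frame(id = as.character(r$id), P_i = r$P_i)
    for (k in seq_len(L)) row[[paste0("C_i", k)]] <- r$C_i[k]
    row$b_i <- r$b_i
    row$iou_i <- r$iou_i
    row
  }))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(T = report$T, B = report$B, A = report$A,
           mean_iou = report$mean_iou),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}

#' Conservative sample size for a confidence-interval estimate
#'
#' Normal-approximation formula `n = ceil((z * sd / margin)^2)`. Following
#' sample-size convention, the critical value is the two-sided normal
#' quantile rounded to two decimals (1.96 for 95%), which reproduces the
#' textbook figures; pass `z` explicitly to override.
#'
#' @param confidence confidence level (default 0.95).
#' @param sd anticipated standard deviation.
#' @param margin margin of error; must be positive.
#' @param z optional explicit critical value.
#' @return required sample size (integer).
#' @export
conservative_sample_size <- function(confidence = 0.95, sd, margin, z = NULL) {
  assert_that(margin > 0, "margin of error must be positive")
  assert_that(confidence > 0 && confidence < 1, "confidence must be in (0,1)")
  z <- z %||% round(stats::qnorm(1 - (1 - confidence) / 2), 2)
  as.integer(ceiling((z * sd / margin)^2))
}
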