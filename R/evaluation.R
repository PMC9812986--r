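#' Pixel-level segmentation metrics
#'
#' Predictions and ground truth are compared pixel-by-pixel. With A the
#' predicted and B the true tubule pixel sets, the Dice similarity
#' coefficient is DSC = 2|A n B| / (|A| + |B|) = 2TP / (2TP + FP + FN);
#' recall = 100 TP / (TP + FN), specificity = 100 TN / (FP + TN) and
#' FPR = 100 - specificity (all in percent). When both masks are empty
#' the DSC is defined as 1 (correctly predicting nothing is not
#' penalised); recall/specificity are `NA` when their denominator is
#' zero.
#'
#' @name evaluation
NULL

#' Threshold a probability map into a binary mask
#'
#' @param map Matrix with values in \[0, 1\].
#' @param threshold Decision threshold; pixels `>= threshold` become 1.
#' @return Binary H x W matrix over \{0, 1\}.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (!is.matrix(map)) stop("`map` must be a matrix", call. = FALSE)
  if (min(map) < 0 || max(map) > 1) {
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  }
  (map >= threshold) * 1
}

metrics_from_counts <- function(tp, fp, tn, fn) {
  dsc <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  specificity <- if (fp + tn > 0) 100 * tn / (fp + tn) else NA_real_
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn, dsc = dsc,
                 recall = recall, specificity = specificity,
                 fpr = 100 - specificity)
}

#' Score a predicted mask against ground truth
#'
#' @param pred,truth Binary H x W matrices over \{0, 1\} of identical
#'   shape.
#' @return One-row tibble with pixel counts `tp`, `fp`, `tn`, `fn`, the
#'   Dice coefficient `dsc` (fraction in \[0, 1\]) and `recall`,
#'   `specificity`, `fpr` in percent.
#' @export
score <- function(pred, truth) {
  check_binary_mask(pred); check_binary_mask(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` must have identical shapes", call. = FALSE)
  }
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  metrics_from_counts(tp, fp, tn, fn)
}

#' Aggregate per-image metric reports
#'
#' `macro` averages the per-image metric values unweighted (the
#' convention for averaging scores over several whole-slide images);
#' `micro` pools the pixel counts and recomputes the metrics, so larger
#' images weigh more.
#'
#' @param reports List of [score()] rows (or a tibble of them).
#' @param mode `"macro"` or `"micro"`.
#' @return One-row metrics tibble; under `macro` the count columns hold
#'   the summed counts while the metric columns are unweighted means.
#' @export
aggregate_scores <- function(reports, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  if (is.data.frame(reports)) reports <- list(reports)
  if (length(reports) == 0) stop("`reports` must be non-empty", call. = FALSE)
  all <- do.call(rbind, reports)
  if (mode == "micro") {
    return(metrics_from_counts(sum(all$tp), sum(all$fp), sum(all$tn), sum(all$fn)))
  }
  tibble::tibble(tp = sum(all$tp), fp = sum(all$fp), tn = sum(all$tn),
                 fn = sum(all$fn),
                 dsc = mean(all$dsc, na.rm = TRUE),
                 recall = mean(all$recall, na.rm = TRUE),
                 specificity = mean(all$specificity, na.rm = TRUE),
                 fpr = mean(all$fpr, na.rm = TRUE))
}

#' Render a TP/FN/FP overlay over the source image
#'
#' Correctly segmented (true positive) pixels are tinted green, missed
#' tubule pixels (false negatives) blue and incorrectly segmented pixels
#' (false positives) red; true negatives keep the original image.
#'
#' @param pred,truth Binary masks of the image's spatial shape.
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param alpha Tint opacity in \[0, 1\].
#' @return RGB array of the input shape.
#' @export
overlay <- function(pred, truth, image, alpha = 0.5) {
  check_binary_mask(pred); check_binary_mask(truth)
  image <- as_rgb(image)
  if (!all(dim(pred) == dim(image)[1:2]) || !all(dim(truth) == dim(image)[1:2])) {
    stop("masks and image shapes must agree", call. = FALSE)
  }
  tint <- function(img, sel, rgb) {
    if (!any(sel)) return(img)
    hw <- prod(dim(img)[1:2])
    idx <- which(sel)
    for (ch in 1:3) {
      lin <- idx + (ch - 1L) * hw
      img[lin] <- (1 - alpha) * img[lin] + alpha * rgb[ch]
    }
    img
  }
  out <- image
  out <- tint(out, pred == 1 & truth == 1, c(0, 1, 0))
  out <- tint(out, pred == 0 & truth == 1, c(0, 0, 1))
  out <- tint(out, pred == 1 & truth == 0, c(1, 0, 0))
  out
}
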