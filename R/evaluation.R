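#' Consensus ground truth from several expert masks
#'
#' Pixelwise majority vote across expert annotations: a pixel is foreground
#' when the mean annotation is at least 0.5, so with two experts ties go to
#' foreground.
#'
#' @param masks List of logical (or 0/1) matrices of equal dimensions.
#' @return Logical consensus mask.
#' @export
consensus_ground_truth <- function(masks) {
  if (!length(masks)) abort("need at least one mask")
  masks <- lapply(masks, function(m) {
    if (is.numeric(m)) m <- m > 0
    if (!is.matrix(m)) abort("masks must be matrices")
    m
  })
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1)))) {
    abort("masks have mismatching shapes")
  }
  acc <- Reduce(`+`, lapply(masks, function(m) matrix(as.numeric(m), d[1], d[2])))
  (acc / length(masks)) >= 0.5
}

as_binary_mask <- function(m, arg) {
  if (is.logical(m)) return(m)
  if (is.numeric(m) && all(m %in% c(0, 1))) return(m > 0)
  if (is.numeric(m) && all(m %in% c(0, 255))) return(m > 0)
  abort(sprintf("`%s` is not a binary mask", arg))
}

#' Score a predicted mask against ground truth
#'
#' Computes the agreement metrics used to validate lesion segmentations:
#' mean squared error between the two masks (coded \{0, 255\} by default,
#' the 8-bit convention under which typical lesion-segmentation MSE values
#' land in the hundreds; `coding = "binary"` uses \{0, 1\}), Pearson
#' correlation of the flattened masks (clipped to \[0, 1\] for reporting,
#' raw value retained in `corr_raw`; undefined for a constant mask and then
#' reported as `NA`), the Sørensen–Dice coefficient
#' \eqn{2|X \cap Y| / (|X| + |Y|)}, and pixelwise sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and accuracy (TP+TN)/MN with
#' truth = 1 as positive.
#'
#' @param pred,truth Binary masks (logical or 0/1 or 0/255) of equal
#'   dimensions.
#' @param coding `"8bit"` (default) or `"binary"` scaling for the MSE.
#' @return One-row tibble: `mse`, `corr`, `corr_raw`, `dice`,
#'   `sensitivity`, `specificity`, `accuracy`, `n_pixels`.
#' @export
score_pair <- function(pred, truth, coding = c("8bit", "binary")) {
  coding <- match.arg(coding)
  pred <- as_binary_mask(pred, "pred")
  truth <- as_binary_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) abort("pred and truth shapes differ")
  n <- length(pred)
  scale <- if (coding == "8bit") 255 else 1
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  mse <- mean((scale * as.numeric(truth) - scale * as.numeric(pred))^2)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  corr_raw <- if (sd(pred) == 0 || sd(truth) == 0) NA_real_ else
    cor(as.numeric(pred), as.numeric(truth))
  tibble(
    mse = mse,
    corr = if (is.na(corr_raw)) NA_real_ else max(corr_raw, 0),
    corr_raw = corr_raw,
    dice = dice,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    accuracy = (tp + tn) / n,
    n_pixels = n
  )
}

#' Score a batch of mask pairs
#'
#' Applies [score_pair()] to each prediction/truth pair and attaches the
#' per-metric descriptive summary (mean, sample standard deviation,
#' standard error and normal-theory 95% confidence interval) retrievable
#' with [glance()] or [summary()].
#'
#' @param pred List of predicted masks (or a single mask).
#' @param truth List of ground-truth masks, same length.
#' @param coding Passed to [score_pair()].
#' @return A `fundus_eval` tibble, one row per pair (column `pair` first).
#' @export
evaluate_batch <- function(pred, truth, coding = c("8bit", "binary")) {
  coding <- match.arg(coding)
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(truth)) truth <- list(truth)
  if (length(pred) != length(truth)) abort("pred and truth lists differ in length")
  rows <- purrr::imap(pred, function(p, i) {
    dplyr::bind_cols(tibble(pair = i), score_pair(p, truth[[i]], coding))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fundus_eval", class(out))
  out
}

metric_summary <- function(scores, conf_level = 0.95) {
  metrics <- c("mse", "corr", "dice", "sensitivity", "specificity", "accuracy")
  z <- qnorm(1 - (1 - conf_level) / 2)
  purrr::map_dfr(metrics, function(mname) {
    x <- scores[[mname]]
    x <- x[!is.na(x)]
    n <- length(x)
    m <- mean(x)
    s <- if (n > 1) sd(x) else NA_real_
    se <- if (n > 1) s / sqrt(n) else NA_real_
    tibble(metric = mname, mean = m, std = s, se = se,
           ci_lower = if (n > 1) m - z * se else NA_real_,
           ci_upper = if (n > 1) m + z * se else NA_real_,
           n = n)
  })
}

#' @rdname evaluate_batch
#' @param x,object A `fundus_eval` tibble.
#' @param ... Unused.
#' @export
glance.fundus_eval <- function(x, ...) metric_summary(x)

#' @rdname evaluate_batch
#' @export
summary.fundus_eval <- function(object, ...) metric_summary(object)

#' Dice coefficient of two masks
#'
#' Convenience accessor for the overlap score
#' \eqn{2|X \cap Y| / (|X| + |Y|)}.
#'
#' @inheritParams score_pair
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(pred, truth) {
  score_pair(pred, truth)$dice
}

#' Score one prediction against several experts
#'
#' Either against the consensus mask (`method = "mask"`, the default:
#' expert annotations are averaged into a majority-vote ground truth before
#' scoring) or by averaging per-expert metrics (`method = "metric"`).
#'
#' @param pred Predicted mask.
#' @param expert_masks List of expert annotation masks.
#' @param method `"mask"` or `"metric"`.
#' @inheritParams score_pair
#' @return One-row tibble of metrics.
#' @export
score_against_experts <- function(pred, expert_masks,
                                  method = c("mask", "metric"),
                                  coding = c("8bit", "binary")) {
  method <- match.arg(method)
  coding <- match.arg(coding)
  if (method == "mask") {
    score_pair(pred, consensus_ground_truth(expert_masks), coding)
  } else {
    scores <- dplyr::bind_rows(lapply(expert_masks, function(m)
      score_pair(pred, m, coding)))
    dplyr::summarise(scores, dplyr::across(dplyr::everything(),
                                           ~ mean(.x, na.rm = TRUE)))
  }
}
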