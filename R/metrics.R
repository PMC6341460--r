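# Filter-quality and segmentation-quality metrics.

noise_moments <- function(noisy, filtered) {
  if (!all(dim(noisy) == dim(filtered)))
    stop_param("noisy and filtered images must share a shape")
  m0 <- mean(noisy); s0 <- sd(as.vector(noisy))
  if (m0 == 0) stop_param("undefined metric: noisy image has zero mean")
  if (s0 == 0) stop_param("undefined metric: noisy image is constant")
  list(m0 = m0, s0 = s0, mf = mean(filtered), sf = sd(as.vector(filtered)))
}

#' Speckle suppression index (SSI)
#'
#' The filtered image's coefficient of variation normalized by the noisy
#' image's: \eqn{(\sigma_f/\mu_f)\,(\mu_0/\sigma_0)}. Values below 1 indicate
#' speckle suppression; the identity filter scores exactly 1 and total
#' smoothing scores 0.
#'
#' @param noisy,filtered Same-shape numeric matrices; `noisy` must be
#'   nonconstant with nonzero mean.
#' @return Nonnegative scalar.
#' @export
ssi <- function(noisy, filtered) {
  w <- noise_moments(noisy, filtered)
  (w$sf / w$mf) * (w$m0 / w$s0)
}

#' Speckle and mean preservation index (SMPI)
#'
#' The standard-deviation ratio penalized by relative mean shift:
#' \eqn{Q \cdot \sigma_f/\sigma_0} with
#' \eqn{Q = 1 + |\mu_0 - \mu_f|/\mu_0}. Lower is better: it rewards variance
#' reduction while punishing filters that move the mean.
#'
#' @inheritParams ssi
#' @export
smpi <- function(noisy, filtered) {
  w <- noise_moments(noisy, filtered)
  (1 + abs(w$m0 - w$mf) / w$m0) * (w$sf / w$s0)
}

#' Build a confusion report from pixel counts
#'
#' Rates are percentages: sensitivity `tpr = 100 tp/(tp+fn)`, specificity
#' `tnr = 100 tn/(tn+fp)`, `fpr = 100 - tnr`, `fnr = 100 - tpr`; `accuracy`
#' is the balanced accuracy `(tpr + tnr)/2` and `pixel_accuracy` the raw
#' fraction `100 (tp+tn)/total`. If the reference has no positives (or no
#' negatives) the corresponding rates are `NA` with a warning rather than a
#' silent 0.
#'
#' @param tp,tn,fp,fn Nonnegative pixel counts.
#' @return A list of class `confusion_report`.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop_param("counts must be nonnegative")
  total <- tp + tn + fp + fn
  if (total == 0) stop_param("empty confusion: all counts zero")
  pos <- tp + fn
  neg <- tn + fp
  if (pos == 0)
    warning("reference has no positive pixels: tpr/fnr undefined",
            call. = FALSE)
  if (neg == 0)
    warning("reference has no negative pixels: tnr/fpr undefined",
            call. = FALSE)
  tpr <- if (pos > 0) 100 * tp / pos else NA_real_
  tnr <- if (neg > 0) 100 * tn / neg else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 tpr = tpr, tnr = tnr,
                 fpr = if (is.na(tnr)) NA_real_ else 100 - tnr,
                 fnr = if (is.na(tpr)) NA_real_ else 100 - tpr,
                 accuracy = (tpr + tnr) / 2,
                 pixel_accuracy = 100 * (tp + tn) / total),
            class = "confusion_report")
}

#' Pixelwise confusion rates of a predicted mask against a reference
#'
#' @param pred,truth Same-shape binary masks (values in \{0, 1\});
#'   `truth` is the reference (e.g. a manually drawn tumor mask).
#' @return A `confusion_report`; see [confusion_from_counts()].
#' @export
confusion_rates <- function(pred, truth) {
  check_mask(pred, "pred")
  check_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth)))
    stop_param("pred and truth must share a shape")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  confusion_from_counts(tp, tn, fp, fn)
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report>\n")
  cat(sprintf("  TPR %.4f  TNR %.4f  FPR %.4f  FNR %.4f\n",
              x$tpr, x$tnr, x$fpr, x$fnr))
  cat(sprintf("  balanced accuracy %.4f  pixel accuracy %.4f\n",
              x$accuracy, x$pixel_accuracy))
  invisible(x)
}
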