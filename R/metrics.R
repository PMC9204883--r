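# ---------------------------------------------------------------------------
# Pixel-level segmentation metrics: residual-ratio FN/FP and mIoU.
#
# The residual ratio asks what fraction of one mask survives removal of
# the other: removing the predicted pixels from the actual ROI leaves the
# false negatives; removing the actual ROI from the prediction leaves the
# false positives.  FN is normalised by the actual ROI, FP by the
# predicted ROI.
# ---------------------------------------------------------------------------

check_masks <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have identical dimensions")
  list(pred = as.vector(pred) != 0, truth = as.vector(truth) != 0)
}

#' Confusion counts for one mask pair
#'
#' @param pred,truth logical masks of identical dimensions.
#' @return named integer vector `tp`, `fp`, `fn`, `tn` summing to the
#'   total pixel count.
#' @export
pixel_counts <- function(pred, truth) {
  m <- check_masks(pred, truth)
  c(tp = sum(m$pred & m$truth), fp = sum(m$pred & !m$truth),
    fn = sum(!m$pred & m$truth), tn = sum(!m$pred & !m$truth))
}

#' Residual-ratio false-negative percentage
#'
#' `100 * |truth \ pred| / |truth|`: the share of the actual ROI left
#' after removing the predicted pixels.
#'
#' @param pred,truth logical masks of identical dimensions.
#' @return percentage in `[0, 100]`; `NA` with a warning if `truth` is
#'   empty (undefined; excluded from aggregates).
#' @export
residual_fn <- function(pred, truth) {
  m <- check_masks(pred, truth)
  n_truth <- sum(m$truth)
  if (n_truth == 0L) {
    warning("empty truth mask: FN undefined")
    return(NA_real_)
  }
  100 * sum(m$truth & !m$pred) / n_truth
}

#' Residual-ratio false-positive percentage
#'
#' `100 * |pred \ truth| / |pred|`: the share of the prediction left after
#' removing the actual ROI.
#'
#' @inheritParams residual_fn
#' @return percentage in `[0, 100]`; `NA` with a warning if `pred` is
#'   empty.
#' @export
residual_fp <- function(pred, truth) {
  m <- check_masks(pred, truth)
  n_pred <- sum(m$pred)
  if (n_pred == 0L) {
    warning("empty prediction mask: FP undefined")
    return(NA_real_)
  }
  100 * sum(m$pred & !m$truth) / n_pred
}

#' Mean intersection over union (single pair)
#'
#' `100 * |pred intersect truth| / |pred union truth|`.
#'
#' @inheritParams residual_fn
#' @return percentage in `[0, 100]`; `NA` with a warning if both masks are
#'   empty.
#' @export
miou <- function(pred, truth) {
  m <- check_masks(pred, truth)
  u <- sum(m$pred | m$truth)
  if (u == 0L) {
    warning("both masks empty: mIoU undefined")
    return(NA_real_)
  }
  100 * sum(m$pred & m$truth) / u
}
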