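#' Pixel-level ROC curve and AUC
#'
#' Sweeps a decision threshold over a continuous per-pixel score image
#' (predict positive where score >= threshold) and records the (false
#' positive rate, true positive rate) operating point at every distinct
#' score; the area under the curve is computed by trapezoidal integration.
#' A constant score yields the chance diagonal (AUC 0.5); AUC equals the
#' Mann-Whitney probability that a random positive pixel outscores a
#' random negative one (ties counted half).
#'
#' @param scores numeric vector or matrix of per-pixel scores.
#' @param truth logical vector or matrix of the same length; must contain
#'   both classes.
#' @return list with `roc`, a data.frame of `threshold`, `fpr`, `tpr`
#'   (monotone non-decreasing in `fpr`, from (0,0) to (1,1)), and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  s <- as.vector(scores)
  y <- as.vector(truth) != 0
  if (length(s) != length(y)) stop("scores and truth differ in length")
  if (anyNA(s) || anyNA(y)) stop("NA in scores or truth")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("truth must contain both classes")
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]
  y_ord <- y[ord]
  last <- !duplicated(s_ord, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(y_ord)[last]
  fp <- cumsum(!y_ord)[last]
  roc <- data.frame(threshold = c(Inf, s_ord[last]),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}
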