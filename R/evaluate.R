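# ---------------------------------------------------------------------------
# Dataset-level evaluation: per-image FN / FP / mIoU, mean +/- SD
# aggregates, and an optional pooled pixel-level ROC/AUC.
# ---------------------------------------------------------------------------

#' Evaluate a set of predicted masks against ground truth
#'
#' Computes the residual-ratio FN and FP percentages and mIoU for every
#' (prediction, truth) pair, aggregates them as mean plus sample (n-1)
#' standard deviation, and, if per-pixel score images are supplied, a
#' pooled pixel-level ROC curve and AUC.  Per-image metrics that are
#' undefined (empty truth for FN, empty prediction for FP, both empty for
#' mIoU) are recorded as `NA` and excluded from the aggregates.
#'
#' @param pred list of logical mask matrices.
#' @param truth list of logical mask matrices, same length and dimensions.
#' @param scores optional list of numeric score matrices (same geometry)
#'   for the ROC; see [segmentation_scores()].
#' @param ids optional character ids (default `img_001`, ...).
#' @return an `eval_report`: list with `per_image` (data.frame `id`,
#'   `fn_pct`, `fp_pct`, `miou_pct`), `aggregate` (data.frame `metric`,
#'   `mean`, `sd`, `n`, `label` formatted "m +/- s %"), `roc` and `auc`
#'   (NULL without scores), and `n_excluded` per metric.
#' @export
evaluate_dataset <- function(pred, truth, scores = NULL, ids = NULL) {
  if (length(pred) != length(truth) || length(pred) == 0L)
    stop("pred and truth must be non-empty lists of equal length")
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(pred))
  per <- data.frame(id = ids,
                    fn_pct = NA_real_, fp_pct = NA_real_,
                    miou_pct = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(pred)) {
    per$fn_pct[i] <- suppressWarnings(residual_fn(pred[[i]], truth[[i]]))
    per$fp_pct[i] <- suppressWarnings(residual_fp(pred[[i]], truth[[i]]))
    per$miou_pct[i] <- suppressWarnings(miou(pred[[i]], truth[[i]]))
  }
  metrics <- c("fn_pct", "fp_pct", "miou_pct")
  n_excluded <- vapply(per[metrics], function(v) sum(is.na(v)), integer(1))
  if (all(vapply(per[metrics], function(v) all(is.na(v)), logical(1))))
    warning("all per-image metrics undefined; empty aggregates")
  agg <- do.call(rbind, lapply(metrics, function(mname) {
    v <- per[[mname]]
    v <- v[!is.na(v)]
    m <- if (length(v)) mean(v) else NA_real_
    s <- if (length(v) >= 2L) stats::sd(v) else if (length(v) == 1L) 0 else
      NA_real_
    data.frame(metric = mname, mean = m, sd = s, n = length(v),
               single = length(v) == 1L,
               label = if (is.na(m)) NA_character_ else
                 sprintf("%.2f ± %.2f %%", m, s),
               stringsAsFactors = FALSE)
  }))
  roc <- NULL
  auc <- NULL
  if (!is.null(scores)) {
    if (length(scores) != length(truth))
      stop("scores must match truth in length")
    r <- roc_auc(unlist(lapply(scores, as.vector)),
                 unlist(lapply(truth, as.vector)))
    roc <- r$roc
    auc <- r$auc
  }
  structure(list(per_image = per, aggregate = agg, roc = roc, auc = auc,
                 n_excluded = n_excluded),
            class = "eval_report")
}

#' Write / read an evaluation report
#'
#' `write_eval_report()` writes the per-image metrics as CSV, the ROC
#' points (if any) as CSV, and the full report as JSON;
#' `read_eval_report()` restores the report from the JSON losslessly.
#'
#' @param report an `eval_report` from [evaluate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory (write) / an `eval_report` (read), invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_image, file.path(dir, "per_image.csv"),
                   row.names = FALSE)
  if (!is.null(report$roc))
    utils::write.csv(report$roc, file.path(dir, "roc_points.csv"),
                     row.names = FALSE)
  payload <- list(per_image = report$per_image,
                  aggregate = report$aggregate,
                  roc = report$roc, auc = report$auc,
                  n_excluded = as.list(report$n_excluded))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(dir) {
  p <- jsonlite::read_json(file.path(dir, "report.json"),
                           simplifyVector = TRUE)
  per <- as.data.frame(p$per_image, stringsAsFactors = FALSE)
  for (col in c("fn_pct", "fp_pct", "miou_pct"))
    per[[col]] <- as.numeric(per[[col]])
  agg <- as.data.frame(p$aggregate, stringsAsFactors = FALSE)
  roc <- if (!is.null(p$roc) && length(p$roc))
    as.data.frame(p$roc, stringsAsFactors = FALSE) else NULL
  structure(list(per_image = per, aggregate = agg, roc = roc,
                 auc = if (is.null(p$auc)) NULL else as.numeric(p$auc),
                 n_excluded = unlist(p$n_excluded)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Pixel-level evaluation over", nrow(x$per_image), "images\n")
  for (i in seq_len(nrow(x$aggregate))) {
    a <- x$aggregate[i, ]
    cat(sprintf("  %-9s %s  (n = %d)\n", a$metric,
                ifelse(is.na(a$label), "undefined", a$label), a$n))
  }
  if (!is.null(x$auc)) cat(sprintf("  AUC       %.4f\n", x$auc))
  invisible(x)
}
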