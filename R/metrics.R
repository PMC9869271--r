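#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,label binary rasters (0/1) of identical dimensions.
#' @return an object of class \code{"confusion_counts"} with fields
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn} (gland pixels correctly
#'   found, background wrongly called gland, gland missed, background
#'   correctly called background).
#' @export
confusion <- function(pred, label) {
  if (!identical(dim(pred), dim(label)))
    stop("pred and label must have identical dimensions")
  pv <- as.integer(pred)
  lv <- as.integer(label)
  if (!all(pv %in% c(0L, 1L)) || !all(lv %in% c(0L, 1L)))
    stop("masks must be binary (0/1)")
  tp <- sum(pv == 1L & lv == 1L)
  fp <- sum(pv == 1L & lv == 0L)
  fn <- sum(pv == 0L & lv == 1L)
  tn <- length(pv) - tp - fp - fn
  confusion_counts(tp, fp, fn, tn)
}

#' Construct confusion counts directly
#'
#' Useful for evaluating published confusion matrices without the
#' underlying rasters.
#' @param tp,fp,fn,tn non-negative pixel counts.
#' @return a \code{"confusion_counts"} object.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' Segmentation quality metrics from confusion counts
#'
#' Computes the four standard two-class segmentation scores:
#' \deqn{Precision = TP / (TP + FP), \quad Recall = TP / (TP + FN)}
#' \deqn{F1 = 2 TP / (2 TP + FP + FN)}
#' and the two-class mean intersection-over-union
#' \deqn{mIoU = \frac{1}{2}\left[\frac{TP}{TP+FP+FN} +
#'   \frac{TN}{TN+FN+FP}\right]}
#' i.e. the average of the foreground IoU and the background IoU (where
#' the background class's "true positives" are the TN pixels). Pixel
#' accuracy \eqn{(TP+TN)/total} is also reported.
#'
#' A metric whose denominator is zero (e.g. precision when nothing is
#' predicted foreground) is returned as \code{NaN} and the report is
#' flagged \code{degenerate = TRUE} so aggregation code can exclude it.
#'
#' @param counts a \code{"confusion_counts"} object.
#' @return an object of class \code{"metric_report"} with fields
#'   \code{miou}, \code{iou} (length-2: foreground, background),
#'   \code{precision}, \code{recall}, \code{f1}, \code{pixel_accuracy},
#'   \code{degenerate}.
#' @export
segmentation_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  div <- function(num, den) if (den == 0) NaN else num / den
  iou_fg <- div(tp, tp + fp + fn)
  iou_bg <- div(tn, tn + fn + fp)
  rep <- list(
    miou = mean(c(iou_fg, iou_bg)),
    iou = c(foreground = iou_fg, background = iou_bg),
    precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    f1 = div(2 * tp, 2 * tp + fp + fn),
    pixel_accuracy = div(tp + tn, tp + fp + fn + tn)
  )
  rep$degenerate <- any(vapply(rep[c("miou", "precision", "recall", "f1")],
                               function(v) any(is.nan(v)), logical(1)))
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("Segmentation metrics\n")
  cat(sprintf("  mIoU:      %.*f (fg %.*f, bg %.*f)\n", digits, x$miou,
              digits, x$iou[1], digits, x$iou[2]))
  cat(sprintf("  Precision: %.*f\n", digits, x$precision))
  cat(sprintf("  Recall:    %.*f\n", digits, x$recall))
  cat(sprintf("  F1-score:  %.*f\n", digits, x$f1))
  cat(sprintf("  Pixel acc: %.*f\n", digits, x$pixel_accuracy))
  if (isTRUE(x$degenerate)) cat("  (degenerate: some denominators were 0)\n")
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              label = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Squared Pearson correlation between predicted and reference counts
#'
#' Counting agreement statistic: the square of the Pearson correlation
#' coefficient between automatic and manual gland counts over a set of
#' tiles or leaves. Affine-invariant, in \[0, 1\].
#'
#' @param pred_counts,ref_counts numeric vectors of equal length >= 3 with
#'   nonzero variance.
#' @return scalar r-squared.
#' @export
count_r2 <- function(pred_counts, ref_counts) {
  if (length(pred_counts) != length(ref_counts))
    stop("count vectors differ in length")
  if (length(pred_counts) < 3) stop("need at least 3 paired counts")
  if (stats::var(pred_counts) == 0)
    stop("pred_counts has zero variance")
  if (stats::var(ref_counts) == 0)
    stop("ref_counts has zero variance")
  stats::cor(pred_counts, ref_counts)^2
}
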