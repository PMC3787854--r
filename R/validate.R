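#' Confusion counts between a decision map and a reference mask
#'
#' Compares per-pixel detection outcomes with the reference mask:
#' `tp` = detected positive and truly positive, `fn` = missed positive,
#' `fp` = false alarm, `tn` = correctly negative. All pixels are evaluated.
#'
#' @param decision,reference [binary_mask] objects of identical shape.
#' @return An object of class `confusion_counts` with fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion <- function(decision, reference) {
  stopifnot(inherits(decision, "binary_mask"),
            inherits(reference, "binary_mask"))
  if (!all(dim(decision$values) == dim(reference$values)))
    stop("decision and reference mask shapes differ", call. = FALSE)
  d <- decision$values == 1L
  r <- reference$values == 1L
  confusion_counts(tp = sum(d & r), fn = sum(!d & r),
                   fp = sum(d & !r), tn = sum(!d & !r))
}

#' Construct confusion counts directly
#'
#' @param tp,fn,fp,tn Non-negative integer pixel counts: true positives,
#'   false negatives, false positives, true negatives.
#' @return An object of class `confusion_counts`.
#' @examples
#' confusion_counts(5627, 811, 1967, 92320)
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fn=%d fp=%d tn=%d (n=%d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn + x$fp + x$tn))
  invisible(x)
}

#' Sensitivity, specificity, and detection bias
#'
#' Sensitivity is the fraction of truly positive pixels detected,
#' `tp / (tp + fn)`; specificity the fraction of truly negative pixels
#' correctly rejected, `tn / (tn + fp)`. The detection bias is the total
#' number of positively detected pixels divided by the number of truly
#' positive pixels, `(tp + fp) / (tp + fn)`: an ideal bias is 1, bias > 1
#' indicates overestimation of the lesion extent and bias < 1
#' underestimation.
#'
#' @param counts A [confusion_counts].
#' @return An object of class `detection_metrics`: list with `sensitivity`,
#'   `specificity`, `bias` at full double precision. The print method rounds
#'   percentages to 2 d.p. and bias to 4 d.p.
#' @examples
#' detection_metrics(confusion_counts(1680, 1454, 691, 86808))
#' @export
detection_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  pos <- counts$tp + counts$fn
  neg <- counts$fp + counts$tn
  if (pos == 0)
    stop("sensitivity and bias undefined: no truly positive pixels",
         call. = FALSE)
  if (neg == 0)
    stop("specificity undefined: no truly negative pixels", call. = FALSE)
  structure(list(sensitivity = counts$tp / pos,
                 specificity = counts$tn / neg,
                 bias = (counts$tp + counts$fp) / pos,
                 counts = counts),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("sensitivity/specificity: %.2f%%/%.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("bias: %.4f\n", x$bias))
  invisible(x)
}

#' Serialize detection metrics (raw and display-rounded) to JSON
#'
#' @param metrics A [detection_metrics].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "detection_metrics"))
  jsonlite::write_json(
    list(counts = metrics$counts[c("tp", "fn", "fp", "tn")],
         sensitivity = metrics$sensitivity,
         specificity = metrics$specificity,
         bias = metrics$bias,
         display = list(
           sensitivity_pct = sprintf("%.2f", 100 * metrics$sensitivity),
           specificity_pct = sprintf("%.2f", 100 * metrics$specificity),
           bias = sprintf("%.4f", metrics$bias))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
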