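#' Confusion counts for the two-class enzyme-pair decision
#'
#' The positive class (coded `+1`) is "enzyme of the candidate class";
#' the negative class (coded `-1`) is everything else.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(is.numeric(counts), all(is.finite(counts)), all(counts >= 0),
            all(counts == round(counts)))
  if (sum(counts) < 1) stop("empty confusion matrix", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Confusion counts from predicted and true labels
#'
#' @param truth,predicted Vectors of labels in `{+1, -1}`.
#' @return A `confusion_counts` object.
#' @export
evaluate_pairs <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c(-1L, 1L)), all(predicted %in% c(-1L, 1L)))
  confusion_counts(tp = sum(truth == 1L & predicted == 1L),
                   fp = sum(truth == -1L & predicted == 1L),
                   tn = sum(truth == -1L & predicted == -1L),
                   fn = sum(truth == 1L & predicted == -1L))
}

#' Per-class correct-classification rate
#'
#' The percentage of the class's members classified into that class:
#' `100 * tp / (tp + fn)` for the positive class and
#' `100 * tn / (tn + fp)` for the negative class. (The literature labels
#' these sensitivity and specificity with conventions that vary by which
#' class is called positive; this function reports neutral per-class
#' rates and leaves the naming to the caller.)
#'
#' @param counts A `confusion_counts` object.
#' @param class `+1` or `-1`.
#' @return Percentage in `[0, 100]`, at full precision (round only for
#'   display).
#' @export
per_class_rate <- function(counts, class) {
  stopifnot(inherits(counts, "confusion_counts"), class %in% c(-1, 1))
  if (class == 1) {
    total <- counts$tp + counts$fn
    if (total == 0) stop("no members of class +1", call. = FALSE)
    100 * counts$tp / total
  } else {
    total <- counts$tn + counts$fp
    if (total == 0) stop("no members of class -1", call. = FALSE)
    100 * counts$tn / total
  }
}

#' Overall accuracy
#'
#' @param counts A `confusion_counts` object.
#' @return `100 * (tp + tn) / total`, percent.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  100 * (counts$tp + counts$tn) / total
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in `[-1, 1]`.
#' If any marginal is zero the coefficient is undefined; 0 is returned
#' with attribute `flagged = TRUE`.
#'
#' @param counts A `confusion_counts` object.
#' @return MCC value.
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(marg == 0)) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  (tp * tn - fp * fn) / sqrt(prod(marg))
}

#' Wilks' lambda and canonical correlation from a discriminant eigenvalue
#'
#' For a single discriminant function with canonical eigenvalue `lambda`,
#' `Wilks = 1 / (1 + lambda)` and `R = sqrt(lambda / (1 + lambda))`, so
#' `R^2 = 1 - Wilks` exactly.
#'
#' @param lambda Canonical eigenvalue, `>= 0`.
#' @return List with `wilks` and `canonical_r`.
#' @examples
#' wilks_from_eigenvalue(1.241879)
#' @export
wilks_from_eigenvalue <- function(lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (lambda < 0) stop("eigenvalue must be non-negative", call. = FALSE)
  list(wilks = 1 / (1 + lambda),
       canonical_r = sqrt(lambda / (1 + lambda)))
}

#' Full evaluation report from confusion counts
#'
#' @param counts A `confusion_counts` object.
#' @return `data.frame` with the counts, per-class rates (percent),
#'   accuracy (percent), and MCC.
#' @export
metrics_report <- function(counts) {
  data.frame(
    tp = counts$tp, fp = counts$fp, tn = counts$tn, fn = counts$fn,
    rate_class_pos = per_class_rate(counts, 1),
    rate_class_neg = per_class_rate(counts, -1),
    accuracy = accuracy(counts),
    mcc = as.numeric(mcc(counts))
  )
}
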