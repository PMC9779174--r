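#' Confusion counts between a mask and reference labels
#'
#' Tallies per-pixel agreement between a candidate vegetation mask and
#' reference class labels, with vegetation as the positive class:
#' TP = reference vegetation predicted vegetation, TN = reference
#' non-vegetation predicted non-vegetation, FP / FN the two error cells.
#'
#' `confusion_counts()` builds the general r x r matrix from two label
#' vectors; `confusion_from_rois()` restricts the tally to the pixels of one
#' ROI role (reference class taken from the ROI labels).
#'
#' @param predicted,reference Vectors of equal length; coerced to factors
#'   over their union of levels.
#' @return An object of class `confusion`: the contingency matrix
#'   (reference in rows, prediction in columns) plus, for the binary
#'   vegetation case, named counts `TP`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(predicted, reference) {
  lev <- union(levels(factor(reference)), levels(factor(predicted)))
  m <- table(reference = factor(reference, lev), predicted = factor(predicted, lev))
  out <- list(matrix = unclass(m), N = sum(m))
  if (identical(sort(lev), sort(c("vegetation", "non-vegetation")))) {
    out$TP <- m["vegetation", "vegetation"]
    out$FN <- m["vegetation", "non-vegetation"]
    out$FP <- m["non-vegetation", "vegetation"]
    out$TN <- m["non-vegetation", "non-vegetation"]
  }
  structure(out, class = "confusion")
}

#' @rdname confusion_counts
#' @param mask Binary vegetation mask (1 = vegetation).
#' @param rois An [roi_set()] whose `role` regions supply reference labels.
#' @param role ROI role to evaluate over (default `"validation"`).
#' @export
confusion_from_rois <- function(mask, rois, role = "validation") {
  mask <- as_mask(mask)
  stopifnot(inherits(rois, "roi_set"))
  if (!all(dim(mask) == rois$dim))
    stop("mask dimensions do not match the ROI set's scene")
  px <- roi_pixels(rois, role)
  if (length(unique(px$class)) < 2L)
    stop("ROI role '", role, "' covers a single class; confusion needs both")
  pred <- ifelse(mask[px$pixel] == 1L, "vegetation", "non-vegetation")
  confusion_counts(pred, px$class)
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion> N =", x$N, "\n")
  print(x$matrix)
  invisible(x)
}

#' Overall accuracy
#'
#' The fraction of reference pixels whose predicted class matches the
#' reference: `OA = (TP + TN) / (TP + FN + FP + TN)` in the binary case,
#' `sum(diag) / N` in general.
#'
#' @param c A `confusion` object (or a square count matrix).
#' @return OA as a fraction in `[0, 1]`.
#' @examples
#' overall_accuracy(confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
overall_accuracy <- function(c) {
  m <- if (inherits(c, "confusion")) c$matrix else as.matrix(c)
  storage.mode(m) <- "double"   # pixel counts overflow integer products
  n <- sum(m)
  if (n == 0) stop("overall accuracy undefined for an empty confusion matrix")
  sum(diag(m)) / n
}

#' Kappa coefficient of agreement
#'
#' Chance-corrected agreement between prediction and reference:
#' `k = (N sum_i x_ii - sum_i x_i+ x_+i) / (N^2 - sum_i x_i+ x_+i)`,
#' where `x_i+` and `x_+i` are row and column sums. `k = 1` means complete
#' agreement; values near 0 mean chance-level agreement.
#'
#' @inheritParams overall_accuracy
#' @return Kappa, a real number `<= 1`.
#' @examples
#' kappa_coefficient(matrix(c(45, 5, 5, 45), 2))  # 0.8
#' @export
kappa_coefficient <- function(c) {
  m <- if (inherits(c, "confusion")) c$matrix else as.matrix(c)
  storage.mode(m) <- "double"   # pixel counts overflow integer products
  n <- sum(m)
  if (n == 0) stop("kappa undefined for an empty confusion matrix")
  chance <- sum(rowSums(m) * colSums(m))
  if (n^2 == chance)
    stop("kappa undefined: all pixels fall in one reference-and-predicted cell")
  (n * sum(diag(m)) - chance) / (n^2 - chance)
}

#' Relative error of FVC
#'
#' `RE = (V_SUP - V_VI) / V_SUP`, the error of an index-derived FVC
#' relative to the supervised-classification reference FVC. Both the signed
#' value and its magnitude are returned; grade-level summaries aggregate
#' `|RE|` so that over- and under-estimation cannot cancel.
#'
#' @param v_sup Reference FVC (percent), must be positive.
#' @param v_vi Index-derived FVC (percent).
#' @return Named numeric vector `c(re, abs_re)`.
#' @examples
#' relative_error(50, 45)  # re 0.1
#' @export
relative_error <- function(v_sup, v_vi) {
  if (!is.finite(v_sup) || v_sup <= 0)
    stop("reference FVC zero: RE undefined")
  re <- (v_sup - v_vi) / v_sup
  c(re = re, abs_re = abs(re))
}
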