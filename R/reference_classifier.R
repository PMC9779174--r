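#' Extract per-pixel training samples from ROIs
#'
#' Collects the raw `(R, G, B)` intensities and class labels of every pixel
#' in one ROI role. Chromatic coordinates `(r, g, b)` can be appended as
#' extra features.
#'
#' @param image An [rgb_image()].
#' @param rois An [roi_set()] on the same scene.
#' @param role ROI role to extract (default `"train"`).
#' @param chromatic_features Append `(r, g, b)` features (default `FALSE`).
#' @return A list with `x` (numeric feature matrix) and `y` (factor of
#'   `vegetation` / `non-vegetation`).
#' @export
extract_training_samples <- function(image, rois, role = "train",
                                     chromatic_features = FALSE) {
  image <- rgb_image(image)
  stopifnot(inherits(rois, "roi_set"))
  if (!all(dim(image)[1:2] == rois$dim))
    stop("image dimensions do not match the ROI set's scene")
  px <- roi_pixels(rois, role)
  x <- cbind(R = channel(image, 1)[px$pixel],
             G = channel(image, 2)[px$pixel],
             B = channel(image, 3)[px$pixel])
  if (chromatic_features) {
    ch <- normalize_chromatic(image)
    x <- cbind(x, r = ch[, , 1][px$pixel], g = ch[, , 2][px$pixel],
               b = ch[, , 3][px$pixel])
  }
  list(x = x, y = factor(px$class, c("non-vegetation", "vegetation")))
}

#' Fit the supervised reference pixel classifier
#'
#' A radial-basis-kernel support vector machine over per-pixel features,
#' the reference against which index-based masks are scored. Defaults follow
#' the reference protocol: RBF kernel with `gamma = 0.333` and no rejection
#' class (every pixel receives the argmax label). Features are standardized
#' internally before the kernel is applied.
#'
#' @param samples A list with `x` and `y` as from
#'   [extract_training_samples()].
#' @param gamma RBF kernel width parameter (default 0.333).
#' @param cost SVM cost parameter (default 1).
#' @param max_per_class Cap on training pixels per class; larger classes are
#'   sub-sampled deterministically under `seed` (default 10000).
#' @param seed Seed for the sub-sampling (default 1).
#' @return An object of class `pixel_classifier`.
#' @export
fit_pixel_classifier <- function(samples, gamma = 0.333, cost = 1,
                                 max_per_class = 10000L, seed = 1L) {
  x <- samples$x; y <- samples$y
  if (nlevels(droplevels(y)) < 2L)
    stop("training samples contain a single class; both classes are required")
  keep <- unlist(lapply(split(seq_along(y), y), function(idx) {
    if (length(idx) <= max_per_class) return(idx)
    set.seed(seed %% .Machine$integer.max)
    sample(idx, max_per_class)
  }), use.names = FALSE)
  model <- e1071::svm(x[keep, , drop = FALSE], droplevels(y[keep]),
                      kernel = "radial", gamma = gamma, cost = cost)
  structure(list(model = model, gamma = gamma, cost = cost,
                 n_features = ncol(x), fitted = TRUE),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> RBF SVM, gamma = %.3f, %d support vectors\n",
              x$gamma, sum(x$model$tot.nSV)))
  invisible(x)
}

#' Classify every pixel of a scene
#'
#' Applies a fitted [fit_pixel_classifier()] model to each pixel and returns
#' the binary vegetation mask whose FVC serves as the supervised reference
#' value `V_SUP`.
#'
#' @param classifier A fitted `pixel_classifier`.
#' @param image An [rgb_image()].
#' @param chromatic_features Must match the setting used at training time.
#' @return Integer 0/1 vegetation mask.
#' @export
classify_image <- function(classifier, image, chromatic_features = FALSE) {
  if (!inherits(classifier, "pixel_classifier") || !isTRUE(classifier$fitted))
    stop("classify_image needs a fitted pixel_classifier")
  image <- rgb_image(image)
  x <- cbind(R = as.numeric(channel(image, 1)),
             G = as.numeric(channel(image, 2)),
             B = as.numeric(channel(image, 3)))
  if (chromatic_features) {
    ch <- normalize_chromatic(image)
    x <- cbind(x, r = as.numeric(ch[, , 1]), g = as.numeric(ch[, , 2]),
               b = as.numeric(ch[, , 3]))
  }
  if (ncol(x) != classifier$n_features)
    stop("feature set does not match the classifier's training features")
  pred <- predict(classifier$model, x)
  as_mask(matrix(pred == "vegetation", dim(image)[1], dim(image)[2]))
}

#' Evaluate the reference classifier on test ROIs
#'
#' @param classifier A fitted `pixel_classifier`.
#' @param image The scene.
#' @param rois ROI set with a populated `test` role.
#' @param chromatic_features As at training time.
#' @return A list with the `confusion` object, `oa` and `kappa`.
#' @export
evaluate_classifier <- function(classifier, image, rois,
                                chromatic_features = FALSE) {
  s <- extract_training_samples(image, rois, role = "test",
                                chromatic_features = chromatic_features)
  pred <- predict(classifier$model, s$x)
  cm <- confusion_counts(as.character(pred), as.character(s$y))
  list(confusion = cm, oa = overall_accuracy(cm), kappa = kappa_coefficient(cm))
}
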