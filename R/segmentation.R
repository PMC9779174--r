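#' Otsu's between-class-variance threshold
#'
#' Finds the histogram threshold maximizing the between-class variance
#' `sigma_B^2(t) = w0(t) w1(t) (mu0(t) - mu1(t))^2` over an `n_bins`
#' histogram spanning the value range. Candidate thresholds are the internal
#' bin edges; ties are broken toward the smallest threshold so the result is
#' deterministic.
#'
#' @param values Finite numeric vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256, matching the 8-bit
#'   heritage of the imagery).
#' @return An object of class `otsu_threshold`: a list with `threshold`,
#'   `between_class_variance`, `histogram_bins`, and the histogram `breaks`.
#' @examples
#' otsu_threshold(c(0, 0, 0, 1, 1, 1))$threshold
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (anyNA(values) || !all(is.finite(values))) stop("values must be finite")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("degenerate: no threshold separates one value (all values equal ",
         format(rng[1]), ")")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(findInterval(values, breaks, rightmost.closed = TRUE), n_bins),
    nbins = n_bins
  )
  p <- counts / length(values)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)[-n_bins]               # class-0 mass below each internal edge
  m0 <- cumsum(p * mids)[-n_bins]        # class-0 first moment
  mu <- sum(p * mids)
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b2 <- rep(-Inf, n_bins - 1L)
  sigma_b2[ok] <- (mu * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  best <- which.max(sigma_b2)            # which.max takes the first (smallest t) tie
  structure(
    list(threshold = breaks[best + 1L],
         between_class_variance = sigma_b2[best],
         histogram_bins = n_bins,
         breaks = breaks),
    class = "otsu_threshold"
  )
}

#' @export
print.otsu_threshold <- function(x, ...) {
  cat(sprintf("<otsu_threshold> t = %.6g, sigma_B^2 = %.6g (%d bins)\n",
              x$threshold, x$between_class_variance, x$histogram_bins))
  invisible(x)
}

#' Decide which side of a threshold is vegetation
#'
#' Index formulas differ in sign convention: some score vegetation high
#' (e.g. ExG) and some low (e.g. ExR, RGRI, CIVE). The class whose pixels
#' have the higher mean green chromatic coordinate `g` is labeled
#' vegetation; on an exact tie the above-threshold class is chosen.
#'
#' @param index_map Numeric index map.
#' @param threshold Scalar threshold splitting the map into `> threshold`
#'   (above) and `<= threshold` (below).
#' @param chromatic The scene's [normalize_chromatic()] coordinates.
#' @param override Optional `"above"`/`"below"` manual polarity that skips
#'   the data-driven rule.
#' @return `"above"` or `"below"`: the vegetation side.
#' @export
resolve_polarity <- function(index_map, threshold, chromatic, override = NULL) {
  if (!is.null(override)) {
    return(match.arg(override, c("above", "below")))
  }
  above <- index_map > threshold
  if (!any(above) || all(above))
    stop("cannot resolve polarity: one side of the threshold is empty")
  gmat <- chromatic[, , 2]
  if (mean(gmat[above]) >= mean(gmat[!above])) "above" else "below"
}

#' Binarize an index map into a vegetation mask
#'
#' Composes [otsu_threshold()] and [resolve_polarity()]: thresholds the map
#' and labels the greener class as vegetation (1).
#'
#' @inheritParams resolve_polarity
#' @inheritParams otsu_threshold
#' @param polarity Optional manual polarity override.
#' @return Integer 0/1 matrix with attribute `threshold` holding the
#'   `otsu_threshold` result and attribute `polarity`.
#' @export
binarize <- function(index_map, chromatic, n_bins = 256L, polarity = NULL) {
  th <- otsu_threshold(index_map, n_bins)
  pol <- resolve_polarity(index_map, th$threshold, chromatic, override = polarity)
  mask <- if (pol == "above") index_map > th$threshold else index_map <= th$threshold
  mask <- as_mask(matrix(mask, nrow(index_map), ncol(index_map)))
  attr(mask, "threshold") <- th
  attr(mask, "polarity") <- pol
  mask
}
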