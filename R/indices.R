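#' Chromatic (brightness-normalized) coordinates
#'
#' Converts 8-bit channel intensities to chromatic coordinates
#' `r = R/(R+G+B)`, `g = G/(R+G+B)`, `b = B/(R+G+B)`, which remove overall
#' brightness so that indices built on them are invariant to global
#' illumination scaling. Black pixels (`R+G+B = 0`) have no defined hue and
#' are mapped to the neutral point `(1/3, 1/3, 1/3)`.
#'
#' @param image An [rgb_image()].
#' @return A `chromatic_image`: a `height x width x 3` double array with
#'   `r + g + b = 1` at every pixel.
#' @examples
#' img <- rgb_image(array(c(50, 100, 50), dim = c(1, 1, 3)))
#' normalize_chromatic(img)[1, 1, ]  # 0.25 0.50 0.25
#' @export
normalize_chromatic <- function(image) {
  image <- rgb_image(image)
  R <- channel(image, 1); G <- channel(image, 2); B <- channel(image, 3)
  s <- R + G + B
  zero <- s == 0
  s[zero] <- 1
  out <- array(c(R / s, G / s, B / s), dim = dim(image))
  if (any(zero)) for (k in 1:3) out[, , k][zero] <- 1 / 3
  structure(out, class = "chromatic_image")
}

# safe elementwise ratio: 0 wherever the denominator is 0
ratio0 <- function(num, den) {
  z <- den == 0
  den[z] <- 1
  out <- num / den
  out[z] <- 0
  out
}

#' @export
print.chromatic_image <- function(x, ...) {
  cat(sprintf("<chromatic_image> %d x %d pixels\n", dim(x)[1], dim(x)[2]))
  invisible(x)
}

# CIVE coefficients as printed in the source formulation; the green
# coefficient is overridable because published variants differ (0.881 vs 0.811)
CIVE_COEF <- c(r = 0.441, g = 0.881, b = 0.385, const = 18.78745)
VEG_ALPHA <- 0.667
COM_WEIGHTS <- c(exg = 0.25, exgr = 0.3, cive = 0.33, veg = 0.12)
COM2_WEIGHTS <- c(exg = 0.36, cive = 0.47, veg = 0.17)

# Index registry. Each entry evaluates one visible-band vegetation index as a
# per-pixel map. `space` records whether the formula reads raw 8-bit channels
# (R,G,B) or chromatic coordinates (r,g,b); either way `fun` receives both.
# All arithmetic is double precision (squared-channel indices overflow
# integer range).
make_registry <- function(cive_g = CIVE_COEF[["g"]]) {
  exg  <- function(ch) 2 * ch$g - ch$r - ch$b
  exr  <- function(ch) 1.4 * ch$r - ch$g
  cive <- function(ch) CIVE_COEF[["r"]] * ch$r - cive_g * ch$g +
    CIVE_COEF[["b"]] * ch$b + CIVE_COEF[["const"]]
  veg  <- function(ch) {
    z <- ch$r == 0 | ch$b == 0
    out <- ch$g / (pmax(ch$r, 1e-300)^VEG_ALPHA * pmax(ch$b, 1e-300)^(1 - VEG_ALPHA))
    out[z] <- 0
    out
  }
  list(
    GLI = list(full = "Green Leaf Index", space = "raw",
      fun = function(rw, ch) ratio0(2 * rw$G - rw$R - rw$B, 2 * rw$G + rw$R + rw$B)),
    ExG = list(full = "Excess Green", space = "chromatic",
      fun = function(rw, ch) exg(ch)),
    ExR = list(full = "Excess Red", space = "chromatic",
      fun = function(rw, ch) exr(ch)),
    ExB = list(full = "Excess Blue", space = "chromatic",
      fun = function(rw, ch) 1.4 * ch$b - ch$g),
    NGBDI = list(full = "Normalized Green Blue Difference Index", space = "raw",
      fun = function(rw, ch) ratio0(rw$G - rw$B, rw$G + rw$B)),
    NGRDI = list(full = "Normalized Green Red Difference Index", space = "raw",
      fun = function(rw, ch) ratio0(rw$G - rw$R, rw$G + rw$R)),
    ExGR = list(full = "Excess Green Minus Excess Red", space = "chromatic",
      fun = function(rw, ch) exg(ch) - exr(ch)),
    MGRVI = list(full = "Modified Green Red Vegetation Index", space = "raw",
      fun = function(rw, ch) ratio0(rw$G^2 - rw$R^2, rw$G^2 + rw$R^2)),
    RGBVI = list(full = "Red Green Blue Vegetation Index", space = "raw",
      fun = function(rw, ch) ratio0(rw$G^2 - rw$B * rw$R, rw$G^2 + rw$B * rw$R)),
    GBRI = list(full = "Green Blue Ratio Index", space = "chromatic",
      fun = function(rw, ch) ratio0(ch$b, ch$g)),
    RGRI = list(full = "Red Green Ratio Index", space = "chromatic",
      fun = function(rw, ch) ratio0(ch$r, ch$g)),
    CIVE = list(full = "Color Index of Vegetation", space = "chromatic",
      fun = function(rw, ch) cive(ch)),
    VEG = list(full = "Vegetative", space = "chromatic",
      fun = function(rw, ch) veg(ch)),
    DEVI = list(full = "Difference Excess Vegetation Index", space = "raw",
      fun = function(rw, ch) ratio0(rw$G + rw$R + rw$B, 3 * rw$G)),
    EGRBDI = list(full = "Excess Green Red Blue Difference Index", space = "raw",
      fun = function(rw, ch) ratio0((2 * rw$G)^2 - rw$B * rw$R,
                                    (2 * rw$G)^2 + rw$B * rw$R)),
    `V-MSAVI` = list(full = "Visible Band Modified Soil Adjusted Vegetation Index",
      space = "chromatic",
      fun = function(rw, ch) {
        radicand <- pmax((2 * ch$g + 1)^2 - 8 * (2 * ch$g - ch$r - ch$b), 0)
        (2 * ch$g + 1 - sqrt(radicand)) / 2
      }),
    g = list(full = "Green Chromatic Coordinates", space = "chromatic",
      fun = function(rw, ch) ch$g),
    COM = list(full = "Combined", space = "chromatic",
      fun = function(rw, ch) {
        e <- exg(ch)
        COM_WEIGHTS[["exg"]] * e + COM_WEIGHTS[["exgr"]] * (e - exr(ch)) +
          COM_WEIGHTS[["cive"]] * cive(ch) + COM_WEIGHTS[["veg"]] * veg(ch)
      }),
    COM2 = list(full = "Combined 2", space = "chromatic",
      fun = function(rw, ch) {
        COM2_WEIGHTS[["exg"]] * exg(ch) + COM2_WEIGHTS[["cive"]] * cive(ch) +
          COM2_WEIGHTS[["veg"]] * veg(ch)
      })
  )
}

.registry <- make_registry()

#' The 19-index registry
#'
#' @return `vi_names()` returns the 19 index identifiers in registry order;
#'   `vi_registry()` returns a data frame with each index's identifier, full
#'   name and input space (`raw` 8-bit channels vs `chromatic` coordinates).
#' @examples
#' vi_names()
#' @export
vi_names <- function() names(.registry)

#' @rdname vi_names
#' @export
vi_registry <- function() {
  data.frame(
    index = names(.registry),
    full_name = vapply(.registry, `[[`, "", "full"),
    input_space = vapply(.registry, `[[`, "", "space"),
    row.names = NULL
  )
}

#' Compute one vegetation-index map
#'
#' Evaluates the named visible-band vegetation index at every pixel.
#' Chromatic-space formulas are evaluated on [normalize_chromatic()] output;
#' raw-space ratio formulas return 0 at pixels whose denominator is 0, and
#' VEG returns 0 where `r` or `b` is 0, so every map is finite.
#'
#' @param image An [rgb_image()].
#' @param name One of [vi_names()].
#' @param chromatic Optional precomputed [normalize_chromatic()] result
#'   (recomputed if missing).
#' @return A numeric matrix of the image's shape with attribute `index_name`.
#' @examples
#' img <- rgb_image(array(c(60, 80, 40), dim = c(1, 1, 3)))
#' compute_index(img, "MGRVI")[1, 1]  # 0.28
#' @export
compute_index <- function(image, name, chromatic = NULL) {
  image <- rgb_image(image)
  if (length(name) != 1L || !name %in% names(.registry))
    stop("unknown vegetation index '", name, "'; valid names are: ",
         paste(names(.registry), collapse = ", "))
  if (is.null(chromatic)) chromatic <- normalize_chromatic(image)
  d <- dim(image)[1:2]
  rw <- list(R = channel(image, 1), G = channel(image, 2), B = channel(image, 3))
  ch <- list(r = matrix(chromatic[, , 1], d[1], d[2]),
             g = matrix(chromatic[, , 2], d[1], d[2]),
             b = matrix(chromatic[, , 3], d[1], d[2]))
  out <- .registry[[name]]$fun(rw, ch)
  stopifnot(all(is.finite(out)))
  attr(out, "index_name") <- name
  out
}

#' Compute all 19 vegetation-index maps
#'
#' @inheritParams compute_index
#' @return A named list of 19 index maps in registry order.
#' @export
compute_all_indices <- function(image, chromatic = NULL) {
  image <- rgb_image(image)
  if (is.null(chromatic)) chromatic <- normalize_chromatic(image)
  out <- lapply(names(.registry), function(nm) compute_index(image, nm, chromatic))
  names(out) <- names(.registry)
  out
}

#' Export an index map as CSV or single-band TIFF
#'
#' CSV stores the per-pixel values as a plain matrix (small images only);
#' TIFF stores a 32-bit float single band.
#'
#' @param map An index map from [compute_index()].
#' @param path Output path ending in `.csv` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_index_map <- function(map, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(map, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    rng <- range(map)
    scaled <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  } else stop("unsupported index-map format '.", ext, "'")
  invisible(path)
}
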