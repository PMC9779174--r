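# Independent oracles and small fixture builders shared across the suite.

# Exhaustive Otsu: exact between-class variance over every distinct midpoint
# between sorted adjacent values. Independent of the histogram implementation.
brute_force_otsu <- function(values) {
  v <- sort(unique(values))
  n <- length(values)
  splits <- (v[-1] + v[-length(v)]) / 2
  best_t <- NA_real_
  best_s <- -Inf
  for (t in splits) {
    lo <- values[values <= t]
    hi <- values[values > t]
    w0 <- length(lo) / n
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  list(threshold = best_t, sigma_b2 = best_s)
}

# Scalar per-pixel reference for every vegetation index, written as plain
# per-pixel arithmetic (loops, no vectorized reuse of the package's code).
scalar_index_reference <- function(image, name) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(NA_real_, h, w)
  a <- 0.667
  for (i in seq_len(h)) for (j in seq_len(w)) {
    R <- as.numeric(image[i, j, 1]); G <- as.numeric(image[i, j, 2])
    B <- as.numeric(image[i, j, 3])
    s <- R + G + B
    if (s > 0) { r <- R / s; g <- G / s; b <- B / s } else r <- g <- b <- 1 / 3
    exg <- 2 * g - r - b
    exr <- 1.4 * r - g
    cive <- 0.441 * r - 0.881 * g + 0.385 * b + 18.78745
    veg <- if (r == 0 || b == 0) 0 else g / (r^a * b^(1 - a))
    out[i, j] <- switch(name,
      GLI = if (2 * G + R + B == 0) 0 else (2 * G - R - B) / (2 * G + R + B),
      ExG = exg,
      ExR = exr,
      ExB = 1.4 * b - g,
      NGBDI = if (G + B == 0) 0 else (G - B) / (G + B),
      NGRDI = if (G + R == 0) 0 else (G - R) / (G + R),
      ExGR = exg - exr,
      MGRVI = if (G^2 + R^2 == 0) 0 else (G^2 - R^2) / (G^2 + R^2),
      RGBVI = if (G^2 + B * R == 0) 0 else (G^2 - B * R) / (G^2 + B * R),
      GBRI = if (g == 0) 0 else b / g,
      RGRI = if (g == 0) 0 else r / g,
      CIVE = cive,
      VEG = veg,
      DEVI = if (G == 0) 0 else (G + R + B) / (3 * G),
      EGRBDI = if ((2 * G)^2 + B * R == 0) 0
               else ((2 * G)^2 - B * R) / ((2 * G)^2 + B * R),
      `V-MSAVI` = {
        rad <- (2 * g + 1)^2 - 8 * (2 * g - r - b)
        (2 * g + 1 - sqrt(max(rad, 0))) / 2
      },
      g = g,
      COM = 0.25 * exg + 0.3 * (exg - exr) + 0.33 * cive + 0.12 * veg,
      COM2 = 0.36 * exg + 0.47 * cive + 0.17 * veg,
      stop("unknown index in scalar reference: ", name)
    )
  }
  out
}

# random valid 8-bit image; even values so that halving keeps integers
random_image <- function(h = 16, w = 16, lo = 0, hi = 255, even = FALSE) {
  vals <- sample(lo:hi, h * w * 3, replace = TRUE)
  if (even) vals <- 2L * (vals %/% 2L)
  rgb_image(array(vals, dim = c(h, w, 3)))
}

# one-pixel image helper
pixel_image <- function(R, G, B) rgb_image(array(c(R, G, B), dim = c(1, 1, 3)))

# two-palette toy scene: bright green patches on brown soil with a known mask
toy_scene <- function(h = 40, w = 40, veg_frac = 0.3, seed = 1) {
  set.seed(seed)
  mask <- matrix(0L, h, w)
  mask[seq_len(round(h * w * veg_frac))] <- 1L
  img <- array(0, dim = c(h, w, 3))
  veg <- c(60, 140, 50); soil <- c(160, 140, 100)
  for (k in 1:3) {
    img[, , k] <- ifelse(mask == 1L, veg[k], soil[k]) +
      sample(-3:3, h * w, replace = TRUE)
  }
  list(image = rgb_image(img), mask = mask)
}

# small scene spec suitable for fast tests (patches small relative to scene)
small_spec <- function(...) {
  scene_spec(height = 96L, width = 96L, patch_radius = c(2, 5), ...)
}
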