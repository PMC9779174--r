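#' Specification of a synthetic grassland scene
#'
#' Describes a nadir RGB grassland scene with a bimodal color structure:
#' greenish vegetation patches over yellow-brown soil. Defaults mimic
#' low-altitude UAV imagery of semi-arid desert grassland: vegetation mean
#' RGB (70, 120, 55) and soil mean RGB (160, 140, 105), elliptical
#' vegetation patches, and an optional `spectral_overlap` knob that pulls
#' the vegetation palette toward the soil palette (the main driver of index
#' failure at high cover).
#'
#' Palette variation has two components, mirroring real canopy/soil
#' texture: a multiplicative luminance term (`luminance_sd`, relative),
#' which scales all three channels together the way brightness texture does
#' and which chromatic coordinates cancel, and a smaller independent
#' per-channel chromatic term (`chromatic_sd`, DN). With the defaults
#' (relative luminance sd 0.08, chromatic sd 3) the total per-channel
#' spread is roughly 12 DN. `noise_sd` adds independent sensor noise on
#' top.
#'
#' @param height,width Scene size in pixels (default 512 x 512).
#' @param target_fvc Intended fractional vegetation coverage, percent.
#' @param vegetation_palette,soil_palette Lists with `mean` (RGB triple),
#'   `luminance_sd` (relative sd of the common multiplicative brightness
#'   term) and `chromatic_sd` (per-channel independent spread, DN).
#' @param patch_radius Range `c(min, max)` of patch semi-axes in pixels.
#' @param spectral_overlap In `[0, 1]`: 0 keeps the palettes apart, 1 makes
#'   vegetation identical to soil.
#' @param noise_sd Additive Gaussian sensor noise, DN.
#' @param shadow_fraction Fraction of vegetation pixels darkened as
#'   within-canopy shadow.
#' @param seed Integer seed; every draw of the generator flows from it.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(height = 512L, width = 512L, target_fvc = 30,
                       vegetation_palette = list(mean = c(70, 120, 55),
                                                 luminance_sd = 0.08,
                                                 chromatic_sd = 3),
                       soil_palette = list(mean = c(160, 140, 105),
                                           luminance_sd = 0.08,
                                           chromatic_sd = 3),
                       patch_radius = c(4, 14),
                       spectral_overlap = 0.15,
                       noise_sd = 2,
                       shadow_fraction = 0,
                       seed = 1L) {
  stopifnot(height >= 8, width >= 8,
            target_fvc >= 0, target_fvc <= 100,
            length(vegetation_palette$mean) == 3L,
            length(soil_palette$mean) == 3L,
            length(patch_radius) == 2L, patch_radius[1] >= 1,
            patch_radius[2] >= patch_radius[1],
            spectral_overlap >= 0, spectral_overlap <= 1,
            noise_sd >= 0, shadow_fraction >= 0, shadow_fraction <= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_fvc = target_fvc,
                 vegetation_palette = vegetation_palette,
                 soil_palette = soil_palette,
                 patch_radius = patch_radius,
                 spectral_overlap = spectral_overlap,
                 noise_sd = noise_sd,
                 shadow_fraction = shadow_fraction,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# lay random overlapping elliptical patches until the covered fraction
# reaches `target` percent; each patch adds well under the +/-2-point
# tolerance, so stopping at the first crossing stays inside it
grow_patch_mask <- function(height, width, target, patch_radius,
                            max_iter = 200000L) {
  mask <- matrix(FALSE, height, width)
  if (target <= 0) return(mask)
  npix <- height * width
  covered <- 0L
  need <- target / 100 * npix
  it <- 0L
  while (covered < need) {
    it <- it + 1L
    if (it > max_iter)
      stop("patch placement did not reach the target FVC within ",
           max_iter, " iterations; enlarge patch_radius or lower target_fvc")
    cy <- stats::runif(1, 1, height)
    cx <- stats::runif(1, 1, width)
    ra <- stats::runif(1, patch_radius[1], patch_radius[2])
    rb <- stats::runif(1, patch_radius[1], patch_radius[2])
    th <- stats::runif(1, 0, pi)
    rmax <- max(ra, rb)
    rows <- max(1L, floor(cy - rmax)):min(height, ceiling(cy + rmax))
    cols <- max(1L, floor(cx - rmax)):min(width, ceiling(cx + rmax))
    dy <- rows - cy
    dx <- cols - cx
    u <- outer(dy, dx, function(a, b) a * cos(th) + b * sin(th))
    v <- outer(dy, dx, function(a, b) -a * sin(th) + b * cos(th))
    inside <- (u / ra)^2 + (v / rb)^2 <= 1
    sub <- mask[rows, cols, drop = FALSE]
    added <- sum(inside & !sub)
    if (added == 0L) next
    mask[rows, cols] <- sub | inside
    covered <- covered + added
  }
  mask
}

#' Generate a synthetic grassland scene
#'
#' Vegetation is laid down as random overlapping elliptical patches until
#' the truth-mask FVC reaches the target (within the +/-2-point tolerance;
#' targets above 50% are generated as soil patches on a vegetation
#' background so dense covers converge equally fast). Pixel colors are
#' drawn per class from the palette (vegetation shifted toward soil by
#' `spectral_overlap`), plus additive Gaussian noise, clipped to 8 bits.
#' The generator is a pure function of the spec, including its seed.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene` with `image` ([rgb_image()]),
#'   `truth_mask` (0/1 matrix), `achieved_fvc` (percent), `intended_grade`
#'   and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(height = 64, width = 64, target_fvc = 25))
#' sc$achieved_fvc
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  invert <- spec$target_fvc > 50
  tgt <- if (invert) 100 - spec$target_fvc else spec$target_fvc
  mask <- grow_patch_mask(h, w, tgt, spec$patch_radius)
  if (invert) mask <- !mask
  veg_mean <- (1 - spec$spectral_overlap) * spec$vegetation_palette$mean +
    spec$spectral_overlap * spec$soil_palette$mean
  soil_mean <- spec$soil_palette$mean
  lum_sd <- ifelse(mask, spec$vegetation_palette$luminance_sd,
                   spec$soil_palette$luminance_sd)
  chr_sd <- ifelse(mask, spec$vegetation_palette$chromatic_sd,
                   spec$soil_palette$chromatic_sd)
  lum <- 1 + stats::rnorm(h * w, 0, 1) * lum_sd   # shared across channels
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    mu <- ifelse(mask, veg_mean[k], soil_mean[k])
    img[, , k] <- mu * lum + stats::rnorm(h * w, 0, chr_sd) +
      stats::rnorm(h * w, 0, spec$noise_sd)
  }
  if (spec$shadow_fraction > 0 && any(mask)) {
    vp <- which(mask)
    ns <- round(spec$shadow_fraction * length(vp))
    if (ns > 0) {
      sh <- sample(vp, ns)
      for (k in 1:3) {
        ck <- img[, , k]
        ck[sh] <- ck[sh] * 0.55
        img[, , k] <- ck
      }
    }
  }
  img <- round(pmin(pmax(img, 0), 255))
  truth <- as_mask(mask)
  achieved <- compute_fvc(truth)$fvc
  structure(list(image = rgb_image(img), truth_mask = truth,
                 achieved_fvc = achieved,
                 intended_grade = assign_grade(achieved),
                 spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d, FVC %.2f%% (%s), seed %d\n",
              x$spec$height, x$spec$width, x$achieved_fvc,
              as.character(x$intended_grade), x$spec$seed))
  invisible(x)
}

# per-grade target-FVC sampling bands, mirroring the spread of a five-grade
# field survey (severe scenes near-bare, non-desertification near-closed)
GRADE_TARGET_BANDS <- list(
  "Severe" = c(2, 4),
  "High" = c(7, 18),
  "Moderate" = c(25, 46),
  "Slight" = c(51.5, 56),
  "Non-desertification" = c(72, 97)
)

#' Generate a five-grade scene panel
#'
#' Produces `n_per_grade` scenes per desertification grade with target FVCs
#' sampled inside each grade's band. By default the non-desertification
#' scenes are generated with a raised `spectral_overlap` (0.45 instead of
#' the base spec's value), reflecting that dense desert-grassland canopies
#' are the least color-separable from soil.
#'
#' @param n_per_grade Scenes per grade (default 6).
#' @param base_spec A [scene_spec()] supplying everything except
#'   `target_fvc` and `seed`.
#' @param seed Panel seed; per-scene seeds are derived from it.
#' @param non_desertification_overlap Spectral overlap used for the
#'   non-desertification grade (default 0.45; set equal to
#'   `base_spec$spectral_overlap` to disable the raise).
#' @return A list of class `scene_panel`: `scenes` (list of
#'   `synthetic_scene`s) and `manifest` (data frame with scene id, seed,
#'   target and achieved FVC, grade).
#' @export
generate_grade_panel <- function(n_per_grade = 6L, base_spec = scene_spec(),
                                 seed = 1L,
                                 non_desertification_overlap = 0.45) {
  stopifnot(inherits(base_spec, "scene_spec"), n_per_grade >= 1L)
  set.seed(seed)
  scenes <- list()
  rows <- list()
  id <- 0L
  for (grade in GRADE_LEVELS) {
    band <- GRADE_TARGET_BANDS[[grade]]
    targets <- stats::runif(n_per_grade, band[1], band[2])
    for (i in seq_len(n_per_grade)) {
      id <- id + 1L
      sp <- base_spec
      sp$target_fvc <- targets[i]
      sp$seed <- (seed * 1000L + id * 7L) %% .Machine$integer.max
      if (grade == "Non-desertification")
        sp$spectral_overlap <- non_desertification_overlap
      sc <- generate_scene(sp)
      scenes[[id]] <- sc
      rows[[id]] <- data.frame(
        image = id, seed = sp$seed, target_fvc = targets[i],
        achieved_fvc = sc$achieved_fvc,
        grade = as.character(sc$intended_grade))
    }
  }
  structure(list(scenes = scenes, manifest = do.call(rbind, rows)),
            class = "scene_panel")
}

#' @export
print.scene_panel <- function(x, ...) {
  cat(sprintf("<scene_panel> %d scenes\n", length(x$scenes)))
  print(table(x$manifest$grade))
  invisible(x)
}

# place `count` non-overlapping pure-class square ROIs of side `side`;
# shrinks the side (not below 2) when placement stalls
place_square_rois <- function(truth, occupied, class_value, count, side,
                              role, class_label, max_attempts = 4000L) {
  h <- nrow(truth); w <- ncol(truth)
  cand <- which(truth == class_value)
  if (length(cand) == 0L)
    stop("no ", class_label, " pixels available for ", role, " ROIs")
  regions <- vector("list", count)
  for (i in seq_len(count)) {
    placed <- FALSE
    s <- side
    attempts <- 0L
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        if (s > 2L) { s <- s - 1L; attempts <- 0L; next }
        stop("insufficient pure ", class_label, " area to place ", count,
             " ", role, " ROIs")
      }
      center <- cand[sample.int(length(cand), 1L)]
      cr <- (center - 1L) %% h + 1L
      cc <- (center - 1L) %/% h + 1L
      r0 <- cr - (s %/% 2L); c0 <- cc - (s %/% 2L)
      if (r0 < 1L || c0 < 1L || r0 + s - 1L > h || c0 + s - 1L > w) next
      rows <- r0:(r0 + s - 1L); cols <- c0:(c0 + s - 1L)
      block_t <- truth[rows, cols]
      if (!all(block_t == class_value)) next
      if (any(occupied[rows, cols])) next
      occupied[rows, cols] <- TRUE
      regions[[i]] <- list(role = role, class = class_label,
                           pixels = rect_pixels(r0, c0, s, s, c(h, w)),
                           bbox = c(r0, c0, s, s))
      placed <- TRUE
    }
  }
  list(regions = regions, occupied = occupied)
}

#' Sample train / test / validation ROIs from a synthetic scene
#'
#' Draws non-overlapping square ROI patches from pure-class areas of the
#' truth mask. Train and test ROIs are small fixed-size squares; validation
#' ROIs are sized so that they total about 12% of the scene's pixels,
#' allocated to the two classes in proportion to their true cover
#' (stratified sampling). Roles are pixel-disjoint by construction.
#'
#' @param scene A [generate_scene()] result.
#' @param counts List with two-element vectors `train`, `test`,
#'   `validation`: `c(n_vegetation, n_soil)` ROIs per role (defaults
#'   60/60, 15/15, 80/80).
#' @param validation_fraction Target total validation area as a fraction of
#'   the scene (default 0.12).
#' @param train_test_side Side of the train/test squares, pixels (default 3).
#' @param seed Sampling seed.
#' @return An [roi_set()].
#' @export
sample_rois <- function(scene,
                        counts = list(train = c(60L, 60L), test = c(15L, 15L),
                                      validation = c(80L, 80L)),
                        validation_fraction = 0.12,
                        train_test_side = 3L,
                        seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(seed %% .Machine$integer.max)
  truth <- scene$truth_mask
  h <- nrow(truth); w <- ncol(truth)
  npix <- h * w
  fvc <- scene$achieved_fvc / 100
  occupied <- matrix(FALSE, h, w)
  regions <- list()
  classes <- data.frame(label = c("vegetation", "non-vegetation"),
                        value = c(1L, 0L), share = c(fvc, 1 - fvc))
  for (role in c("train", "test", "validation")) {
    cnt <- counts[[role]]
    if (is.null(cnt)) next
    for (ci in 1:2) {
      n_roi <- cnt[ci]
      if (n_roi == 0L) next
      if (classes$share[ci] == 0)
        stop("scene has no ", classes$label[ci], " pixels; cannot place ",
             role, " ROIs")
      side <- if (role == "validation") {
        area_per_roi <- validation_fraction * npix * classes$share[ci] / n_roi
        max(2L, min(30L, as.integer(round(sqrt(area_per_roi)))))
      } else as.integer(train_test_side)
      res <- place_square_rois(truth, occupied, classes$value[ci], n_roi,
                               side, role, classes$label[ci])
      occupied <- res$occupied
      regions <- c(regions, res$regions)
    }
  }
  roi_set(regions, c(h, w))
}
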