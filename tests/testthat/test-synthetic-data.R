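test_that("scene generation is a pure function of the spec", {
  sp <- small_spec(target_fvc = 20, seed = 31)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(unclass(a$truth_mask), unclass(b$truth_mask))
  expect_identical(a$achieved_fvc, b$achieved_fvc)
})

test_that("boundary targets behave exactly", {
  empty <- generate_scene(small_spec(target_fvc = 0, seed = 1))
  expect_true(all(empty$truth_mask == 0L))
  expect_equal(empty$achieved_fvc, 0)
  full <- generate_scene(small_spec(target_fvc = 100, seed = 1))
  expect_true(all(full$truth_mask == 1L))
  expect_equal(full$achieved_fvc, 100)
})

test_that("achieved FVC lands within tolerance of the target across the bands", {
  for (tf in c(3, 12, 30, 53, 85)) {
    sc <- generate_scene(small_spec(target_fvc = tf, seed = 40 + tf))
    expect_lt(abs(sc$achieved_fvc - tf), 2)
    expect_equal(as.character(assign_grade(sc$achieved_fvc)),
                 as.character(sc$intended_grade))
  }
})

test_that("class color separation shrinks monotonically with spectral overlap", {
  seps <- vapply(c(0, 0.3, 0.6), function(ov) {
    sc <- generate_scene(scene_spec(height = 128L, width = 128L,
                                    target_fvc = 40, spectral_overlap = ov,
                                    patch_radius = c(3, 7), seed = 77))
    ch <- normalize_chromatic(sc$image)
    g <- ch[, , 2]
    mean(g[sc$truth_mask == 1L]) - mean(g[sc$truth_mask == 0L])
  }, 0)
  expect_true(all(diff(seps) < 0))
  expect_gt(seps[1], 0)
})

test_that("ExG + Otsu FVC tracks the truth mask on a default scene", {
  sc <- generate_scene(scene_spec(height = 256L, width = 256L,
                                  target_fvc = 30, seed = 12))
  expect_gte(sc$achieved_fvc, 28)
  expect_lte(sc$achieved_fvc, 32)
  ch <- normalize_chromatic(sc$image)
  mask <- binarize(compute_index(sc$image, "ExG", ch), ch)
  expect_lt(abs(compute_fvc(mask)$fvc - sc$achieved_fvc), 2)
})

test_that("the grade panel is balanced, deterministic, and correctly labeled", {
  base <- small_spec()
  p <- generate_grade_panel(n_per_grade = 2L, base_spec = base, seed = 9)
  expect_length(p$scenes, 10)
  expect_true(all(table(p$manifest$grade) == 2))
  for (sc in p$scenes)
    expect_equal(as.character(assign_grade(sc$achieved_fvc)),
                 as.character(sc$intended_grade))
  # non-desertification scenes carry the raised overlap
  non <- p$manifest$grade == "Non-desertification"
  for (i in which(non))
    expect_equal(p$scenes[[i]]$spec$spectral_overlap, 0.45)
  p2 <- generate_grade_panel(n_per_grade = 2L, base_spec = base, seed = 9)
  expect_identical(p$manifest, p2$manifest)
  expect_identical(unclass(p$scenes[[3]]$image), unclass(p2$scenes[[3]]$image))
})

test_that("ROI sampling respects counts, purity, disjointness and area", {
  sc <- generate_scene(scene_spec(target_fvc = 30, seed = 21))
  rois <- sample_rois(sc, seed = 2)
  tab <- roi_counts(rois)
  expect_equal(as.integer(tab["train", ]), c(60L, 60L))
  expect_equal(as.integer(tab["test", ]), c(15L, 15L))
  expect_equal(as.integer(tab["validation", ]), c(80L, 80L))
  # purity: ROI labels agree with the truth mask at every pixel
  for (role in c("train", "test", "validation")) {
    px <- roi_pixels(rois, role)
    expect_true(all((sc$truth_mask[px$pixel] == 1L) ==
                      (px$class == "vegetation")), info = role)
  }
  # pixel-disjoint roles
  all_px <- lapply(c("train", "test", "validation"),
                   function(r) roi_pixels(rois, r)$pixel)
  expect_equal(length(unique(unlist(all_px))), length(unlist(all_px)))
  # validation area within 12% +/- 1% of the scene
  vfrac <- length(all_px[[3]]) / prod(rois$dim)
  expect_gt(vfrac, 0.11)
  expect_lt(vfrac, 0.13)
})

test_that("ROI sampling fails cleanly when a class is absent", {
  bare <- generate_scene(small_spec(target_fvc = 0, seed = 3))
  expect_error(sample_rois(bare, seed = 1), "no vegetation pixels|cannot place")
})

test_that("ROI rectangles round-trip through the CSV carrier", {
  sc <- generate_scene(scene_spec(height = 128L, width = 128L, target_fvc = 40,
                                  patch_radius = c(3, 7), seed = 5))
  rois <- sample_rois(sc, counts = list(train = c(8L, 8L), test = c(4L, 4L),
                                        validation = c(10L, 10L)), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_roi_csv(rois, path)
  back <- read_roi_csv(path, dim = rois$dim)
  expect_equal(length(back$regions), length(rois$regions))
  for (i in seq_along(rois$regions))
    expect_equal(sort(back$regions[[i]]$pixels), sort(rois$regions[[i]]$pixels))
})

test_that("ROI labeled-mask PNG round-trips the validation pixels", {
  sc <- generate_scene(scene_spec(height = 128L, width = 128L, target_fvc = 40,
                                  patch_radius = c(3, 7), seed = 5))
  rois <- sample_rois(sc, counts = list(validation = c(10L, 10L)), seed = 6)
  path <- withr::local_tempfile(fileext = ".png")
  write_roi_mask_png(rois, path, role = "validation")
  back <- read_roi_mask_png(path, role = "validation")
  orig <- roi_pixels(rois, "validation")
  got <- roi_pixels(back, "validation")
  expect_setequal(orig$pixel[orig$class == "vegetation"],
                  got$pixel[got$class == "vegetation"])
  expect_setequal(orig$pixel[orig$class == "non-vegetation"],
                  got$pixel[got$class == "non-vegetation"])
})
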