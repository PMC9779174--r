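test_that("chromatic normalization gives exact fractions and handles black pixels", {
  expect_equal(as.numeric(normalize_chromatic(pixel_image(100, 100, 100))),
               rep(1 / 3, 3))
  expect_equal(as.numeric(normalize_chromatic(pixel_image(50, 100, 50))),
               c(0.25, 0.5, 0.25))
  expect_equal(as.numeric(normalize_chromatic(pixel_image(0, 0, 0))),
               rep(1 / 3, 3))
  set.seed(11)
  img <- random_image(12, 9)
  ch <- normalize_chromatic(img)
  expect_true(all(abs(ch[, , 1] + ch[, , 2] + ch[, , 3] - 1) < 1e-9))
  expect_true(all(ch >= 0 & ch <= 1))
})

test_that("rgb_image rejects malformed input", {
  expect_error(rgb_image(matrix(1, 3, 3)), "height x width x 3")
  expect_error(rgb_image(array(-1, dim = c(2, 2, 3))), "\\[0, 255\\]")
  expect_error(rgb_image(array(1.5, dim = c(2, 2, 3))), "integers")
})

test_that("hand-computed index values are reproduced", {
  # pure green: (r,g,b) = (0,1,0) so ExG = 2
  expect_equal(compute_index(pixel_image(0, 255, 0), "ExG")[1, 1], 2)
  # any gray pixel: GLI = 0 by symmetry
  for (v in c(1, 128, 255))
    expect_equal(compute_index(pixel_image(v, v, v), "GLI")[1, 1], 0)
  # CIVE at gray: (0.441 - 0.881 + 0.385)/3 + 18.78745
  expect_equal(compute_index(pixel_image(77, 77, 77), "CIVE")[1, 1],
               (0.441 - 0.881 + 0.385) / 3 + 18.78745, tolerance = 1e-12)
  # MGRVI by direct arithmetic: (80^2 - 60^2)/(80^2 + 60^2)
  expect_equal(compute_index(pixel_image(60, 80, 40), "MGRVI")[1, 1], 0.28)
  # DEVI literal reading: (G+R+B)/(3G); 0 where G = 0
  expect_equal(compute_index(pixel_image(30, 60, 90), "DEVI")[1, 1], 1)
  expect_equal(compute_index(pixel_image(30, 0, 90), "DEVI")[1, 1], 0)
  # VEG undefined at r = 0 or b = 0 maps to 0
  expect_equal(compute_index(pixel_image(0, 100, 50), "VEG")[1, 1], 0)
  expect_equal(compute_index(pixel_image(100, 100, 0), "VEG")[1, 1], 0)
})

test_that("unknown index names are rejected with the list of valid names", {
  img <- pixel_image(1, 2, 3)
  expect_error(compute_index(img, "NDVI"), "GLI.*COM2")
  expect_error(compute_index(img, "NDVI"), "unknown vegetation index")
})

test_that("compute_all_indices returns all 19 maps in registry order", {
  expect_length(vi_names(), 19)
  expect_equal(anyDuplicated(vi_names()), 0)
  img <- random_image(6, 6)
  maps <- compute_all_indices(img)
  expect_named(maps, vi_names())
  # uniform gray image: green-excess and normalized-difference indices vanish
  gray <- rgb_image(array(90L, dim = c(4, 4, 3)))
  gmaps <- compute_all_indices(gray)
  for (nm in c("ExG", "GLI", "NGRDI", "NGBDI", "MGRVI"))
    expect_true(all(gmaps[[nm]] == 0), info = nm)
  # ExGR at gray is the constant -(ExR at gray) = -(1.4 - 1)/3
  expect_equal(unique(as.numeric(gmaps$ExGR)), -0.4 / 3, tolerance = 1e-12)
})

test_that("ratio-form indices are invariant to global intensity scaling", {
  set.seed(7)
  img <- random_image(10, 10, lo = 20, hi = 120, even = TRUE)
  scale_invariant <- c("ExG", "ExR", "ExB", "ExGR", "CIVE", "VEG", "COM",
                       "COM2", "GLI", "NGBDI", "NGRDI", "MGRVI", "RGBVI",
                       "GBRI", "RGRI", "EGRBDI", "g", "DEVI")
  for (c_fac in c(0.5, 2)) {
    scaled <- rgb_image(unclass(img) * c_fac)
    for (nm in scale_invariant) {
      expect_equal(compute_index(scaled, nm), compute_index(img, nm),
                   tolerance = 1e-9, ignore_attr = TRUE,
                   info = paste(nm, "at c =", c_fac))
    }
  }
})

test_that("index maps stay within their algebraic bounds and are finite", {
  set.seed(21)
  for (rep in 1:3) {
    img <- random_image(12, 12)
    maps <- compute_all_indices(img)
    for (nm in c("GLI", "NGBDI", "NGRDI", "MGRVI", "RGBVI", "EGRBDI"))
      expect_true(all(maps[[nm]] >= -1 & maps[[nm]] <= 1), info = nm)
    expect_true(all(maps$g >= 0 & maps$g <= 1))
    expect_true(all(maps$ExG >= -1 & maps$ExG <= 2))
    for (nm in vi_names())
      expect_true(all(is.finite(maps[[nm]])), info = nm)
  }
})

test_that("vectorized maps equal the scalar per-pixel reference", {
  set.seed(33)
  img <- random_image(16, 16, lo = 0, hi = 255)
  # include degenerate pixels
  img[1, 1, ] <- 0L
  img <- rgb_image(unclass(img))
  ch <- normalize_chromatic(img)
  for (nm in vi_names()) {
    expect_equal(compute_index(img, nm, ch), scalar_index_reference(img, nm),
                 tolerance = 1e-9, ignore_attr = TRUE, info = nm)
  }
})

test_that("index maps round-trip through CSV export", {
  img <- random_image(5, 4)
  map <- compute_index(img, "ExG")
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_map(map, path)
  back <- as.matrix(utils::read.csv(path, header = FALSE))
  expect_equal(unname(back), unname(unclass(map)), tolerance = 1e-12,
               ignore_attr = TRUE)
})
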