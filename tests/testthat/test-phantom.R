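test_that("generated lesions have the requested chord and band/fluid contrast", {
  cfg <- noiseless_config(seed = 7)
  g <- generate_bscan(cfg, 50, seed = 7)
  expect_equal(g$ann$right[["x"]] - g$ann$left[["x"]], 50)
  expect_lt(g$ann$left[["x"]], g$ann$right[["x"]])
  expect_equal(g$ann$left[["y"]], g$ann$right[["y"]])  # chord on one row
  # noiseless phantom is piecewise constant: each endpoint is fluid-dark and
  # the pixel 5 px laterally outside the dome is band-bright
  contrast <- min(cfg$band_intensity_levels) - cfg$background_level
  px <- g$scan$pixels
  lv <- px[g$ann$left[["y"]] + 1, g$ann$left[["x"]] + 1]
  lo <- px[g$ann$left[["y"]] + 1, g$ann$left[["x"]] + 1 - 5]
  rv <- px[g$ann$right[["y"]] + 1, g$ann$right[["x"]] + 1]
  ro <- px[g$ann$right[["y"]] + 1, g$ann$right[["x"]] + 1 + 5]
  expect_gte(lo - lv, contrast)
  expect_gte(ro - rv, contrast)
  expect_true(all(px >= 0 & px <= 255))
})

test_that("the same configuration and seed reproduce the image bit for bit", {
  cfg <- phantom_config(seed = 11)
  a <- generate_bscan(cfg, 40, seed = 11)
  b <- generate_bscan(cfg, 40, seed = 11)
  expect_identical(a$scan$pixels, b$scan$pixels)
  expect_identical(a$ann, b$ann)
  s1 <- generate_patient_series(phantom_config(seed = 12))
  s2 <- generate_patient_series(phantom_config(seed = 12))
  expect_identical(lapply(s1$scans, function(p) p$scan$pixels),
                   lapply(s2$scans, function(p) p$scan$pixels))
})

test_that("out-of-range diameters are rejected with an explicit message", {
  cfg <- phantom_config(seed = 1)
  expect_error(generate_bscan(cfg, 3, seed = 1), "diameter")
  expect_error(generate_bscan(cfg, 127, seed = 1), "diameter")
})

test_that("per-frame diameters follow the chord-of-sphere profile", {
  # closed-form enumeration (the profile formula evaluated directly)
  closed_form <- function(d_max, n) {
    k <- 0:(n - 1)
    pmax(round(d_max * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2))), 4)
  }
  expect_equal(diameter_profile(60, 3), as.integer(c(4, 60, 4)))
  expect_equal(diameter_profile(48, 5)[3], 48L)
  for (n in c(3L, 5L, 9L, 24L)) {
    s <- generate_patient_series(phantom_config(n_frames_per_patient = n,
                                                seed = 20 + n))
    diams <- vapply(s$scans, function(p)
      p$ann$right[["x"]] - p$ann$left[["x"]], numeric(1))
    expect_equal(diams, as.numeric(closed_form(s$d_max, n)))
    expect_equal(max(diams), as.numeric(s$d_max))
    frames <- vapply(s$scans, function(p) p$scan$frame_index, integer(1))
    expect_true(all(diff(frames) > 0))
  }
})

test_that("speckle perturbation grows monotonically with its scale", {
  base <- generate_bscan(noiseless_config(seed = 31), 44, seed = 31)$scan$pixels
  mads <- vapply(c(0.05, 0.15, 0.3), function(s) {
    cfg <- phantom_config(speckle_sigma = s, seed = 31)
    mean(abs(generate_bscan(cfg, 44, seed = 31)$scan$pixels - base))
  }, numeric(1))
  expect_true(all(diff(mads) > 0))
})

test_that("horizontal flip mirrors coordinates and swaps the side labels", {
  px <- matrix(0, 80, 100)
  scan <- bscan(px)
  ann <- annotation(c(10, 40), c(60, 40))
  fl <- augment_hflip(scan, ann)
  expect_equal(unname(fl$ann$left), c(39, 40))
  expect_equal(unname(fl$ann$right), c(89, 40))
  back <- augment_hflip(fl$scan, fl$ann)      # involution
  expect_identical(back$scan$pixels, scan$pixels)
  expect_equal(back$ann, ann)
})

test_that("shifts translate image and points together and respect bounds", {
  g <- generate_bscan(noiseless_config(seed = 5), 30, seed = 5)
  id <- augment_shift(g$scan, g$ann, 0, 0)
  expect_identical(id$scan$pixels, g$scan$pixels)
  expect_equal(id$ann, g$ann)
  sh <- augment_shift(g$scan, g$ann, 7, -3)
  expect_equal(sh$ann$left, g$ann$left + c(7, -3))
  # interior pixels move rigidly
  expect_equal(sh$scan$pixels[20:60, 20:60], g$scan$pixels[23:63, 13:53])
  expect_error(augment_shift(g$scan, g$ann, 1000, 0), "out of bounds")
})

test_that("datasets round-trip through PNG images and a CSV manifest", {
  cfg <- phantom_config(n_frames_per_patient = 3, seed = 41)
  series <- list(generate_patient_series(cfg, "pa", seed = 41),
                 generate_patient_series(cfg, "pb", seed = 42))
  dir <- withr::local_tempdir()
  write_dataset(series, dir)
  back <- read_dataset(dir)
  expect_length(back, 2L)
  for (i in 1:2) {
    for (k in 1:3) {
      expect_identical(back[[i]]$scans[[k]]$scan$pixels,
                       series[[i]]$scans[[k]]$scan$pixels)
      expect_equal(back[[i]]$scans[[k]]$ann, series[[i]]$scans[[k]]$ann)
    }
  }
})

test_that("malformed manifests fail naming the row; empty directories read as empty", {
  cfg <- phantom_config(n_frames_per_patient = 2, seed = 43)
  dir <- withr::local_tempdir()
  write_dataset(list(generate_patient_series(cfg, "pa", seed = 43)), dir)
  m <- read.csv(file.path(dir, "manifest.csv"))
  m$left_x[2] <- "abc"
  write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "row 2")
  m$left_x[2] <- 10.5
  write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "row 2")
  expect_identical(read_dataset(withr::local_tempdir()), list())
})
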