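# Rigid transforms, resampling, registration, ROI extraction.

test_that("transform algebra: composition with the inverse is the identity", {
  tr <- rigid_transform(theta = 7.3, tx = 1.2, ty = -0.8)
  id <- compose_transform(tr, invert_transform(tr))
  expect_lt(abs(id$theta), 1e-9)
  expect_lt(abs(id$tx), 1e-9)
  expect_lt(abs(id$ty), 1e-9)
})

test_that("resampling basics: identity, constants, label preservation", {
  tr <- truth_one()
  img <- as_volume(tr$t2)
  expect_identical(resample(img, rigid_transform(0, 0, 0)), img)

  const <- array(5, dim = c(32, 32, 1))
  out <- resample(const, rigid_transform(3, 0.4, -0.2), spacing = c(1, 1, 1))
  inside <- is.finite(out)
  expect_true(all(abs(out[inside] - 5) < 1e-12))

  mask <- tr$masks$brain * 1
  outm <- resample(mask, rigid_transform(4, 0.3, 0.1),
                   spacing = tr$spacing, interpolation = "nearest",
                   na_value = 0)
  expect_true(all(outm %in% c(0, 1)))
  expect_error(resample(img, rigid_transform(1, 0, 0),
                        interpolation = "cubic"))
})

test_that("a known translation moves the brain centroid by that amount", {
  tr <- truth_one()
  cp <- simulate_cpmg_series(tr, snr = Inf)
  shift <- rigid_transform(0, 2 * tr$spacing[1], 0)
  mis <- apply_known_misalignment(cp, shift)
  expect_equal(mis$misalignment, shift)
  c0 <- image_centroid(cp$data[, , 1, 1])
  c1 <- image_centroid(mis$data[, , 1, 1])
  expect_equal(c1[1] - c0[1], 2, tolerance = 0.02)
  expect_equal(c1[2] - c0[2], 0, tolerance = 0.02)
  # out-of-bounds transforms are rejected
  expect_error(apply_known_misalignment(cp, rigid_transform(20, 0, 0)),
               class = "ischemri_bounds")
  expect_error(apply_known_misalignment(cp, rigid_transform(0, 99, 0)),
               class = "ischemri_bounds")
})

test_that("self-registration returns the identity", {
  tr <- truth_one()
  img <- simulate_cpmg_series(tr, snr = 40, seed = 4L)$data[, , 1, 1]
  xf <- register_rigid(img, img, spacing = tr$spacing)
  expect_lt(abs(xf$theta), 0.1)
  expect_lt(abs(xf$tx) / tr$spacing[1], 0.05)
  expect_lt(abs(xf$ty) / tr$spacing[2], 0.05)
})

test_that("registration recovers a known misalignment at SNR 40", {
  tr <- truth_one()
  cp <- simulate_cpmg_series(tr, snr = 40, seed = 6L)
  fixed <- cp$data[, , 1, 1]
  T0 <- rigid_transform(5, 1.0, -0.5)
  mis <- apply_known_misalignment(cp, T0)
  rec <- register_rigid(mis$data[, , 1, 1], fixed, spacing = tr$spacing)
  expect_rec <- invert_transform(T0)
  expect_lt(abs(rec$theta - expect_rec$theta), 0.5)
  expect_lt(abs(rec$tx - expect_rec$tx), 0.1)   # mm (~1/3 voxel)
  expect_lt(abs(rec$ty - expect_rec$ty), 0.1)
})

test_that("transform round trip loses less than 1% RMS inside the brain", {
  tr <- truth_one()
  img <- simulate_cpmg_series(tr, snr = Inf)$data[, , 1, 1]
  T0 <- rigid_transform(8, 0.7, -0.9)
  fwd <- resample(as_volume(img), T0, spacing = tr$spacing, na_value = 0)
  back <- resample(fwd, invert_transform(T0), spacing = tr$spacing,
                   na_value = 0)[, , 1]
  # erode the brain mask to exclude edge interpolation
  er <- tr$masks$brain[, , 1]
  er <- er & rbind(FALSE, er[-nrow(er), ]) & rbind(er[-1, ], FALSE) &
        cbind(FALSE, er[, -ncol(er)]) & cbind(er[, -1], FALSE)
  for (k in 1:2) er <- er & rbind(FALSE, er[-nrow(er), ]) &
        rbind(er[-1, ], FALSE) & cbind(FALSE, er[, -ncol(er)]) &
        cbind(er[, -1], FALSE)
  rms <- sqrt(mean((back[er] - img[er])^2)) / sqrt(mean(img[er]^2))
  expect_lt(rms, 0.01)
})

test_that("registration errors on empty or non-overlapping inputs", {
  blank <- array(0, dim = c(32, 32, 1))
  img <- array(0, dim = c(32, 32, 1)); img[10:20, 10:20, 1] <- 1
  expect_error(register_rigid(blank, img), class = "ischemri_registration")
  far <- array(0, dim = c(32, 32, 1)); far[28:32, 28:32, 1] <- 1
  expect_error(register_rigid(far, img), class = "ischemri_registration")
})

test_that("ROI summaries: constants, mixtures, and errors", {
  atlas <- default_atlas()
  vals <- array(42, dim = atlas$dim)
  m <- parameter_map(vals, "T2", atlas$masks$brain, atlas$spacing)
  s <- roi_summary(m, atlas, "cortical_mca")
  expect_equal(s$mean, 42); expect_equal(s$sd, 0)
  expect_equal(s$n, sum(atlas$rois$cortical_mca))

  roi <- atlas$rois$cortical_mca
  vals2 <- array(10, dim = atlas$dim)
  idx <- which(roi)
  vals2[idx[seq(1, length(idx), by = 2)]] <- 30
  vals2[idx[seq(2, length(idx), by = 2)]] <- 10
  m2 <- parameter_map(vals2, "T2", atlas$masks$brain, atlas$spacing)
  expect_equal(roi_summary(m2, atlas, "cortical_mca")$mean, 20)

  expect_error(roi_summary(m, atlas, "nope"), class = "ischemri_roi")
  empty <- parameter_map(vals, "T2", atlas$masks$brain & FALSE, atlas$spacing)
  expect_error(roi_summary(empty, atlas, "cortical_mca"),
               class = "ischemri_roi")
})

test_that("mirror-ROI ratio is exactly 1 for a mirrored map and tracks
           fixture values otherwise", {
  atlas <- default_atlas()
  set.seed(2)
  half <- array(runif(prod(atlas$dim), 10, 20), dim = atlas$dim)
  sym <- (half + mirror_mask(half)) / 2
  m <- parameter_map(sym, "CBF", atlas$masks$brain, atlas$spacing)
  expect_equal(ipsi_contra_ratio(m, atlas, "cortical_mca"), 1)
  # arithmetic on a hemisphere-contrast map
  vals <- array(148.4, dim = atlas$dim)
  vals[atlas$masks$ipsilateral] <- 28.2
  m2 <- parameter_map(vals, "CBF", atlas$masks$brain, atlas$spacing)
  expect_equal(ipsi_contra_ratio(m2, atlas, "cortical_mca"), 0.19,
               tolerance = 1e-3)
})

test_that("transforms serialize to JSON and back", {
  tr <- rigid_transform(3.25, -0.75, 0.5, fixed_grid = "atlas")
  p <- tempfile(fileext = ".json")
  write_transform(tr, p)
  back <- read_transform(p)
  expect_equal(back$theta, tr$theta)
  expect_equal(back$tx, tr$tx)
  expect_equal(back$ty, tr$ty)
  expect_equal(back$fixed_grid, "atlas")
})
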