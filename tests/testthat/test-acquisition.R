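test_that("forward projection matches analytic chord lengths of a disk", {
  spec <- build_calibration_phantom("water", 10)
  g <- rasterize_phantom(spec, 256, 0.59)
  geo <- small_geometry(n_angles = 8)
  li <- forward_project(g, geo)
  r <- 50  # mm
  s <- geo$det_pos_mm
  chord_cm <- ifelse(abs(s) < r, 2 * sqrt(pmax(r^2 - s^2, 0)), 0) / 10
  # water raster is 1 g/mL -> integrals equal chord length in cm
  inside <- abs(s) < 0.9 * r
  expect_equal(li$water[inside, 1], chord_cm[inside], tolerance = 0.01)
  # rays missing the body
  expect_equal(li$water[abs(s) > r + 2, 1],
               rep(0, sum(abs(s) > r + 2)))
  # rotational symmetry of a centered disk
  for (a in 2:8)
    expect_equal(li$water[, a], li$water[, 1], tolerance = 0.005)
})

test_that("bin sinogram noise is Poisson with the dose-scaled mean and is seed-reproducible", {
  sp <- tube_spectrum(); bn <- energy_bins(); dm <- dose_model()
  # a sinogram of 10^4 identical rays stands in for repeated draws of one ray
  one <- expected_bin_counts(c(water = 20), sp, bn, 1)
  expected <- array(rep(one, each = 1e4), dim = c(100, 100, 4))
  s1 <- simulate_bin_sinogram(expected, 2, dm, seed = 5)
  s2 <- simulate_bin_sinogram(expected, 2, dm, seed = 5)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_bin_sinogram(expected, 2, dm, seed = 6)
  expect_false(identical(s1$counts, s3$counts))
  lam <- one * dm$photons_per_ray_per_mgy * 2
  for (b in 1:4) {
    m <- mean(s1$counts[, , b])
    se <- sqrt(lam[b] / 1e4)
    expect_lt(abs(m - lam[b]), 3 * se)
    # integer counts
    expect_true(all(s1$counts[, , b] == round(s1$counts[, , b])))
  }
  # relative spread at 8 mGy is about half that at 2 mGy (Poisson scaling)
  s8 <- simulate_bin_sinogram(expected, 8, dm, seed = 5)
  rel2 <- sd(s1$counts[, , 1]) / mean(s1$counts[, , 1])
  rel8 <- sd(s8$counts[, , 1]) / mean(s8$counts[, , 1])
  expect_equal(rel8 / rel2, 0.5, tolerance = 0.1)
  expect_error(simulate_bin_sinogram(expected, 3, dm, seed = 1), "dose")
})

test_that("log normalization implements the clamped pre-log transform", {
  sp <- tube_spectrum(); bn <- energy_bins()
  blank <- blank_frac <- kedgesim:::blank_expected_fractions(sp, bn,
                                                             c(2, 2, 4))
  n0 <- 1000
  sino <- structure(list(counts = blank * n0, n0_per_ray = n0,
                         dose_mgy = 8, seed = NA), class = "bin_sinogram")
  expect_equal(log_normalize(sino, blank), array(0, c(2, 2, 4)))
  sino$counts <- blank * n0 / exp(1)
  expect_equal(log_normalize(sino, blank), array(1, c(2, 2, 4)),
               tolerance = 1e-12)
  # fully absorbed rays stay finite via the 0.5-count floor
  sino$counts <- array(0, c(2, 2, 4))
  p <- log_normalize(sino, blank)
  expect_true(all(is.finite(p)))
  expect_equal(p[1, 1, 1], -log(0.5 / (blank[1, 1, 1] * n0)))
  sino$counts <- array(0, c(2, 2, 3))
  expect_error(log_normalize(sino, blank), "shape")
})

test_that("filtered backprojection is linear and recovers a uniform disk", {
  geo <- small_geometry(n_angles = 240)
  spec <- build_calibration_phantom("water", 10)
  g <- rasterize_phantom(spec, 256, 0.59)
  li <- forward_project(g, geo)
  mu <- 0.22  # 1/cm, a water-like attenuation
  p <- array(li$water * mu, dim = c(dim(li$water), 1))
  st <- reconstruct_fbp(p, geo)
  # zero sinogram -> zero image; scaling by k scales the image by k
  st0 <- reconstruct_fbp(p * 0, geo)
  expect_equal(st0$images, st$images * 0)
  st2 <- reconstruct_fbp(p * 2, geo)
  expect_equal(st2$images, st$images * 2, tolerance = 1e-12)
  # interior accuracy within 2%
  n <- 256; cc <- (1:n - (n + 1) / 2) * 0.59
  central <- outer(cc^2, cc^2, "+") < 25^2  # central 50% of the disk
  expect_equal(mean(st$images[, , 1][central]), mu, tolerance = 0.02)
})

test_that("bin-image background noise scales as dose^(-1/2)", {
  geo <- small_geometry(n_angles = 240)
  expected <- pure_expected()
  doses <- c(1, 2, 4, 8)
  stds <- vapply(doses, function(d) {
    mean(vapply(1:2, function(k) {
      st <- acquire_bin_images(NULL, geo, dose_mgy = d, seed = 900 + 10 * d + k,
                               expected = expected)
      # background patch in the water holder, bin 3
      sd(st$images[118:138, 118:138, 3])
    }, 0))
  }, 0)
  fit <- stats::lm(log(stds) ~ log(doses))
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.05)
})

test_that("a large water phantom shows beam-hardening cupping before correction", {
  spec <- build_calibration_phantom("water", 40)
  pixel <- 1.3 * 400 / 256
  g <- rasterize_phantom(spec, 256, pixel)
  geo <- scan_geometry(256, pixel, 240)
  st <- acquire_bin_images(g, geo, dose_mgy = 8, poisson = FALSE)
  n <- 256; cc <- (1:n - (n + 1) / 2) * pixel
  r2 <- outer(cc^2, cc^2, "+")
  center <- mean(st$images[, , 1][r2 < 30^2])
  edge <- mean(st$images[, , 1][r2 > 150^2 & r2 < 180^2])
  expect_lt(center, edge)  # cupping: center reads low in the softest bin
})
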