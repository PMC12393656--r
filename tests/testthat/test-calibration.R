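test_that("calibration protocol emits one record per material x diameter x dose cell", {
  cfg <- calibration_config(diameters_cm = c(10, 20), doses_mgy = c(2, 8),
                            n_angles = 120)
  cal <- run_calibration_protocol(cfg, seed = 3, poisson = FALSE)
  expect_equal(nrow(cal$records), 3 * 2 * 2)
  expect_equal(nrow(dplyr::distinct(cal$records, material, diameter_cm,
                                    dose_mgy)),
               nrow(cal$records))
  # water cells carry no contrast
  expect_true(all(cal$records$concentration[cal$records$material == "water"]
                  == 0))
  # a noiseless protocol leaves only deterministic texture in the ROI
  expect_true(all(cal$records$std_bin2 < 0.01 * cal$records$mean_bin2))
  # water profiles exist for every water diameter and bin
  expect_equal(nrow(dplyr::distinct(cal$water_profiles, diameter_cm, bin)),
               2 * 4)
})

test_that("model fitting recovers a known linear signature model exactly", {
  # noiseless records generated from a known signature matrix whose water
  # baseline is the package's reference vector (correction = identity)
  ref <- kedgesim:::reference_water_vector(tube_spectrum(), energy_bins())
  S <- cbind(water = ref,
             iodine = c(0.020, 0.007, 0.0035, 0.0018),
             gadolinium = c(0.005, 0.0055, 0.0027, 0.0013))
  cells <- tidyr::expand_grid(material = c("water", "iodine", "gadolinium"),
                              diameter_cm = c(10, 20), dose_mgy = c(2, 8))
  conc <- c(water = 0, iodine = 13.5, gadolinium = 10)
  records <- dplyr::mutate(cells, concentration = conc[material],
                           n_pixels = 100)
  for (b in 1:4) {
    records[[paste0("mean_bin", b)]] <- S[b, "water"] +
      ifelse(records$material == "water", 0,
             S[b, cbind(records$material)] * records$concentration)
    records[[paste0("std_bin", b)]] <- 0
  }
  profiles <- tidyr::expand_grid(diameter_cm = c(10, 20),
                                 dose_mgy = c(2, 8), bin = 1:4,
                                 ring = 1:10) |>
    dplyr::mutate(raw = ref[bin])
  caldata <- structure(list(records = records,
                            water_profiles = profiles,
                            config = calibration_config()),
                       class = "calibration_data")
  model <- fit_calibration_model(caldata)
  for (d in c(10, 20))
    expect_equal(unname(signature_matrix(model, d)), unname(S),
                 tolerance = 1e-6)
  # interpolation between calibrated diameters stays on the constant model
  expect_equal(unname(signature_matrix(model, 15)), unname(S),
               tolerance = 1e-6)
})

test_that("fitted iodine and gadolinium signatures are well separated (K-edge)", {
  model <- small_model()
  S <- signature_matrix(model, 10)
  expect_equal(qr(S)$rank, 3)
  ang <- acos(sum(S[, 2] * S[, 3]) /
                sqrt(sum(S[, 2]^2) * sum(S[, 3]^2))) * 180 / pi
  expect_gt(ang, 5)
  g <- glance(model)
  expect_equal(g$rank, 3)
  expect_gt(g$iodine_gadolinium_angle_deg, 5)
})

test_that("water pre-correction flattens water to the diameter-independent reference", {
  model <- small_model()
  ref <- model$reference_water
  for (d in c(10, 20)) {
    pixel <- 1.3 * d * 10 / 256
    g <- rasterize_phantom(build_calibration_phantom("water", d), 256,
                           pixel)
    geo <- scan_geometry(256, pixel, 240)
    st <- acquire_bin_images(g, geo, dose_mgy = 8, poisson = FALSE)
    stc <- apply_water_precorrection(st, model, d)
    expect_equal(dim(stc$images), dim(st$images))
    n <- 256; cc <- (1:n - (n + 1) / 2) * pixel
    interior <- outer(cc^2, cc^2, "+") < (0.45 * d * 10)^2
    for (b in 1:4)
      expect_equal(mean(stc$images[, , b][interior]), ref[b],
                   tolerance = 0.01)
  }
  expect_error(apply_water_precorrection(
    acquire_bin_images(NULL, small_geometry(120), dose_mgy = 8,
                       poisson = FALSE,
                       expected = pure_expected()[, 1:120, , drop = FALSE]),
    model, 45), "range")
})

test_that("degenerate correction fits fall back to a monotone rescaling", {
  # clustered raw values (no beam hardening spread): near-identity scaling
  fit <- kedgesim:::fit_correction_poly(rep(0.2, 10) + rnorm(10, 0, 1e-6),
                                        0.2)
  expect_equal(fit$coef[1], 1, tolerance = 1e-3)
  expect_equal(fit$coef[2], 0)
  # the mapping is monotone over and beyond the fitted range, and 0 -> 0
  fit2 <- kedgesim:::fit_correction_poly(seq(0.27, 0.30, length.out = 20),
                                         0.35)
  xs <- seq(0, 1, length.out = 200)
  ys <- kedgesim:::eval_correction_poly(fit2, xs)
  expect_true(all(diff(ys) > 0))
  expect_equal(kedgesim:::eval_correction_poly(fit2, 0), 0)
})
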