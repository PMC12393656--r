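# Shared, lazily built fixtures. Heavy objects (calibration models, study
# runs) are computed once per test session and cached; everything is
# generated in code from fixed seeds.

ks_cache <- new.env(parent = emptyenv())

ks_get <- function(name, builder) {
  if (!exists(name, envir = ks_cache)) assign(name, builder(), envir = ks_cache)
  get(name, envir = ks_cache)
}

# Small noiseless calibration model (2 diameters, 1 dose, 240 angles):
# enough for decomposition/evaluation tests at the 10 cm study diameter.
small_model <- function() {
  ks_get("small_model", function() {
    cal <- run_calibration_protocol(
      calibration_config(diameters_cm = c(10, 20), doses_mgy = 8,
                         n_angles = 240),
      seed = 11, poisson = FALSE)
    fit_calibration_model(cal)
  })
}

small_geometry <- function(n_angles = 240) scan_geometry(256, 0.59, n_angles)

# Expected (unit-fluence) bin sinogram of the pure study phantom at the
# small geometry, reused across noisy-realization tests.
pure_expected <- function() {
  ks_get("pure_expected", function() {
    grid <- rasterize_phantom(build_study_phantom("pure"), 256, 0.59)
    li <- forward_project(grid, small_geometry())
    expected_bin_sinogram(li, tube_spectrum(), energy_bins())
  })
}

# A hand-built strictly linear calibration model (identity water correction,
# known signature matrix): decomposition oracle tests run against it.
synthetic_model <- function(S = NULL) {
  ref <- c(0.35, 0.20, 0.18, 0.17)
  if (is.null(S))
    S <- cbind(water = ref,
               iodine = c(0.020, 0.007, 0.0035, 0.0018),
               gadolinium = c(0.005, 0.0055, 0.0027, 0.0013))
  sig <- dplyr::bind_rows(lapply(c("iodine", "gadolinium"), function(m)
    tibble::tibble(material = m, diameter_cm = 10, bin = 1:4,
                   value = S[, m])))
  identity_poly <- list(coef = c(1, 0), raw_hi = 10)
  structure(list(signatures = sig, reference_water = S[, "water"],
                 corrections = list(`10` = rep(list(identity_poly), 4)),
                 diameters_cm = 10, poly_order = 2,
                 bins = energy_bins(), spectrum = tube_spectrum(),
                 provenance = tibble::tibble()),
            class = "calibration_model")
}

# Wrap plain per-bin images into a bin_image_stack.
synthetic_stack <- function(images, pixel_size_mm = 0.59, ...) {
  structure(list(images = images, pixel_size_mm = pixel_size_mm,
                 n = dim(images)[1], water_corrected = TRUE,
                 body_diameter_cm = 10, ...),
            class = "bin_image_stack")
}

# Wrap matrices into a material_map_set.
synthetic_maps <- function(iodine, gadolinium = iodine * 0,
                           water = iodine * 0 + 1, pixel_size_mm = 0.59,
                           dose_mgy = 8, repeat_index = 1) {
  structure(list(water = water, iodine = iodine, gadolinium = gadolinium,
                 pixel_size_mm = pixel_size_mm, dose_mgy = dose_mgy,
                 repeat_index = repeat_index, body_diameter_cm = 10),
            class = "material_map_set")
}

# Full-protocol noisy calibration model at study defaults (48 cells).
full_model <- function() {
  ks_get("full_model", function() {
    cal <- run_calibration_protocol(calibration_config(), seed = 101,
                                    poisson = TRUE)
    fit_calibration_model(cal)
  })
}

# Dose-ladder study at test scale: both phantom modes, all four doses,
# 3 repeats, 5 pooled realizations per scan (the full design with a reduced
# slice count), sharing the full calibration model.
ladder_study <- function() {
  ks_get("ladder_study", function() {
    run_full_study(study_config(n_realizations = 5, master_seed = 42),
                   model = full_model())
  })
}

# Brute-force grid-search oracle for the per-pixel least-squares problem.
grid_search_decompose <- function(b, S, center, half_width = 0.25,
                                  step = 0.01) {
  grids <- lapply(center, function(c0)
    seq(c0 - half_width, c0 + half_width, by = step))
  best <- NULL; best_val <- Inf
  for (w in grids[[1]]) for (io in grids[[2]]) for (gd in grids[[3]]) {
    r <- b - S %*% c(w, io, gd)
    v <- sum(r^2)
    if (v < best_val) { best_val <- v; best <- c(w, io, gd) }
  }
  best
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# group assignments (no ties), mirroring the exact rank-sum convention.
mw_exact_enumeration <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  x <- c(a, b)
  r <- rank(x)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}
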