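#' Mean and standard deviation over a circular ROI
#' @noRd
roi_stats <- function(img, pixel_size_mm, cx_mm = 0, cy_mm = 0, radius_mm,
                      min_pixels = 1L) {
  n <- nrow(img)
  cc <- (seq_len(n) - (n + 1) / 2) * pixel_size_mm
  inside <- outer((cc - cx_mm)^2, (cc - cy_mm)^2, "+") <= radius_mm^2
  npix <- sum(inside)
  if (npix < min_pixels)
    stop(sprintf("ROI has %d pixels (< %d); use a larger grid", npix,
                 min_pixels))
  v <- img[inside]
  list(mean = mean(v), std = sd(v), n_pixels = npix)
}

#' Radial profile (ring means) of an image
#' @noRd
radial_profile <- function(img, pixel_size_mm, r_max_mm, n_rings = 24L) {
  n <- nrow(img)
  cc <- (seq_len(n) - (n + 1) / 2) * pixel_size_mm
  r <- sqrt(outer(cc^2, cc^2, "+"))
  ring <- findInterval(r, seq(0, r_max_mm, length.out = n_rings + 1),
                       rightmost.closed = TRUE)
  keep <- ring >= 1 & ring <= n_rings
  tibble::tibble(ring = factor(ring[keep], levels = seq_len(n_rings)),
                 v = img[keep]) |>
    dplyr::group_by(.data$ring) |>
    dplyr::summarise(raw = mean(.data$v), .groups = "drop") |>
    dplyr::pull(.data$raw)
}

#' Calibration protocol configuration
#'
#' @param materials Calibration vials: water plus iodine (13.5 mg/mL) and
#'   gadolinium (10.0 mg/mL).
#' @param diameters_cm Phantom diameters scanned (extension rings).
#' @param doses_mgy Dose levels (the protocol's tube-current axis maps onto
#'   dose, since both only scale fluence in the forward model).
#' @param n Reconstruction grid size.
#' @param n_angles Projection angles over 180 degrees.
#' @param fov_factor Field of view as a multiple of the body diameter.
#' @param insert_radius_mm Central vial radius.
#' @param spectrum,bins,dmodel Physics configuration.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(materials = KEDGE_MATERIALS,
                               diameters_cm = c(10, 20, 30, 40),
                               doses_mgy = c(1, 2, 4, 8),
                               n = 256, n_angles = 360, fov_factor = 1.3,
                               insert_radius_mm = 6,
                               spectrum = tube_spectrum(),
                               bins = energy_bins(),
                               dmodel = dose_model()) {
  structure(list(materials = materials, diameters_cm = diameters_cm,
                 doses_mgy = doses_mgy, n = n, n_angles = n_angles,
                 fov_factor = fov_factor, insert_radius_mm = insert_radius_mm,
                 spectrum = spectrum, bins = bins, dmodel = dmodel),
            class = "calibration_config")
}

#' Run the simulated calibration protocol
#'
#' Scans each calibration vial (water, I 13.5 mg/mL, Gd 10.0 mg/mL) at every
#' phantom diameter and dose level through the full acquisition chain, and
#' measures the central-vial ROI (60% of the vial diameter) in every bin
#' image. Water scans additionally contribute radial profiles of the
#' water-only interior, which the model fit uses to flatten beam-hardening
#' cupping.
#'
#' @param config A [calibration_config()].
#' @param seed Master seed; per-cell seeds are derived deterministically.
#' @param poisson Set `FALSE` for a noise-free protocol.
#' @return Object of class `calibration_data`: list with `records` (tibble,
#'   one row per material x diameter x dose, mean/std per bin in wide
#'   columns) , `water_profiles` (tibble of ring means) and the `config`.
#' @export
run_calibration_protocol <- function(config = calibration_config(),
                                     seed = 1L, poisson = TRUE) {
  stopifnot(inherits(config, "calibration_config"))
  tables <- attenuation_tables()
  cells <- tidyr::expand_grid(material = config$materials,
                              diameter_cm = config$diameters_cm)
  seeds <- derive_seeds(seed, nrow(cells) * length(config$doses_mgy))
  si <- 0L
  records <- list()
  profiles <- list()
  for (i in seq_len(nrow(cells))) {
    material <- cells$material[i]
    d <- cells$diameter_cm[i]
    pixel <- config$fov_factor * d * 10 / config$n
    spec <- build_calibration_phantom(material, d,
                                      insert_radius_mm = config$insert_radius_mm)
    grid <- rasterize_phantom(spec, n = config$n, pixel_size_mm = pixel)
    geo <- scan_geometry(config$n, pixel, config$n_angles)
    li <- forward_project(grid, geo)
    expected <- expected_bin_sinogram(li, config$spectrum, config$bins,
                                      tables = tables)
    conc <- max(spec$inserts$iodine_mg_ml, spec$inserts$gadolinium_mg_ml)
    for (dose in config$doses_mgy) {
      si <- si + 1L
      stack <- acquire_bin_images(NULL, geo, config$spectrum, config$bins,
                                  config$dmodel, dose_mgy = dose,
                                  seed = seeds[si], poisson = poisson,
                                  expected = expected, tables = tables)
      st <- lapply(seq_len(config$bins$n_bins), function(b)
        roi_stats(stack$images[, , b], pixel,
                  radius_mm = 0.6 * config$insert_radius_mm))
      rec <- tibble::tibble(material = material, concentration = conc,
                            diameter_cm = d, dose_mgy = dose,
                            n_pixels = st[[1]]$n_pixels)
      for (b in seq_along(st)) {
        rec[[paste0("mean_bin", b)]] <- st[[b]]$mean
        rec[[paste0("std_bin", b)]] <- st[[b]]$std
      }
      records[[length(records) + 1L]] <- rec
      if (material == "water") {
        r_max <- 0.95 * d * 10 / 2
        for (b in seq_len(config$bins$n_bins)) {
          profiles[[length(profiles) + 1L]] <- tibble::tibble(
            diameter_cm = d, dose_mgy = dose, bin = b,
            raw = radial_profile(stack$images[, , b], pixel, r_max))
        }
      }
    }
  }
  structure(list(records = dplyr::bind_rows(records),
                 water_profiles = dplyr::bind_rows(profiles),
                 config = config),
            class = "calibration_data")
}

#' @export
print.calibration_data <- function(x, ...) {
  cat(sprintf("<calibration_data: %d records, %d materials x %d diameters x %d doses>\n",
              nrow(x$records), length(unique(x$records$material)),
              length(unique(x$records$diameter_cm)),
              length(unique(x$records$dose_mgy))))
  invisible(x)
}

#' Thin-object reference water attenuation per bin (1/cm)
#' @noRd
reference_water_vector <- function(spectrum, bins,
                                   tables = attenuation_tables()) {
  idx <- bin_index(bins, spectrum$energies)
  mu <- mass_attenuation_at(tables$water, spectrum$energies)
  vapply(seq_len(bins$n_bins), function(b) {
    w <- spectrum$fluence_weights[idx == b]
    sum(w * mu[idx == b]) / sum(w)
  }, 0)
}

# Fit one per-(bin, diameter) water-correction polynomial mapping raw bin
# values to the reference water value. Quadratic through the origin by
# default; falls back to a linear rescaling when the observed raw spread is
# too narrow to constrain curvature (e.g. a monoenergetic beam). Beyond the
# fitted range the mapping continues linearly (C1), keeping it monotone and
# controlled for high-contrast pixels.
fit_correction_poly <- function(raw, target, order = 2) {
  raw <- raw[is.finite(raw) & raw > 0]
  spread <- (max(raw) - min(raw)) / mean(raw)
  if (order < 2 || spread < 0.01) {
    coef <- c(target / mean(raw), 0)
  } else {
    A <- cbind(raw, raw^2)
    fit <- qr.coef(qr(A), rep(target, length(raw)))
    coef <- as.numeric(fit)
    # monotonicity over the fitted range, else linear fallback
    hi <- max(raw) * 1.1
    if (coef[1] <= 0 || coef[1] + 2 * coef[2] * hi <= 0)
      coef <- c(target / mean(raw), 0)
  }
  list(coef = coef, raw_hi = max(raw) * 1.1)
}

eval_correction_poly <- function(poly, x) {
  c1 <- poly$coef[1]; c2 <- poly$coef[2]; h <- poly$raw_hi
  inside <- x <= h
  out <- numeric(length(x))
  out[inside] <- c1 * x[inside] + c2 * x[inside]^2
  slope_h <- c1 + 2 * c2 * h
  out[!inside] <- (c1 * h + c2 * h^2) + slope_h * (x[!inside] - h)
  out
}

#' Fit the calibration model (bin signatures + water correction)
#'
#' From the protocol records, fits (i) a per-bin, per-diameter water
#' correction forcing water to read a diameter-independent reference value
#' (the thin-object effective water attenuation of the spectrum), and (ii)
#' per-unit-concentration bin signatures for iodine and gadolinium:
#' `s_m(d) = (corrected mean of material m - corrected mean of water at the
#' same diameter and dose) / concentration`, averaged over doses and kept
#' per diameter (linear interpolation between diameters). The water column of
#' the signature matrix is the reference water vector itself.
#'
#' @param caldata A [run_calibration_protocol()] result.
#' @param poly_order Water-correction polynomial order (default 2,
#'   quadratic through the origin).
#' @return Object of class `calibration_model`.
#' @export
fit_calibration_model <- function(caldata, poly_order = 2) {
  stopifnot(inherits(caldata, "calibration_data"))
  cfg <- caldata$config
  nb <- cfg$bins$n_bins
  ref <- reference_water_vector(cfg$spectrum, cfg$bins)
  diameters <- sort(unique(caldata$records$diameter_cm))

  corrections <- lapply(diameters, function(d) {
    lapply(seq_len(nb), function(b) {
      pr <- dplyr::filter(caldata$water_profiles,
                          .data$diameter_cm == d, .data$bin == b)
      if (!nrow(pr)) stop("missing water profile for diameter ", d)
      fit_correction_poly(pr$raw, ref[b], order = poly_order)
    })
  })
  names(corrections) <- as.character(diameters)

  correct_cell <- function(row) {
    d <- as.character(row$diameter_cm)
    vapply(seq_len(nb), function(b)
      eval_correction_poly(corrections[[d]][[b]],
                           row[[paste0("mean_bin", b)]]), 0)
  }
  sig <- list()
  for (m in setdiff(unique(caldata$records$material), "water")) {
    for (d in diameters) {
      per_dose <- lapply(sort(unique(caldata$records$dose_mgy)), function(dose) {
        rm_ <- dplyr::filter(caldata$records, .data$material == m,
                             .data$diameter_cm == d, .data$dose_mgy == dose)
        rw <- dplyr::filter(caldata$records, .data$material == "water",
                            .data$diameter_cm == d, .data$dose_mgy == dose)
        if (!nrow(rm_) || !nrow(rw)) stop("incomplete calibration grid")
        (correct_cell(rm_) - correct_cell(rw)) / rm_$concentration
      })
      sig[[length(sig) + 1L]] <- tibble::tibble(
        material = m, diameter_cm = d, bin = seq_len(nb),
        value = Reduce(`+`, per_dose) / length(per_dose))
    }
  }
  signatures <- dplyr::bind_rows(sig)

  model <- structure(
    list(signatures = signatures, reference_water = ref,
         corrections = corrections, diameters_cm = diameters,
         poly_order = poly_order, bins = cfg$bins, spectrum = cfg$spectrum,
         provenance = caldata$records),
    class = "calibration_model")
  S <- signature_matrix(model, diameters[1])
  if (qr(S)$rank < ncol(S))
    stop("signature matrix is rank deficient; decomposition unsolvable")
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model: %d bins, diameters %s cm, poly order %d>\n",
              x$bins$n_bins, paste(x$diameters_cm, collapse = "/"),
              x$poly_order))
  invisible(x)
}

#' Signature matrix at a given phantom diameter
#'
#' Columns are water (the reference vector, per g/mL), iodine and gadolinium
#' (per mg/mL); rows are energy bins. Signatures are interpolated linearly
#' between calibrated diameters.
#'
#' @param model A [fit_calibration_model()] result.
#' @param diameter_cm Body diameter, within the calibrated range.
#' @return A `n_bins x 3` matrix with columns `water`, `iodine`,
#'   `gadolinium`.
#' @export
signature_matrix <- function(model, diameter_cm) {
  stopifnot(inherits(model, "calibration_model"))
  check_diameter(model, diameter_cm)
  nb <- model$bins$n_bins
  cols <- vapply(c("iodine", "gadolinium"), function(m) {
    vapply(seq_len(nb), function(b) {
      sub <- dplyr::filter(model$signatures, .data$material == m,
                           .data$bin == b)
      if (nrow(sub) == 1) return(sub$value)
      approx(sub$diameter_cm, sub$value, xout = diameter_cm)$y
    }, 0)
  }, numeric(nb))
  cbind(water = model$reference_water, cols)
}

check_diameter <- function(model, diameter_cm) {
  rng <- range(model$diameters_cm)
  if (diameter_cm < rng[1] || diameter_cm > rng[2])
    stop(sprintf("diameter %g cm outside calibrated range [%g, %g] cm",
                 diameter_cm, rng[1], rng[2]))
}

#' Apply the beam-hardening water pre-correction to bin images
#'
#' Maps each bin image through the fitted per-bin correction at the stack's
#' body diameter (corrections are interpolated between calibrated
#' diameters by blending the corrected values of the two nearest diameters).
#' Water-only regions then read the diameter-independent reference value;
#' zero-attenuation pixels stay at zero; image shape is preserved.
#'
#' @param stack A `bin_image_stack`.
#' @param model A [fit_calibration_model()] result.
#' @param body_diameter_cm Diameter of the scanned body, cm (10--40).
#' @return A corrected `bin_image_stack` (flag `water_corrected = TRUE`).
#' @export
apply_water_precorrection <- function(stack, model, body_diameter_cm) {
  stopifnot(inherits(stack, "bin_image_stack"),
            inherits(model, "calibration_model"))
  check_diameter(model, body_diameter_cm)
  ds <- model$diameters_cm
  i_hi <- min(which(ds >= body_diameter_cm - 1e-9), length(ds))
  i_lo <- if (ds[i_hi] == body_diameter_cm || i_hi == 1) i_hi else i_hi - 1
  wt <- if (i_lo == i_hi) 1 else
    (ds[i_hi] - body_diameter_cm) / (ds[i_hi] - ds[i_lo])
  out <- stack
  for (b in seq_len(dim(stack$images)[3])) {
    img <- stack$images[, , b]
    v_lo <- eval_correction_poly(model$corrections[[as.character(ds[i_lo])]][[b]], img)
    v_hi <- eval_correction_poly(model$corrections[[as.character(ds[i_hi])]][[b]], img)
    out$images[, , b] <- array(wt * v_lo + (1 - wt) * v_hi, dim = dim(img))
  }
  out$water_corrected <- TRUE
  out$body_diameter_cm <- body_diameter_cm
  out
}
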