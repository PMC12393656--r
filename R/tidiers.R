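#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a calibration model into its per-unit bin signatures
#'
#' @param x A [fit_calibration_model()] result.
#' @param ... Unused.
#' @return Tibble: `material`, `diameter_cm`, `bin`, `value` (1/cm per
#'   mg/mL), including the water reference column (per g/mL).
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(material = "water", diameter_cm = NA_real_,
                   bin = seq_along(x$reference_water),
                   value = x$reference_water),
    x$signatures)
}

#' One-row summary of a calibration model
#'
#' Reports the signature-matrix condition at the smallest calibrated
#' diameter and the angle between the iodine and gadolinium signatures (the
#' K-edge separability that makes three-material decomposition solvable).
#'
#' @param x A [fit_calibration_model()] result.
#' @param ... Unused.
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  S <- signature_matrix(x, min(x$diameters_cm))
  ang <- acos(sum(S[, 2] * S[, 3]) /
                sqrt(sum(S[, 2]^2) * sum(S[, 3]^2))) * 180 / pi
  tibble::tibble(n_records = nrow(x$provenance),
                 n_diameters = length(x$diameters_cm),
                 rank = qr(S)$rank,
                 condition_number = kappa(S, exact = TRUE),
                 iodine_gadolinium_angle_deg = ang)
}

#' Tidy a study bundle into its ROI measurement table
#' @param x A [run_full_study()] result.
#' @param ... Unused.
#' @method tidy kedge_study
#' @export
tidy.kedge_study <- function(x, ...) x$measurements

#' One-row summary of a study run
#'
#' Linearity of CNR with concentration per material (highest dose, pure
#' solutions), background noise at the extreme doses, and the familywise
#' test-grid size.
#'
#' @param x A [run_full_study()] result.
#' @param ... Unused.
#' @method glance kedge_study
#' @export
glance.kedge_study <- function(x, ...) {
  cc <- dplyr::filter(x$trends, .data$kind == "cnr_vs_concentration",
                      .data$phantom_mode == "pure")
  bg <- dplyr::filter(x$measurements,
                      .data$insert_id == "water_background",
                      .data$material_map == "iodine")
  tibble::tibble(
    r2_cnr_conc_iodine =
      cc$r_squared[cc$material_map == "iodine"][1] %||% NA_real_,
    r2_cnr_conc_gadolinium =
      cc$r_squared[cc$material_map == "gadolinium"][1] %||% NA_real_,
    noise_iodine_low_dose = mean(bg$std[bg$dose_mgy == min(bg$dose_mgy)]),
    noise_iodine_high_dose = mean(bg$std[bg$dose_mgy == max(bg$dose_mgy)]),
    n_comparisons = x$manifest$n_comparisons,
    bonferroni_cutoff = x$manifest$bonferroni_cutoff)
}
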