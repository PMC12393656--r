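#' Derive reproducible child seeds from a master seed
#'
#' A single master seed deterministically yields one sub-seed per condition,
#' so any condition can be re-simulated in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Per-pixel least-squares multi-material decomposition
#'
#' Solves, for every pixel of a water-corrected bin-image stack, the
#' ordinary (unweighted, unconstrained) least-squares problem
#' `xhat = argmin_x || b - S x ||^2` with the 4 x 3 calibration signature
#' matrix `S` (columns water, iodine, gadolinium). One QR factorization of
#' `S` is reused across all pixels. Estimates may be negative under noise;
#' no clipping is applied.
#'
#' @param stack A water-corrected `bin_image_stack`.
#' @param model A [fit_calibration_model()] result.
#' @param body_diameter_cm Body diameter for signature interpolation;
#'   defaults to the diameter recorded on the stack.
#' @return Object of class `material_map_set`: list with `water` (g/mL
#'   equivalent), `iodine` and `gadolinium` (mg/mL) matrices plus metadata.
#' @export
decompose_pixelwise <- function(stack, model,
                                body_diameter_cm = stack$body_diameter_cm) {
  stopifnot(inherits(stack, "bin_image_stack"),
            inherits(model, "calibration_model"))
  if (is.null(body_diameter_cm))
    stop("body_diameter_cm missing: correct the stack first or pass it")
  if (anyNA(stack$images)) stop("NaN/NA in input bin images")
  S <- signature_matrix(model, body_diameter_cm)
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) stop("signature matrix is rank deficient")
  dims <- dim(stack$images)
  B <- matrix(stack$images, nrow = dims[1] * dims[2], ncol = dims[3])
  X <- t(qr.coef(qrS, t(B)))
  structure(list(
    water = matrix(X[, 1], dims[1], dims[2]),
    iodine = matrix(X[, 2], dims[1], dims[2]),
    gadolinium = matrix(X[, 3], dims[1], dims[2]),
    pixel_size_mm = stack$pixel_size_mm,
    dose_mgy = stack$dose_mgy, seed = stack$seed,
    realization_index = stack$realization_index,
    repeat_index = stack$repeat_index,
    body_diameter_cm = body_diameter_cm),
    class = "material_map_set")
}

#' @export
print.material_map_set <- function(x, ...) {
  cat(sprintf("<material_map_set: %dx%d @ %.3g mm%s>\n",
              nrow(x$iodine), ncol(x$iodine), x$pixel_size_mm,
              if (!is.null(x$dose_mgy)) paste0(", ", x$dose_mgy, " mGy") else ""))
  invisible(x)
}
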