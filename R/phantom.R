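#' Construct a phantom specification
#'
#' A phantom is a circular water-equivalent body (density 1 g/mL) with
#' disk-shaped inserts holding contrast-agent solutions. Inserts must lie
#' fully inside the body and be pairwise disjoint.
#'
#' @param body_diameter_cm Body diameter in cm.
#' @param inserts A tibble/data.frame with columns `x_mm`, `y_mm` (center),
#'   `radius_mm`, `iodine_mg_ml`, `gadolinium_mg_ml`, and optionally
#'   `insert_id`.
#' @param label Free-text label.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_diameter_cm, inserts, label = "") {
  inserts <- tibble::as_tibble(inserts)
  if (!nrow(inserts)) stop("at least one insert required")
  if (!"insert_id" %in% names(inserts))
    inserts$insert_id <- paste0("ins", seq_len(nrow(inserts)))
  req <- c("x_mm", "y_mm", "radius_mm", "iodine_mg_ml", "gadolinium_mg_ml")
  stopifnot(all(req %in% names(inserts)))
  r_body <- body_diameter_cm * 10 / 2
  d_center <- sqrt(inserts$x_mm^2 + inserts$y_mm^2)
  if (any(d_center + inserts$radius_mm > r_body))
    stop("inserts must lie fully inside the body")
  if (any(inserts$iodine_mg_ml < 0) || any(inserts$gadolinium_mg_ml < 0))
    stop("concentrations must be non-negative")
  n <- nrow(inserts)
  if (n > 1) {
    pair <- utils::combn(n, 2)
    dd <- sqrt((inserts$x_mm[pair[1, ]] - inserts$x_mm[pair[2, ]])^2 +
               (inserts$y_mm[pair[1, ]] - inserts$y_mm[pair[2, ]])^2)
    if (any(dd < inserts$radius_mm[pair[1, ]] + inserts$radius_mm[pair[2, ]]))
      stop("insert regions must be pairwise disjoint")
  }
  structure(list(body_diameter_cm = body_diameter_cm, inserts = inserts,
                 label = label),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec '%s': %g cm body, %d insert(s)>\n",
              x$label, x$body_diameter_cm, nrow(x$inserts)))
  print(x$inserts)
  invisible(x)
}

#' Study phantom with pure or mixed contrast solutions
#'
#' Pure mode: 8 syringe-like inserts, iodine and gadolinium each at
#' 1, 2.5, 5 and 10 mg/mL. Mixed mode: 6 inserts at I:Gd ratios
#' 1:2.5, 2.5:1, 2.5:2.5, 2.5:5, 5:2.5 and 5:5 mg/mL. All inserts sit on a
#' ring inside a 10 cm water-equivalent holder.
#'
#' @param mode `"pure"` or `"mixed"`.
#' @param insert_radius_mm Insert radius (default 6 mm).
#' @param ring_radius_mm Radius of the ring of insert centers (default 30 mm).
#' @return A [phantom_spec()].
#' @export
build_study_phantom <- function(mode = c("pure", "mixed"),
                                insert_radius_mm = 6, ring_radius_mm = 30) {
  mode <- match.arg(mode)
  conc <- if (mode == "pure") {
    tibble::tibble(
      iodine_mg_ml     = c(1, 2.5, 5, 10, 0, 0, 0, 0),
      gadolinium_mg_ml = c(0, 0, 0, 0, 1, 2.5, 5, 10)
    )
  } else {
    tibble::tibble(
      iodine_mg_ml     = c(1,   2.5, 2.5, 2.5, 5,   5),
      gadolinium_mg_ml = c(2.5, 1,   2.5, 5,   2.5, 5)
    )
  }
  n <- nrow(conc)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  inserts <- dplyr::mutate(
    conc,
    x_mm = ring_radius_mm * cos(theta),
    y_mm = ring_radius_mm * sin(theta),
    radius_mm = insert_radius_mm,
    insert_id = sprintf("%s_I%g_Gd%g", mode, .data$iodine_mg_ml,
                        .data$gadolinium_mg_ml)
  )
  phantom_spec(10, inserts, label = paste0("study_", mode))
}

#' Calibration phantom: one centered vial in a water body
#'
#' The calibration protocol scans water, iodine at 13.5 mg/mL and gadolinium
#' at 10.0 mg/mL in a 10 cm water-equivalent phantom, with extension rings
#' increasing the diameter stepwise to 40 cm.
#'
#' @param material `"water"`, `"iodine"` or `"gadolinium"`.
#' @param diameter_cm One of 10, 20, 30, 40.
#' @param insert_radius_mm Central vial radius (default 15 mm).
#' @return A [phantom_spec()].
#' @export
build_calibration_phantom <- function(material, diameter_cm,
                                      insert_radius_mm = 15) {
  material <- match.arg(material, KEDGE_MATERIALS)
  if (!diameter_cm %in% c(10, 20, 30, 40))
    stop("diameter_cm must be one of 10, 20, 30, 40")
  conc <- c(water = NA, iodine = 13.5, gadolinium = 10.0)
  inserts <- tibble::tibble(
    x_mm = 0, y_mm = 0, radius_mm = insert_radius_mm,
    iodine_mg_ml = if (material == "iodine") conc[["iodine"]] else 0,
    gadolinium_mg_ml = if (material == "gadolinium") conc[["gadolinium"]] else 0,
    insert_id = paste0("cal_", material)
  )
  phantom_spec(diameter_cm, inserts,
               label = sprintf("cal_%s_d%g", material, diameter_cm))
}

#' Rasterize a phantom onto per-material density grids
#'
#' Produces water (g/mL), iodine and gadolinium (mg/mL) rasters on an
#' `n x n` grid with anti-aliased boundaries via `supersample x supersample`
#' subsampling of each pixel. The interior of an insert carries exactly its
#' specified concentrations; pixels outside the body are zero in every
#' raster. The generating spec is retained for ground-truth evaluation.
#'
#' @param spec A [phantom_spec()].
#' @param n Grid size in pixels (>= 64).
#' @param pixel_size_mm Pixel spacing in mm; the grid must cover the body.
#' @param supersample Subsamples per pixel edge (default 4).
#' @return Object of class `material_grid`: list with `water`, `iodine`,
#'   `gadolinium` matrices, `pixel_size_mm`, `n` and `spec`.
#' @export
rasterize_phantom <- function(spec, n = 256, pixel_size_mm = 0.59,
                              supersample = 4) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 64, supersample >= 1)
  fov <- n * pixel_size_mm
  if (fov < spec$body_diameter_cm * 10)
    stop("grid does not cover the phantom body; increase n or pixel size")
  centers <- (seq_len(n) - (n + 1) / 2) * pixel_size_mm
  offs <- (seq_len(supersample) - (supersample + 1) / 2) *
    (pixel_size_mm / supersample)
  water <- iodine <- gadolinium <- matrix(0, n, n)
  r_body <- spec$body_diameter_cm * 10 / 2
  for (ox in offs) for (oy in offs) {
    X <- matrix(centers + ox, n, n)
    Y <- matrix(centers + oy, n, n, byrow = TRUE)
    inside_body <- (X^2 + Y^2) <= r_body^2
    water <- water + inside_body
    for (k in seq_len(nrow(spec$inserts))) {
      ins <- spec$inserts[k, ]
      inside <- ((X - ins$x_mm)^2 + (Y - ins$y_mm)^2) <= ins$radius_mm^2
      iodine <- iodine + inside * ins$iodine_mg_ml
      gadolinium <- gadolinium + inside * ins$gadolinium_mg_ml
    }
  }
  s2 <- supersample^2
  structure(list(water = water / s2, iodine = iodine / s2,
                 gadolinium = gadolinium / s2,
                 pixel_size_mm = pixel_size_mm, n = n, spec = spec),
            class = "material_grid")
}

#' @export
print.material_grid <- function(x, ...) {
  cat(sprintf("<material_grid: %dx%d @ %.3g mm (%s)>\n", x$n, x$n,
              x$pixel_size_mm, x$spec$label))
  invisible(x)
}
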