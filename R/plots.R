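#' CNR versus concentration, faceted by material map
#'
#' Points are per-repeat CNR values; lines are the ordinary least-squares
#' fits whose slopes and R-squared the study reports.
#'
#' @param bundle A [run_full_study()] result.
#' @param dose_mgy Dose level to plot (default: highest simulated).
#' @return A ggplot object.
#' @export
plot_cnr_concentration <- function(bundle, dose_mgy = NULL) {
  stopifnot(inherits(bundle, "kedge_study"))
  dose_mgy <- dose_mgy %||% max(bundle$cnr$dose_mgy)
  d <- dplyr::filter(bundle$cnr, .data$true_concentration > 0,
                     .data$dose_mgy == !!dose_mgy)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true_concentration,
                                  y = .data$cnr,
                                  colour = .data$phantom_mode)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$material_map)) +
    ggplot2::labs(x = "concentration [mg/mL]", y = "CNR",
                  colour = "solution",
                  title = sprintf("CNR vs concentration at %g mGy", dose_mgy)) +
    ggplot2::theme_minimal()
}

#' CNR versus radiation dose at a fixed concentration
#'
#' @param bundle A [run_full_study()] result.
#' @param concentration Concentration to follow across doses (default 5).
#' @return A ggplot object.
#' @export
plot_cnr_dose <- function(bundle, concentration = 5) {
  stopifnot(inherits(bundle, "kedge_study"))
  d <- dplyr::filter(bundle$cnr,
                     .data$true_concentration == !!concentration)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_mgy, y = .data$cnr,
                                  colour = .data$phantom_mode)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$material_map)) +
    ggplot2::labs(x = "CTDIvol [mGy]", y = "CNR", colour = "solution",
                  title = sprintf("CNR vs dose at %g mg/mL", concentration)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of measured versus true concentration
#'
#' Differences (measured - expected) against expected concentration, with
#' the mean difference (solid) and 1.96-sd limits of agreement (dashed) per
#' material map.
#'
#' @param bundle A [run_full_study()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(bundle) {
  stopifnot(inherits(bundle, "kedge_study"))
  d <- dplyr::filter(bundle$measurements,
                     .data$insert_id != "water_background",
                     .data$true_concentration > 0) |>
    dplyr::mutate(difference = .data$mean - .data$true_concentration)
  lims <- d |>
    dplyr::group_by(.data$material_map) |>
    dplyr::summarise(md = mean(.data$difference),
                     lo = mean(.data$difference) - 1.96 * sd(.data$difference),
                     hi = mean(.data$difference) + 1.96 * sd(.data$difference),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true_concentration,
                                  y = .data$difference,
                                  colour = factor(.data$dose_mgy))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = .data$md)) +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = .data$lo),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = .data$hi),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$material_map)) +
    ggplot2::labs(x = "expected concentration [mg/mL]",
                  y = "measured - expected [mg/mL]", colour = "mGy") +
    ggplot2::theme_minimal()
}

#' Study overview plot
#'
#' @param object A [run_full_study()] result.
#' @param ... Passed to [plot_cnr_concentration()].
#' @return A ggplot object.
#' @method autoplot kedge_study
#' @export
autoplot.kedge_study <- function(object, ...) {
  plot_cnr_concentration(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Two-color iodine/gadolinium overlay of a condition's mean maps
#'
#' Renders iodine in red and gadolinium in green with a linear
#' window/level of 2.5/5 mg/mL and writes an RGB TIFF.
#'
#' @param bundle A [run_full_study()] result.
#' @param condition Name of a `mean_maps` entry, e.g. `"mixed_8_1"`
#'   (mode_dose_repeat); defaults to the first.
#' @param path Output TIFF path.
#' @param window,level Display window and level in mg/mL.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(bundle, condition = NULL, path, window = 5,
                           level = 2.5) {
  stopifnot(inherits(bundle, "kedge_study"))
  condition <- condition %||% names(bundle$mean_maps)[1]
  mm <- bundle$mean_maps[[condition]]
  if (is.null(mm)) stop("unknown condition '", condition, "'; available: ",
                        paste(names(bundle$mean_maps), collapse = ", "))
  scale01 <- function(img) pmin(pmax((img - (level - window / 2)) / window,
                                     0), 1)
  rgb <- array(0, dim = c(dim(mm$iodine), 3))
  rgb[, , 1] <- scale01(mm$iodine)
  rgb[, , 2] <- scale01(mm$gadolinium)
  tiff::writeTIFF(rgb, path, bits.per.sample = 8L)
  invisible(path)
}
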