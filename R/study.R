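#' Full-study configuration
#'
#' Defaults reproduce the study's acquisition table and experimental setup:
#' four thresholds at 20/55/72/90 keV, 140 kVp, doses 1/2/4/8 mGy with 3
#' repeats, pure solutions at 1/2.5/5/10 mg/mL and the six mixed I:Gd
#' ratios, 256 x 256 images at 0.59 mm pixel spacing, calibration over
#' 10--40 cm diameters. Any field can be overridden.
#'
#' @param thresholds_kev,tube_kvp Energy thresholds and tube voltage.
#' @param doses_mgy,repeats,n_realizations Dose levels, repeat scans per
#'   condition, and independent noise realizations pooled per scan
#'   (emulating 15 central slices).
#' @param modes Phantom modes to run (`"pure"`, `"mixed"`).
#' @param n,pixel_size_mm,n_angles Reconstruction grid and projection count.
#' @param insert_radius_mm,ring_radius_mm Study phantom geometry.
#' @param calibration_diameters_cm,calibration_doses_mgy Calibration grid.
#' @param photons_per_ray_per_mgy Dose-to-fluence constant.
#' @param filtration_g_cm2 Inherent tube filtration (water-equivalent).
#' @param master_seed Master seed of the deterministic seed tree.
#' @param poisson Simulate Poisson count noise (default `TRUE`).
#' @param alpha_family Family-wise alpha for the statistics grid.
#' @param baseline_dose_mgy Baseline dose for the bias table.
#' @return A list of class `study_config`.
#' @export
study_config <- function(thresholds_kev = c(20, 55, 72, 90), tube_kvp = 140,
                         doses_mgy = c(1, 2, 4, 8), repeats = 3,
                         n_realizations = 15, modes = c("pure", "mixed"),
                         n = 256, pixel_size_mm = 0.59, n_angles = 360,
                         insert_radius_mm = 6, ring_radius_mm = 30,
                         calibration_diameters_cm = c(10, 20, 30, 40),
                         calibration_doses_mgy = c(1, 2, 4, 8),
                         photons_per_ray_per_mgy = 1.2e4,
                         filtration_g_cm2 = 2.5, master_seed = 1,
                         poisson = TRUE, alpha_family = 0.05,
                         baseline_dose_mgy = 8) {
  cfg <- as.list(environment())
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm,
                                   paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Deterministic seed tree of a study configuration
#'
#' @param config A [study_config()].
#' @return Tibble with one row per (mode, dose, repeat, realization) and its
#'   seed; the calibration seed is in attribute `calibration_seed`.
#' @export
study_seeds <- function(config) {
  grid <- tidyr::expand_grid(phantom_mode = config$modes,
                             dose_mgy = config$doses_mgy,
                             repeat_index = seq_len(config$repeats),
                             realization_index = seq_len(config$n_realizations))
  seeds <- derive_seeds(config$master_seed, nrow(grid) + 1L)
  grid$seed <- seeds[-1]
  attr(grid, "calibration_seed") <- seeds[1]
  grid
}

study_physics <- function(config) {
  list(spectrum = tube_spectrum(tube_kvp = config$tube_kvp,
                                filtration_g_cm2 = config$filtration_g_cm2,
                                e_min = config$thresholds_kev[1]),
       bins = energy_bins(config$thresholds_kev, config$tube_kvp),
       dmodel = dose_model(config$photons_per_ray_per_mgy,
                           sort(union(config$doses_mgy,
                                      config$calibration_doses_mgy))))
}

#' Run the full simulated K-edge imaging study
#'
#' Wires phantom, acquisition, calibration, decomposition and evaluation
#' into the study's full factorial design: one calibration pass, then pure
#' and mixed phantom scans at every dose with repeated acquisitions,
#' material decomposition, ROI measurement, the dose-baseline bias table,
#' CNR and trend fits, Bland-Altman analysis, and the nonparametric test
#' grid with a familywise Bonferroni correction sized by the grid itself.
#' Fully deterministic for a fixed `master_seed`.
#'
#' @param config A [study_config()].
#' @param model Optional pre-fitted [fit_calibration_model()] (skips the
#'   calibration pass).
#' @param progress Print one line per stage/condition (default `FALSE`).
#' @return Object of class `kedge_study`: list with `calibration_records`,
#'   `model`, `measurements`, `bias`, `cnr`, `trends`, `bland_altman`,
#'   `stats`, `mean_maps`, `manifest`.
#' @export
run_full_study <- function(config = study_config(), model = NULL,
                           progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  phys <- study_physics(config)
  tables <- attenuation_tables()
  seeds <- study_seeds(config)
  say <- function(...) if (progress) message(sprintf(...))

  cal_records <- NULL
  if (is.null(model)) {
    say("calibration: %d diameters x %d doses",
        length(config$calibration_diameters_cm),
        length(config$calibration_doses_mgy))
    cal <- run_calibration_protocol(
      calibration_config(diameters_cm = config$calibration_diameters_cm,
                         doses_mgy = config$calibration_doses_mgy,
                         n = config$n, n_angles = config$n_angles,
                         insert_radius_mm = config$insert_radius_mm,
                         spectrum = phys$spectrum, bins = phys$bins,
                         dmodel = phys$dmodel),
      seed = attr(seeds, "calibration_seed"), poisson = config$poisson)
    model <- fit_calibration_model(cal)
    cal_records <- cal$records
  }

  geo <- scan_geometry(config$n, config$pixel_size_mm, config$n_angles)
  measurements <- list()
  mean_maps <- list()
  for (mode in config$modes) {
    spec <- build_study_phantom(mode, config$insert_radius_mm,
                                config$ring_radius_mm)
    grid <- rasterize_phantom(spec, config$n, config$pixel_size_mm)
    li <- forward_project(grid, geo)
    expected <- expected_bin_sinogram(li, phys$spectrum, phys$bins,
                                      tables = tables)
    for (dose in config$doses_mgy) for (rep_i in seq_len(config$repeats)) {
      say("scan: %s %g mGy repeat %d", mode, dose, rep_i)
      cond <- dplyr::filter(seeds, .data$phantom_mode == mode,
                            .data$dose_mgy == dose,
                            .data$repeat_index == rep_i)
      maps <- lapply(seq_len(nrow(cond)), function(j) {
        st <- acquire_bin_images(NULL, geo, phys$spectrum, phys$bins,
                                 phys$dmodel, dose_mgy = dose,
                                 seed = cond$seed[j],
                                 poisson = config$poisson,
                                 expected = expected,
                                 meta = list(repeat_index = rep_i,
                                             realization_index = j),
                                 tables = tables)
        st <- apply_water_precorrection(st, model,
                                        spec$body_diameter_cm)
        decompose_pixelwise(st, model)
      })
      mm <- measure_rois(maps, spec, dose_mgy = dose, repeat_index = rep_i)
      mm$phantom_mode <- mode
      measurements[[length(measurements) + 1L]] <- mm
      mean_maps[[paste(mode, dose, rep_i, sep = "_")]] <- list(
        phantom_mode = mode, dose_mgy = dose, repeat_index = rep_i,
        iodine = Reduce(`+`, lapply(maps, `[[`, "iodine")) / length(maps),
        gadolinium = Reduce(`+`, lapply(maps, `[[`, "gadolinium")) / length(maps),
        water = Reduce(`+`, lapply(maps, `[[`, "water")) / length(maps),
        pixel_size_mm = config$pixel_size_mm)
    }
  }
  measurements <- dplyr::bind_rows(measurements)

  cnr <- cnr_table(measurements)
  bias <- if (length(config$doses_mgy) > 1)
    relative_bias_vs_baseline(measurements, config$baseline_dose_mgy)
  else NULL
  trends <- study_trends(cnr, config)
  ba <- study_bland_altman(measurements)
  stats_grid <- study_stats_grid(measurements, config)

  manifest <- list(
    package_version = as.character(utils::packageVersion("kedgesim")),
    config = unclass(config),
    calibration_seed = attr(seeds, "calibration_seed"),
    scan_seeds = as.data.frame(seeds),
    n_comparisons = attr(stats_grid, "n_comparisons"),
    bonferroni_cutoff = attr(stats_grid, "cutoff"))

  structure(list(calibration_records = cal_records, model = model,
                 measurements = measurements, bias = bias, cnr = cnr,
                 trends = trends, bland_altman = ba, stats = stats_grid,
                 mean_maps = mean_maps, manifest = manifest),
            class = "kedge_study")
}

#' @export
print.kedge_study <- function(x, ...) {
  cat(sprintf("<kedge_study: %d ROI rows, %d CNR rows, %d stat tests>\n",
              nrow(x$measurements), nrow(x$cnr), nrow(x$stats)))
  invisible(x)
}

# CNR-vs-concentration (at the highest dose) and CNR-vs-dose (at 5 mg/mL)
# linear trends per material map and solution type.
study_trends <- function(cnr, config) {
  own <- dplyr::filter(cnr, .data$true_concentration > 0)
  out <- list()
  dmax <- max(config$doses_mgy)
  for (m in unique(own$material_map)) for (md in unique(own$phantom_mode)) {
    sub <- dplyr::filter(own, .data$material_map == m,
                         .data$phantom_mode == md, .data$dose_mgy == dmax)
    if (length(unique(sub$true_concentration)) >= 3) {
      tr <- linear_trend(sub$true_concentration, sub$cnr)
      tr$kind <- "cnr_vs_concentration"; tr$material_map <- m
      tr$phantom_mode <- md; tr$dose_mgy <- dmax
      out[[length(out) + 1L]] <- tr
    }
    sub2 <- dplyr::filter(own, .data$material_map == m,
                          .data$phantom_mode == md,
                          .data$true_concentration == 5)
    if (length(unique(sub2$dose_mgy)) >= 3) {
      tr <- linear_trend(sub2$dose_mgy, sub2$cnr)
      tr$kind <- "cnr_vs_dose"; tr$material_map <- m
      tr$phantom_mode <- md; tr$concentration <- 5
      out[[length(out) + 1L]] <- tr
    }
  }
  dplyr::bind_rows(out)
}

# Bland-Altman per material map and dose, over the map material's inserts.
study_bland_altman <- function(measurements) {
  own <- dplyr::filter(measurements,
                       .data$insert_id != "water_background",
                       .data$true_concentration > 0)
  dplyr::group_by(own, .data$material_map, .data$dose_mgy) |>
    dplyr::group_modify(function(d, key)
      bland_altman(d$mean, d$true_concentration)) |>
    dplyr::ungroup() |>
    dplyr::select(!"group")
}

# The nonparametric test grid. Following the study's analysis plan, noise
# and dose-baseline bias are categorized by material map first, then tested
# against dose and concentration (Kruskal-Wallis + Dunn) and against
# solution type (Mann-Whitney); the material factor itself gets a
# Mann-Whitney test. The familywise cutoff is alpha / (number of p-values
# produced by this very grid).
study_stats_grid <- function(measurements, config) {
  ins <- dplyr::filter(measurements, .data$insert_id != "water_background",
                       .data$true_concentration > 0)
  bg <- dplyr::filter(measurements, .data$insert_id == "water_background")
  rows <- list()
  add <- function(x, material) {
    x$material_map <- material
    rows[[length(rows) + 1L]] <<- x
  }
  split_num <- function(d, col, val) split(d[[val]], d[[col]])

  bias <- NULL
  if (length(config$doses_mgy) > 1) {
    keys <- c("insert_id", "material_map", "solution_type", "repeat_index",
              "phantom_mode")
    base <- dplyr::filter(ins, .data$dose_mgy == config$baseline_dose_mgy) |>
      dplyr::select(dplyr::all_of(keys), baseline_mean = "mean")
    bias <- dplyr::inner_join(ins, base, by = keys) |>
      dplyr::filter(.data$dose_mgy != config$baseline_dose_mgy) |>
      dplyr::mutate(bias = .data$mean - .data$baseline_mean)
  }

  for (m in unique(ins$material_map)) {
    bg_m <- dplyr::filter(bg, .data$material_map == m)
    ins_m <- dplyr::filter(ins, .data$material_map == m)
    if (length(unique(bg_m$dose_mgy)) >= 3)
      add(kruskal_dunn(split_num(bg_m, "dose_mgy", "std"), "noise_vs_dose",
                       config$alpha_family), m)
    if (length(unique(ins_m$true_concentration)) >= 3)
      add(kruskal_dunn(split_num(ins_m, "true_concentration", "std"),
                       "noise_vs_concentration", config$alpha_family), m)
    if (dplyr::n_distinct(ins_m$solution_type) == 2) {
      st <- split(ins_m$std, ins_m$solution_type)
      add(mann_whitney(st[[1]], st[[2]], "noise_vs_solution_type"), m)
    }
    if (!is.null(bias)) {
      bias_m <- dplyr::filter(bias, .data$material_map == m)
      if (length(unique(bias_m$dose_mgy)) >= 3)
        add(kruskal_dunn(split_num(bias_m, "dose_mgy", "bias"),
                         "bias_vs_dose", config$alpha_family), m)
      if (length(unique(bias_m$true_concentration)) >= 3)
        add(kruskal_dunn(split_num(bias_m, "true_concentration", "bias"),
                         "bias_vs_concentration", config$alpha_family), m)
      if (dplyr::n_distinct(bias_m$solution_type) == 2) {
        sb <- split(bias_m$bias, bias_m$solution_type)
        add(mann_whitney(sb[[1]], sb[[2]], "bias_vs_solution_type"), m)
      }
    }
  }
  add(mann_whitney(ins$std[ins$material_map == "iodine"],
                   ins$std[ins$material_map == "gadolinium"],
                   "noise_vs_material"), "both")
  if (!is.null(bias))
    add(mann_whitney(bias$bias[bias$material_map == "iodine"],
                     bias$bias[bias$material_map == "gadolinium"],
                     "bias_vs_material"), "both")

  grid <- dplyr::bind_rows(rows)
  n_comp <- sum(!is.na(grid$p_value))
  cutoff <- config$alpha_family / n_comp
  grid$cutoff <- cutoff
  grid$significant <- grid$p_value < cutoff
  attr(grid, "n_comparisons") <- n_comp
  attr(grid, "cutoff") <- bonferroni_cutoff(config$alpha_family, n_comp)
  grid
}

#' Write study outputs to a directory
#'
#' Tables as UTF-8 CSV (`calibration.csv`, `rois.csv`, `bias.csv`,
#' `cnr.csv`, `stats.csv`, `trends.csv`, `bland_altman.csv`), per-condition
#' mean material maps as single-channel 32-bit float TIFF, and the run
#' manifest (config, seeds, software version) as `manifest.yaml`.
#'
#' @param bundle A [run_full_study()] result.
#' @param directory Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_outputs <- function(bundle, directory) {
  stopifnot(inherits(bundle, "kedge_study"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", directory)
  wcsv <- function(x, name) {
    if (!is.null(x) && nrow(x))
      readr::write_csv(x, file.path(directory, name))
  }
  wcsv(bundle$calibration_records, "calibration.csv")
  wcsv(bundle$measurements, "rois.csv")
  wcsv(bundle$bias, "bias.csv")
  wcsv(bundle$cnr, "cnr.csv")
  wcsv(bundle$stats, "stats.csv")
  wcsv(bundle$trends, "trends.csv")
  wcsv(bundle$bland_altman, "bland_altman.csv")
  for (nm in names(bundle$mean_maps)) {
    mm <- bundle$mean_maps[[nm]]
    for (m in c("water", "iodine", "gadolinium")) {
      path <- file.path(directory, sprintf("map_%s_%s.tif", m, nm))
      ret <- try(write_float_tiff(mm[[m]], path, mm$pixel_size_mm),
                 silent = TRUE)
      if (inherits(ret, "try-error"))
        stop("failed to write ", path, ": ", attr(ret, "condition")$message)
    }
  }
  mpath <- file.path(directory, "manifest.yaml")
  man <- bundle$manifest
  man$scan_seeds <- lapply(as.list(man$scan_seeds), unname)
  yaml::write_yaml(man, mpath)
  invisible(mpath)
}
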