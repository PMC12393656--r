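#' Measure insert and background ROIs on material maps
#'
#' Places a circular ROI at the center of every insert, with ROI radius equal
#' to 60% of the insert radius (i.e. the ROI covers 60% of the sample
#' diameter), plus one background ROI at the center of the water holder, on
#' both the iodine and gadolinium maps. Slice averaging across the scan
#' volume is emulated by pooling the pixels of several independent noise
#' realizations of the same condition.
#'
#' @param maps A `material_map_set` or a list of them (independent
#'   realizations of one condition; default pooling emulates 15 central
#'   slices).
#' @param spec The generating [phantom_spec()] (ground truth geometry).
#' @param background_center ROI center for the water background, mm.
#' @param background_radius_mm Background ROI radius (default: the insert
#'   ROI radius).
#' @param dose_mgy,repeat_index Condition labels attached to the rows
#'   (defaults taken from the first map set).
#' @param min_pixels Minimum pixels per ROI per realization (default 50).
#' @return A tibble with one row per (insert or background) x material map:
#'   `insert_id`, `material_map`, `true_concentration`, `solution_type`,
#'   `dose_mgy`, `repeat_index`, `n_realizations`, `mean`, `std`, `n_pixels`.
#' @export
measure_rois <- function(maps, spec, background_center = c(0, 0),
                         background_radius_mm = NULL,
                         dose_mgy = NULL, repeat_index = NULL,
                         min_pixels = 50L) {
  if (inherits(maps, "material_map_set")) maps <- list(maps)
  stopifnot(inherits(spec, "phantom_spec"))
  px <- maps[[1]]$pixel_size_mm
  if (is.null(dose_mgy)) dose_mgy <- maps[[1]]$dose_mgy
  if (is.null(repeat_index)) repeat_index <- maps[[1]]$repeat_index
  solution <- ifelse(spec$inserts$iodine_mg_ml > 0 &
                       spec$inserts$gadolinium_mg_ml > 0, "mixed", "pure")
  rois <- dplyr::bind_rows(
    tibble::tibble(insert_id = spec$inserts$insert_id,
                   x_mm = spec$inserts$x_mm, y_mm = spec$inserts$y_mm,
                   radius_mm = 0.6 * spec$inserts$radius_mm,
                   solution_type = solution,
                   iodine = spec$inserts$iodine_mg_ml,
                   gadolinium = spec$inserts$gadolinium_mg_ml),
    tibble::tibble(insert_id = "water_background",
                   x_mm = background_center[1], y_mm = background_center[2],
                   radius_mm = background_radius_mm %||%
                     (0.6 * spec$inserts$radius_mm[1]),
                   solution_type = "background", iodine = 0, gadolinium = 0))
  out <- list()
  for (i in seq_len(nrow(rois))) {
    for (m in c("iodine", "gadolinium")) {
      vals <- unlist(lapply(maps, function(mp) {
        n <- nrow(mp[[m]])
        cc <- (seq_len(n) - (n + 1) / 2) * px
        inside <- outer((cc - rois$x_mm[i])^2, (cc - rois$y_mm[i])^2, "+") <=
          rois$radius_mm[i]^2
        if (sum(inside) < min_pixels)
          stop(sprintf("ROI '%s' has %d pixels (< %d); use a larger grid",
                       rois$insert_id[i], sum(inside), min_pixels))
        mp[[m]][inside]
      }))
      out[[length(out) + 1L]] <- tibble::tibble(
        insert_id = rois$insert_id[i], material_map = m,
        true_concentration = rois[[m]][i],
        solution_type = rois$solution_type[i],
        dose_mgy = dose_mgy %||% NA_real_,
        repeat_index = repeat_index %||% NA_integer_,
        n_realizations = length(maps),
        mean = mean(vals), std = sd(vals), n_pixels = length(vals))
    }
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contrast-to-noise ratio of one insert against the water background
#'
#' `CNR = (insert mean - background mean) / background std`.
#'
#' @param insert,background One-row tibbles (or lists) with `mean` and `std`
#'   fields, as produced by [measure_rois()].
#' @return One-row tibble: `insert_id`, `material_map`, `dose_mgy`, `cnr`.
#' @export
compute_cnr <- function(insert, background) {
  if (background$std <= 0) stop("background std must be positive")
  tibble::tibble(insert_id = insert$insert_id %||% NA_character_,
                 material_map = insert$material_map %||% NA_character_,
                 dose_mgy = insert$dose_mgy %||% NA_real_,
                 cnr = (insert$mean - background$mean) / background$std)
}

#' CNR table for a full set of ROI measurements
#'
#' Pairs every insert row with the background row of the same
#' (material map, dose, repeat) condition and applies [compute_cnr()].
#'
#' @param measurements A [measure_rois()] tibble (possibly several
#'   conditions bound together, with a `solution_type` column).
#' @return Tibble with one CNR row per insert x material map x condition.
#' @export
cnr_table <- function(measurements) {
  bg <- dplyr::filter(measurements, .data$insert_id == "water_background")
  ins <- dplyr::filter(measurements, .data$insert_id != "water_background")
  keys <- intersect(c("material_map", "dose_mgy", "repeat_index", "phantom_mode"),
                    names(measurements))
  dplyr::inner_join(ins, dplyr::select(bg, dplyr::all_of(keys),
                                       bg_mean = "mean", bg_std = "std"),
                    by = keys) |>
    dplyr::mutate(cnr = (.data$mean - .data$bg_mean) / .data$bg_std) |>
    dplyr::select(dplyr::any_of(c("insert_id", "material_map",
                                  "solution_type", "phantom_mode",
                                  "true_concentration", "dose_mgy",
                                  "repeat_index", "cnr")))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = measured - expected`; reports the mean difference and
#' the limits of agreement `mean(d) +/- 1.96 sd(d)` (sample sd, n-1). An
#' exact-percentile variant (2.5th/97.5th percentiles of `d`) is available
#' via `method = "percentile"`.
#'
#' @param measured,expected Numeric vectors of equal length (>= 2), mg/mL.
#' @param group Optional group label attached to the result row.
#' @param method `"loa"` (default, 1.96 sd) or `"percentile"`.
#' @return One-row tibble: `group`, `n`, `mean_difference`, `loa_low`,
#'   `loa_high`.
#' @export
bland_altman <- function(measured, expected, group = NA_character_,
                         method = c("loa", "percentile")) {
  method <- match.arg(method)
  if (length(measured) != length(expected))
    stop("measured and expected must have equal length")
  stopifnot(length(measured) >= 2)
  d <- measured - expected
  md <- mean(d)
  lim <- if (method == "loa") md + c(-1.96, 1.96) * sd(d) else
    unname(quantile(d, c(0.025, 0.975), type = 7))
  tibble::tibble(group = group, n = length(d), mean_difference = md,
                 loa_low = lim[1], loa_high = lim[2])
}

#' Dose-baseline bias table
#'
#' With no independent reference, the highest-dose measurement (8 mGy) is
#' treated as the baseline: `bias(dose) = mean(dose) - mean(baseline)` per
#' insert and repeat, then aggregated as mean +/- sd over inserts (and
#' repeats) within each (material map, solution type, dose) cell -- the
#' layout of the study's bias table.
#'
#' @param measurements A combined [measure_rois()] tibble covering several
#'   doses; background rows are ignored, and only inserts that actually
#'   contain the mapped material enter the table.
#' @param baseline_dose_mgy Baseline dose (default 8).
#' @return Tibble: `dose_mgy` x `material_map` x `solution_type` with
#'   `bias_mean`, `bias_sd`, `n`.
#' @export
relative_bias_vs_baseline <- function(measurements, baseline_dose_mgy = 8) {
  ins <- dplyr::filter(measurements,
                       .data$insert_id != "water_background",
                       .data$true_concentration > 0)
  keys <- intersect(c("insert_id", "material_map", "solution_type",
                      "repeat_index", "phantom_mode"), names(ins))
  base <- dplyr::filter(ins, .data$dose_mgy == baseline_dose_mgy) |>
    dplyr::select(dplyr::all_of(keys), baseline_mean = "mean")
  if (!nrow(base)) stop("no measurements at the baseline dose ",
                        baseline_dose_mgy, " mGy")
  joined <- dplyr::inner_join(ins, base, by = keys)
  if (nrow(joined) < nrow(ins))
    stop("missing baseline cell for some (insert, material) pairs")
  joined |>
    dplyr::filter(.data$dose_mgy != baseline_dose_mgy) |>
    dplyr::mutate(bias = .data$mean - .data$baseline_mean) |>
    dplyr::group_by(.data$dose_mgy, .data$material_map,
                    .data$solution_type) |>
    dplyr::summarise(bias_mean = mean(.data$bias),
                     bias_sd = sd(.data$bias),
                     n = dplyr::n(), .groups = "drop")
}

#' Ordinary least-squares linear trend
#'
#' @param x,y Numeric vectors; `x` needs at least 3 distinct values.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_trend <- function(x, y) {
  if (length(unique(x)) < 3) stop("need at least 3 distinct x values")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                 n = length(y))
}

#' Mann-Whitney U test (two-sided rank-sum test)
#'
#' Wraps the exact rank-sum test for small samples without ties (matching
#' exhaustive permutation enumeration) and the tie-corrected normal
#' approximation otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param grouping Label of the grouping variable under test.
#' @param cutoff Family-wise adjusted significance cutoff (default 0.05).
#' @return One-row tibble: `test`, `grouping`, `statistic` (U for group a),
#'   `p_value`, `cutoff`, `significant`.
#' @export
mann_whitney <- function(group_a, group_b, grouping = NA_character_,
                         cutoff = 0.05) {
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided",
                                            exact = NULL, correct = TRUE))
  tibble::tibble(test = "mann_whitney", grouping = grouping,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 cutoff = cutoff, significant = ht$p.value < cutoff)
}

#' Kruskal-Wallis test with Dunn's post hoc pairwise comparisons
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()]) across
#' k >= 3 groups, followed by Dunn's z-tests on mean ranks for every pair:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with tie
#' term `T = sum(t^3 - t) / (12 (N - 1))`. Pairwise significance uses the
#' Bonferroni-style familywise cutoff `alpha_family / n_comparisons`.
#'
#' @param groups Named list of numeric vectors (k >= 3).
#' @param grouping Label of the grouping variable under test.
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param n_comparisons Number of comparisons the correction divides by
#'   (default: the number of Dunn pairs here).
#' @return Tibble: one `kruskal_wallis` row (statistic = H) and one `dunn`
#'   row per pair (statistic = z), with `p_value`, `cutoff`, `significant`.
#' @export
kruskal_dunn <- function(groups, grouping = NA_character_,
                         alpha_family = 0.05, n_comparisons = NULL) {
  k <- length(groups)
  if (k < 3) stop("need at least 3 groups; use mann_whitney() for two")
  if (any(!lengths(groups))) stop("groups must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  kw <- stats::kruskal.test(groups)
  pairs <- utils::combn(k, 2)
  n_comparisons <- n_comparisons %||% ncol(pairs)
  cutoff <- alpha_family / n_comparisons
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  N <- length(x)
  tie_t <- table(x)
  tie_term <- sum(tie_t^3 - tie_t) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)[names(groups)]
  nn <- lengths(groups)
  dunn <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nn[i1] + 1 / nn[i2]))
    z <- unname((rbar[i1] - rbar[i2]) / se)
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(test = "dunn", grouping = grouping,
                   comparison = paste(names(groups)[i1], "vs",
                                      names(groups)[i2]),
                   statistic = unname(z), p_value = p, cutoff = cutoff,
                   significant = p < cutoff)
  })
  dplyr::bind_rows(
    tibble::tibble(test = "kruskal_wallis", grouping = grouping,
                   comparison = NA_character_,
                   statistic = unname(kw$statistic), p_value = kw$p.value,
                   cutoff = cutoff, significant = kw$p.value < cutoff),
    dplyr::bind_rows(dunn))
}

#' Bonferroni-adjusted significance cutoff
#'
#' `alpha / n`, reported at one significant figure as in the study's test
#' grid (0.05 over 117 comparisons gives 0.0004).
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_comparisons Number of comparisons.
#' @param signif_digits Significant figures for reporting (default 1).
#' @return The rounded cutoff.
#' @export
bonferroni_cutoff <- function(alpha = 0.05, n_comparisons,
                              signif_digits = 1) {
  stopifnot(n_comparisons >= 1)
  signif(alpha / n_comparisons, signif_digits)
}
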