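test_that("ROI measurement covers 60% of the insert diameter and reads exact fields", {
  spec <- build_study_phantom("pure")
  n <- 256; px <- 0.59
  cc <- (1:n - (n + 1) / 2) * px
  io <- matrix(0, n, n)
  for (k in seq_len(nrow(spec$inserts))) {
    ins <- spec$inserts[k, ]
    inside <- outer((cc - ins$x_mm)^2, (cc - ins$y_mm)^2, "+") <=
      ins$radius_mm^2
    io[inside] <- ins$iodine_mg_ml
  }
  m <- measure_rois(synthetic_maps(io), spec)
  row5 <- dplyr::filter(m, true_concentration == 5,
                        material_map == "iodine",
                        insert_id != "water_background")
  expect_equal(row5$mean, 5)
  expect_equal(row5$std, 0)
  # ROI radius is 0.6x the insert radius: pixel count matches that disk
  expect_equal(row5$n_pixels, sum(outer(cc^2, cc^2, "+") <= (0.6 * 6)^2),
               tolerance = 0.1)
  bg <- dplyr::filter(m, insert_id == "water_background")
  expect_equal(unique(bg$true_concentration), 0)
  expect_equal(unique(bg$solution_type), "background")
  # pooling realizations multiplies the pixel count
  m2 <- measure_rois(list(synthetic_maps(io), synthetic_maps(io)), spec)
  expect_equal(m2$n_pixels, 2 * m$n_pixels)
  expect_error(measure_rois(synthetic_maps(io), spec, min_pixels = 1e5),
               "larger grid")
})

test_that("CNR follows its defining arithmetic", {
  ins <- tibble::tibble(insert_id = "a", material_map = "iodine",
                        dose_mgy = 8, mean = 5, std = 1)
  bg <- tibble::tibble(mean = 0, std = 0.6)
  expect_equal(compute_cnr(ins, bg)$cnr, 5 / 0.6)
  expect_equal(compute_cnr(dplyr::mutate(ins, mean = 0), bg)$cnr, 0)
  expect_equal(compute_cnr(dplyr::mutate(ins, mean = 10), bg)$cnr,
               2 * compute_cnr(ins, bg)$cnr)
  expect_error(compute_cnr(ins, tibble::tibble(mean = 0, std = 0)),
               "positive")
})

test_that("Bland-Altman limits of agreement use the sample-sd convention", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$loa_low, 0)
  expect_equal(same$loa_high, 0)
  off <- bland_altman(c(1.5, 2.5, 3.5), c(1, 2, 3))
  expect_equal(off$mean_difference, 0.5)
  expect_equal(off$loa_high - off$loa_low, 0)
  tri <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(tri$mean_difference, 0)
  expect_equal(tri$loa_low, -1.96)   # sd({-1,0,1}) = 1 with n-1
  expect_equal(tri$loa_high, 1.96)
  expect_error(bland_altman(1:3, 1:4), "equal length")
  pc <- bland_altman(seq(-1, 1, length.out = 41), rep(0, 41),
                     method = "percentile")
  expect_lt(pc$loa_low, 0); expect_gt(pc$loa_high, 0)
})

test_that("dose-baseline bias reproduces the reference-table arithmetic and layout", {
  grid <- tidyr::expand_grid(insert_id = c("i1", "i2"),
                             material_map = c("iodine", "gadolinium"),
                             solution_type = c("pure", "mixed"),
                             dose_mgy = c(1, 2, 4, 8),
                             repeat_index = 1)
  grid$true_concentration <- 5
  grid$mean <- 5 + ifelse(grid$dose_mgy == 1, -0.7, 0)
  grid$std <- 0.5
  out <- relative_bias_vs_baseline(grid)
  expect_setequal(out$dose_mgy, c(1, 2, 4))     # baseline row excluded
  expect_equal(nrow(out), 3 * 2 * 2)
  expect_equal(out$bias_mean[out$dose_mgy == 1], rep(-0.7, 4))
  expect_equal(out$bias_mean[out$dose_mgy == 4], rep(0, 4))
  expect_error(relative_bias_vs_baseline(grid, baseline_dose_mgy = 16),
               "baseline")
})

test_that("linear trend returns slope, intercept and R-squared from OLS", {
  x <- c(1, 2.5, 5, 10)
  exact <- linear_trend(x, 1.3 * x)
  expect_equal(exact$slope, 1.3)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r_squared, 1)
  flat <- linear_trend(x, rep(2, 4))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_trend(rep(1, 4), 1:4), "distinct")
})

test_that("Mann-Whitney matches exact permutation enumeration for small samples", {
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(sep$statistic), 0)   # complete separation
  tied <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(tied$statistic), 9 / 2)  # U = n_a n_b / 2 by symmetry
  set.seed(31)
  for (k in 1:8) {
    a <- round(rnorm(sample(3:6, 1)), 6)
    b <- round(rnorm(sample(3:6, 1), mean = runif(1, -1, 1)), 6)
    got <- mann_whitney(a, b)
    expect_equal(got$p_value, mw_exact_enumeration(a, b), tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis/Dunn grid follows the rank formulas and the Bonferroni cutoff", {
  same <- kruskal_dunn(list(a = c(1, 2, 3), b = c(1, 2, 3),
                            c = c(1, 2, 3)))
  expect_equal(unname(same$statistic[same$test == "kruskal_wallis"]), 0)
  expect_equal(bonferroni_cutoff(0.05, 117), 4e-4)
  expect_equal(0.05 / 117, 0.000427, tolerance = 1e-3)
  # hand-worked 3x3 toy: ranks 1..9, mean ranks 2/5/8, no ties,
  # se = sqrt((N(N+1)/12)(1/3+1/3)) = sqrt(5)
  toy <- kruskal_dunn(list(a = c(1, 2, 3), b = c(4, 5, 6),
                           c = c(7, 8, 9)))
  d_ab <- toy[toy$test == "dunn" & toy$comparison == "a vs b", ]
  expect_equal(unname(d_ab$statistic), (2 - 5) / sqrt(5))
  expect_equal(d_ab$p_value, 2 * pnorm(-abs((2 - 5) / sqrt(5))))
  expect_equal(unique(toy$cutoff), 0.05 / 3)
  expect_error(kruskal_dunn(list(1:3, 4:6)), "mann_whitney")
})
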