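test_that("the seed tree is deterministic and covers the factorial design", {
  cfg <- study_config()
  s1 <- study_seeds(cfg)
  s2 <- study_seeds(cfg)
  expect_identical(s1, s2)
  # 2 modes x 4 doses x 3 repeats (x 15 realizations)
  expect_equal(nrow(dplyr::distinct(s1, phantom_mode, dose_mgy,
                                    repeat_index)), 24)
  expect_equal(nrow(s1), 24 * 15)
  expect_equal(anyDuplicated(s1$seed), 0)
  expect_true(all(s1$seed < 2^31))
  expect_false(identical(study_seeds(study_config(master_seed = 2))$seed,
                         s1$seed))
})

test_that("a reduced study run is deterministic and structurally complete", {
  cfg <- study_config(modes = "pure", doses_mgy = 8, repeats = 1,
                      n_realizations = 2, n_angles = 240, master_seed = 5)
  b1 <- run_full_study(cfg, model = small_model())
  b2 <- run_full_study(cfg, model = small_model())
  expect_equal(b1$measurements, b2$measurements)
  expect_equal(b1$cnr, b2$cnr)
  # (8 inserts + background) x 2 material maps
  expect_equal(nrow(b1$measurements), 18)
  expect_equal(nrow(b1$cnr), 16)
  expect_true(all(c("calibration_records", "model", "measurements", "cnr",
                    "trends", "bland_altman", "stats", "mean_maps",
                    "manifest") %in% names(b1)))
  expect_s3_class(tidy(b1), "tbl_df")
  expect_equal(nrow(glance(b1)), 1)
  # manifest suffices to identify every seed used
  expect_equal(sort(b1$manifest$scan_seeds$seed),
               sort(study_seeds(cfg)$seed))
  assign("reduced_study", b1, envir = ks_cache)
})

test_that("outputs round-trip through CSV and float TIFF", {
  b <- ks_get("reduced_study", function() {
    run_full_study(study_config(modes = "pure", doses_mgy = 8, repeats = 1,
                                n_realizations = 2, n_angles = 240,
                                master_seed = 5),
                   model = small_model())
  })
  dir <- withr::local_tempdir()
  write_outputs(b, dir)
  files <- list.files(dir)
  expect_true(all(c("rois.csv", "cnr.csv", "stats.csv", "manifest.yaml")
                  %in% files))
  # one TIFF per material per condition
  expect_equal(sum(grepl("^map_.*\\.tif$", files)), 3 * 1)
  rois <- readr::read_csv(file.path(dir, "rois.csv"),
                          show_col_types = FALSE)
  expect_equal(as.data.frame(rois), as.data.frame(b$measurements))
  img <- tiff::readTIFF(file.path(dir, grep("map_iodine", files,
                                            value = TRUE)[1]))
  expect_equal(img, b$mean_maps[[1]]$iodine, tolerance = 1e-6,
               ignore_attr = TRUE)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(sort(unlist(man$scan_seeds$seed)),
               sort(b$manifest$scan_seeds$seed))
})

test_that("the overview and agreement plots build without evaluation", {
  b <- ks_get("reduced_study", function()
    run_full_study(study_config(modes = "pure", doses_mgy = 8, repeats = 1,
                                n_realizations = 2, n_angles = 240,
                                master_seed = 5),
                   model = small_model()))
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(plot_bland_altman(b), "ggplot")
  expect_s3_class(plot_cnr_dose(b), "ggplot")
})

test_that("the config file layer validates its schema and rejects typos", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "config.yaml")
  write_default_config(p)
  cfg <- read_study_config(p)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$thresholds_kev, c(20, 55, 72, 90))
  expect_equal(cfg$doses_mgy, c(1, 2, 4, 8))
  writeLines(c("schema: kedgesim/1", "dosis_mgy: [1]"), p)
  expect_error(read_study_config(p), "unknown config key")
  writeLines("doses_mgy: [1]", p)
  expect_error(read_study_config(p), "schema")
  expect_error(read_study_config(file.path(dir, "absent.yaml")),
               "absent.yaml")
})

test_that("the CLI dispatcher reports errors and runs a tiny end-to-end job", {
  expect_equal(cli_main(c("full-run", "--config", "/no/such/file.yaml",
                          "--quiet")), 1L)
  expect_equal(cli_main(c("wat", "--quiet")), 1L)
  expect_equal(cli_main(c("full-run", "--badflag", "x")), 1L)
  dir <- withr::local_tempdir()
  expect_equal(cli_main(c("init", "--out", dir, "--quiet")), 0L)
  p <- file.path(dir, "config.yaml")
  cfg <- yaml::read_yaml(p)
  cfg$modes <- "pure"; cfg$doses_mgy <- 8; cfg$repeats <- 1
  cfg$n_realizations <- 1; cfg$n_angles <- 180
  cfg$calibration_diameters_cm <- 10; cfg$calibration_doses_mgy <- 8
  yaml::write_yaml(cfg, p)
  out <- file.path(dir, "run")
  expect_equal(suppressMessages(
    cli_main(c("full-run", "--config", p, "--out", out, "--seed", "3",
               "--quiet"))), 0L)
  expect_true(file.exists(file.path(out, "rois.csv")))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
})
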