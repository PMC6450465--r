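test_that("dataset synthesis writes movies, an index and a manifest, deterministically", {
  cfg <- test_config(noise_sd = 0.05, seed = 4, grid = c(12, 12))
  cfg$bcl_list <- c(140, 100)
  d1 <- withr::local_tempdir()
  idx <- cmd_synthesize(d1, cfg, conditions = c("control", "NE"),
                        n_repeats = 2, voltage = FALSE)
  expect_equal(nrow(idx), 2 * 2 * 2)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(all(file.exists(file.path(d1, idx$sidecar))))
  # same seed: identical files
  d2 <- withr::local_tempdir()
  cmd_synthesize(d2, cfg, conditions = c("control", "NE"),
                 n_repeats = 2, voltage = FALSE)
  f <- idx$sidecar[1]
  tif <- sub("\\.json$", "_ca.tif", f)
  expect_identical(readBin(file.path(d1, tif), "raw", 1e7),
                   readBin(file.path(d2, tif), "raw", 1e7))
  # default BZ mask is recorded in the manifest
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_gt(man$parameters$field_summary$n_bz, 0)
})

test_that("dataset analysis emits per-pixel tables and bcl summaries", {
  cfg <- test_config(noise_sd = 0.05, seed = 4, grid = c(12, 12))
  cfg$bcl_list <- c(140, 100)
  dir <- withr::local_tempdir()
  cmd_synthesize(dir, cfg, conditions = "control", n_repeats = 2,
                 voltage = FALSE)
  res <- cmd_analyze(dir)
  expect_equal(nrow(res$tables), 2)  # one row per condition x bcl
  expect_true(all(c("bz_nz_ratio", "mean_nam") %in% names(res$tables)))
  expect_true(file.exists(file.path(dir, "summary_by_bcl.csv")))
  expect_true(file.exists(file.path(dir, "summaries.json")))
  # alternans grows as the cycle length shortens (the programmed ladder)
  tab <- res$tables[order(-res$tables$bcl_ms), ]
  expect_lt(tab$mean_nam[1], tab$mean_nam[2])
})

test_that("analysis refuses mixed frame rates and missing indexes", {
  expect_error(cmd_analyze(withr::local_tempdir()), "index")
  cfg <- test_config(noise_sd = 0, seed = 4, grid = c(12, 12))
  cfg$bcl_list <- 100
  dir <- withr::local_tempdir()
  cmd_synthesize(dir, cfg, conditions = "control", n_repeats = 2,
                 voltage = FALSE)
  # corrupt one sidecar's frame rate
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  sc <- file.path(dir, idx$sidecar[2])
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  meta$frame_rate_hz <- 500
  jsonlite::write_json(meta, sc, auto_unbox = TRUE, digits = NA)
  expect_error(cmd_analyze(dir), "frame rates")
})

test_that("simulation command writes scans and manifests", {
  dir <- withr::local_tempdir()
  res <- cmd_simulate(dir, protocol = "block", bar_level = 1,
                      n_cells = 120, n_prepace = 40,
                      ci_range = c(230, 240), step = 5,
                      bz_range = c(41, 80))
  expect_s3_class(res, "vulnerability_result")
  expect_true(file.exists(file.path(dir, "block_scan.csv")))
  expect_true(file.exists(file.path(dir, "block_result.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$command, "simulate-block")
  expect_equal(man$parameters$n_prepace, 40)
})
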