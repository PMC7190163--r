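test_that("batch files append without touching prior rows and round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "results.csv")
  rows1 <- tibble::tibble(sample_id = "s1", nucleus_id = 1:6,
                          cell_type = rep(c("GFP", "mCherry"), 3),
                          count_HES1 = c(5L, 1L, 9L, 2L, 7L, 3L))
  write_batch_results(rows1, path)
  bytes1 <- readBin(path, "raw", file.size(path))

  rows2 <- tibble::tibble(sample_id = "s2", nucleus_id = 1:3,
                          cell_type = "GFP", count_HES1 = c(4L, 4L, 4L))
  write_batch_results(rows2, path)
  bytes2 <- readBin(path, "raw", file.size(path))
  expect_identical(bytes2[seq_along(bytes1)], bytes1)

  back <- read_batch_results(path)
  expect_equal(nrow(back), 9L)
  expect_equal(back[1:6, ], rows1)

  expect_error(write_batch_results(rows1, path), "already contains")
  corrupt <- file.path(dir, "corrupt.csv")
  writeLines(c("a,b", "1,2"), corrupt)
  expect_error(write_batch_results(rows1, corrupt), "corrupt")
})

test_that("metadata round-trips, overrides selectively, and validates schema", {
  dir <- withr::local_tempdir()
  cfg <- run_config(sample_id = "s1",
                    segmentation = segmentation_params(min_depth = 1e-6))
  meta <- list(sample_id = "s1", version = "0.0.1",
               config = fishcount:::config_as_list(cfg))
  path <- file.path(dir, "meta.yaml")
  save_metadata(meta, path)
  back <- load_metadata(path)
  expect_equal(back$sample_id, "s1")
  expect_equal(back$config$segmentation$min_depth, 1e-6)

  over <- load_metadata(path, overrides = list("segmentation.min_depth" = 1e-5))
  expect_equal(over$config$segmentation$min_depth, 1e-5)
  expect_equal(over$config$detect$min_mass, back$config$detect$min_mass)

  yaml::write_yaml(list(sample_id = "x"), file.path(dir, "bad.yaml"))
  expect_error(load_metadata(file.path(dir, "bad.yaml")), "missing key")
  expect_error(save_metadata(list(sample_id = "x"), path), "incomplete")
})

test_that("every configurable parameter appears in the run metadata", {
  run <- fx_run()
  flat <- function(x, prefix = "") {
    if (!is.list(x)) return(prefix)
    unlist(lapply(names(x), function(nm) flat(x[[nm]], paste0(prefix, ".", nm))))
  }
  stored <- flat(run$metadata$config)
  declared <- flat(fishcount:::config_as_list(run_config()))
  expect_true(all(setdiff(declared, stored) == character(0)))
})

test_that("a full run writes five step images plus a composite, deterministically", {
  run <- fx_run()
  dir1 <- withr::local_tempdir()
  paths <- save_step_images(run, dir1)
  expect_equal(length(paths), 6L)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths),
                  sprintf("%s_%s.png", run$sample_id,
                          c("1_filtering", "2_detection", "3_segmentation",
                            "4_assignment", "5_quantification", "composite")))
  dir2 <- withr::local_tempdir()
  paths2 <- save_step_images(run, dir2)
  for (i in seq_along(paths)) {
    expect_identical(readBin(paths[i], "raw", file.size(paths[i])),
                     readBin(paths2[i], "raw", file.size(paths2[i])))
  }

  # a partial run (through detection) produces only its stages' images
  partial <- run
  partial$labelmap <- NULL
  partial$assignments <- NULL
  partial$counts <- NULL
  dir3 <- withr::local_tempdir()
  paths3 <- save_step_images(partial, dir3)
  expect_equal(length(paths3), 2L)
})

test_that("detection overlays are deterministic PNG files", {
  sv <- fx_spot_field()
  spots <- detect_spots(sv$filtered, detection_params(min_mass = 1), channel = "SIM")
  rep <- categorize_spots(spots, 20, 30)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "o1.png"); p2 <- file.path(dir, "o2.png")
  render_detection_overlay(sv$filtered, rep, p1)
  render_detection_overlay(sv$filtered, rep, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  empty <- categorize_spots(spots[0, ], 20, 30)
  expect_no_error(render_detection_overlay(sv$filtered, empty,
                                           file.path(dir, "e.png")))
})
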