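test_that("manifest validation enforces channel-role invariants", {
  specs_ok <- tibble::tibble(name = c("DAPI", "HES1", "GFP", "mCherry"),
                             role = c("nuclei", "transcript", "cell_marker", "cell_marker"))
  vols <- lapply(1:4, function(i) array(stats::runif(2 * 8 * 8), c(2, 8, 8)))
  names(vols) <- specs_ok$name
  exp <- new_experiment("s1", vols, specs_ok)
  expect_s3_class(exp, "fish_experiment")
  expect_equal(length(exp$channels), 4L)

  expect_error(new_experiment("s", vols[1:2],
                              tibble::tibble(name = c("A", "B"),
                                             role = c("transcript", "transcript"))),
               "exactly one nuclei")
  expect_error(new_experiment("s", vols[1:2],
                              tibble::tibble(name = c("A", "B"),
                                             role = c("nuclei", "nuclei"))),
               "exactly one nuclei")
  expect_error(new_experiment("s", vols[1:1],
                              tibble::tibble(name = "A", role = "nuclei")),
               "at least one transcript")
  bad_vols <- vols
  bad_vols$HES1 <- array(0, c(2, 8, 9))
  expect_error(new_experiment("s1", bad_vols, specs_ok), "different \\(y, x\\) shapes")
})

test_that("TIFF round trip preserves arrays and manifest loading works", {
  dir <- withr::local_tempdir()
  set.seed(4)
  vols <- list(DAPI = array(stats::runif(3 * 10 * 12), c(3, 10, 12)),
               HES1 = array(stats::runif(3 * 10 * 12), c(3, 10, 12)))
  specs <- tibble::tibble(name = c("DAPI", "HES1"), role = c("nuclei", "transcript"))
  exp <- new_experiment("rt", vols, specs)
  write_experiment(exp, dir)
  manifest <- list(id = "rt", voxel_size = c(0.4, 0.285, 0.285),
                   channels = list(
                     list(name = "DAPI", role = "nuclei", path = "rt_DAPI.tif"),
                     list(name = "HES1", role = "transcript", path = "rt_HES1.tif")))
  exp2 <- load_experiment(manifest, dir = dir)
  expect_equal(unclass(exp2$channels$DAPI), unclass(exp$channels$DAPI),
               ignore_attr = TRUE, tolerance = 1e-7)
  expect_equal(unclass(exp2$channels$HES1), unclass(exp$channels$HES1),
               ignore_attr = TRUE, tolerance = 1e-7)
  expect_error(load_experiment(manifest, dir = withr::local_tempdir()),
               "not found")
})

test_that("single-page TIFF loads as a z = 1 volume", {
  dir <- withr::local_tempdir()
  m <- matrix(stats::runif(64), 8, 8)
  tiff::writeTIFF(m, file.path(dir, "flat.tif"), bits.per.sample = 32L)
  manifest <- list(channels = list(
    list(name = "DAPI", role = "nuclei", path = "flat.tif"),
    list(name = "T", role = "transcript", path = "flat.tif")))
  exp <- load_experiment(manifest, dir = dir)
  expect_equal(dim(exp$channels$DAPI)[1], 1L)
  expect_equal(exp$channels$DAPI[1, , ], m, tolerance = 1e-7)
})

test_that("normalize maps linearly to [0, 1], constant to zero, idempotently", {
  v <- new_volume(array(c(100, 600, 1100, 400, 900, 350), c(1, 2, 3)))
  nv <- normalize_volume(v)
  expect_equal(nv[1, 2, 1], 0.5)  # raw 600 with min 100, max 1100
  expect_equal(min(nv), 0)
  expect_equal(max(nv), 1)

  const <- new_volume(array(7, c(2, 3, 3)))
  expect_true(all(normalize_volume(const) == 0))

  set.seed(11)
  r <- new_volume(array(stats::rnorm(60, 5, 2), c(3, 4, 5)))
  once <- normalize_volume(r)
  expect_equal(unclass(normalize_volume(once)), unclass(once))
})

test_that("max projection equals the per-pixel brute-force maximum", {
  set.seed(2)
  v <- array(stats::runif(4 * 6 * 5), c(4, 6, 5))
  proj <- max_project(v)
  oracle <- matrix(0, 6, 5)
  for (y in 1:6) for (x in 1:5) oracle[y, x] <- max(v[, y, x])
  expect_equal(proj, oracle)

  flat <- array(stats::runif(30), c(1, 6, 5))
  expect_equal(max_project(flat), flat[1, , ])
})
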