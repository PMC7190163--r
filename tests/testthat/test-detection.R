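test_that("all well-separated synthetic spots are found with subvoxel accuracy", {
  sv <- simulate_spot_volume(n_spots = 20, shape = c(10L, 96L, 96L), seed = 3)
  f <- bandpass(normalize_volume(sv$volume), filter_params())
  spots <- detect_spots(f, detection_params(min_mass = 1), channel = "SIM")
  expect_equal(nrow(spots), 20L)
  mm <- fishcount:::match_spots(spots, sv$truth, gate = 2)
  expect_equal(nrow(mm$pairs), 20L)
  expect_lt(mean(mm$pairs$dist), 0.5)
})

test_that("degenerate inputs give empty tables, not errors", {
  zeros <- new_volume(array(0, c(4, 16, 16)))
  expect_equal(nrow(detect_spots(zeros, detection_params())), 0L)
  sv <- fx_spot_field()
  expect_equal(nrow(detect_spots(sv$filtered, detection_params(min_mass = Inf))), 0L)
  expect_error(detect_spots(new_volume(array(1, c(2, 4, 4))),
                            detection_params(spot_radius = 5)),
               "larger than")
})

test_that("the min_mass gate is monotone and threshold zero gives a superset", {
  sv <- fx_spot_field()
  thresholds <- seq(0, 40, length.out = 10)
  sets <- lapply(thresholds, function(t)
    detect_spots(sv$filtered, detection_params(min_mass = t), channel = "SIM"))
  counts <- vapply(sets, nrow, integer(1))
  expect_true(all(diff(counts) <= 0))
  key <- function(s) paste(round(s$z, 6), round(s$y, 6), round(s$x, 6))
  base_keys <- key(sets[[1]])
  for (s in sets[-1]) expect_true(all(key(s) %in% base_keys))
})

test_that("the separation filter keeps the brighter of two close spots", {
  a <- array(0, c(7, 21, 21))
  for (z in 1:7) for (y in 1:21) for (x in 1:21) {
    a[z, y, x] <- 0.6 * exp(-((z - 4)^2 / 2 + ((y - 10)^2 + (x - 10)^2) / (2 * 1.2^2))) +
                  0.4 * exp(-((z - 4)^2 / 2 + ((y - 10)^2 + (x - 11)^2) / (2 * 1.2^2)))
  }
  spots <- detect_spots(new_volume(a),
                        detection_params(min_mass = 0, separation = 3,
                                         percentile_floor = 0.9))
  expect_equal(nrow(spots), 1L)
  # the survivor sits nearer the brighter component
  expect_lt(abs(spots$x - 10.5), 1)
  # exhaustive pairwise suppression oracle on the ungated candidate set
  cand <- detect_spots(new_volume(a),
                       detection_params(min_mass = 0, separation = 1,
                                        percentile_floor = 0.9))
  if (nrow(cand) > 1) {
    ord <- order(-cand$mass, cand$z, cand$y, cand$x)
    keep <- logical(nrow(cand))
    for (i in ord) {
      ok <- TRUE
      for (j in which(keep)) {
        if ((cand$z[i] - cand$z[j])^2 + (cand$y[i] - cand$y[j])^2 +
            (cand$x[i] - cand$x[j])^2 < 9) ok <- FALSE
      }
      keep[i] <- ok
    }
    expect_equal(nrow(spots), sum(keep))
  }
})

test_that("a z = 1 volume reproduces an independent 2-D reference detector", {
  sv <- simulate_spot_volume(n_spots = 12, shape = c(1L, 80L, 80L),
                             psf_sigma = c(1, 1.5, 1.5), seed = 8)
  f <- bandpass(normalize_volume(sv$volume), filter_params())
  p <- detection_params(min_mass = 2, separation = 3, percentile_floor = 0.97)
  spots <- detect_spots(f, p)
  ref <- detect_spots_2d_reference(f[1, , ], p$spot_radius, p$min_mass,
                                   p$separation, p$percentile_floor)
  expect_equal(nrow(spots), nrow(ref))
  expect_equal(sort(spots$mass), sort(ref$mass), tolerance = 1e-10)
  ord_s <- order(spots$y, spots$x); ord_r <- order(ref$y, ref$x)
  expect_lt(max(abs(spots$y[ord_s] - ref$y[ord_r])), 0.5)
  expect_lt(max(abs(spots$x[ord_s] - ref$x[ord_r])), 0.5)
  expect_true(all(spots$z == 1))
})

test_that("interval categorization partitions the spot set", {
  sv <- fx_spot_field()
  spots <- detect_spots(sv$filtered, detection_params(min_mass = 1), channel = "SIM")
  med <- stats::median(spots$mass)
  rep <- categorize_spots(spots, med * 0.95, med * 1.05)
  expect_equal(sum(rep$counts$n), nrow(spots))
  expect_true(all(rep$spots$mass[rep$spots$bin == "below"] < med * 0.95))
  expect_true(all(rep$spots$mass[rep$spots$bin == "above"] >= med * 1.05))

  # degenerate interval: the middle bin vanishes
  rep2 <- categorize_spots(spots, med, med)
  expect_equal(rep2$counts$n[rep2$counts$bin == "within"], 0L)
  expect_equal(sum(rep2$counts$n), nrow(spots))
  expect_error(categorize_spots(spots, 2, 1), "must not exceed")
})
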