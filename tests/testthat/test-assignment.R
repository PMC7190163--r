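test_that("marker thresholding finds positive regions and drops specks", {
  img <- matrix(0.05, 48, 48)
  img[10:20, 10:20] <- 0.9      # real region
  img[40, 40] <- 0.9            # single-pixel speck
  mask <- detect_positive_regions(img, threshold = 0.3, min_size = 20,
                                  smoothing_sigma = 0)
  expect_true(all(mask[12:18, 12:18]))
  expect_false(mask[40, 40])
  expect_true(all(detect_positive_regions(img, 0, min_size = 0, smoothing_sigma = 0)))
  expect_error(detect_positive_regions(img, 1.5), "in \\[0, 1\\]")
})

test_that("nuclei are assigned to their true cell types on the fixture", {
  sim <- fx_experiment()
  run <- fx_run()
  sc <- score_against_truth(run, sim$truth)
  expect_equal(sc$assignment$accuracy, 1)
  expect_false(any(run$assignments$multi))
  # overlap fractions are decisive, not marginal
  frac_cols <- grep("^frac_", names(run$assignments))
  top <- apply(run$assignments[frac_cols], 1, max)
  expect_true(all(top > 0.9))
})

test_that("positivity is monotone in min_overlap_fraction", {
  run <- fx_run()
  n_pos <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1), function(th) {
    a <- assign_nuclei(run$labelmap, run$masks,
                       assignment_params(min_overlap_fraction = th))
    sum(unlist(a[grep("^pos_", names(a))]))
  }, numeric(1))
  expect_true(all(diff(n_pos) <= 0))
})

test_that("spot counting conserves every spot and respects region lookup", {
  L <- matrix(0L, 32, 32)
  L[5:12, 5:12] <- 1L
  L[20:28, 20:28] <- 2L
  lm <- new_labelmap(L, compact = FALSE)
  spots <- tibble::tibble(channel = "T", z = c(1, 1, 1), y = c(8.2, 24, 2),
                          x = c(8.4, 24, 2), mass = 1, peak = 1,
                          sigma_z = NA_real_, sigma_y = NA_real_,
                          sigma_x = NA_real_, fallback = FALSE,
                          region_id = NA_integer_)
  res <- count_spots_per_region(spots, lm)
  expect_equal(res$spots$region_id, c(1L, 2L, 0L))
  expect_equal(res$counts$n[res$counts$region_id == 0L], 1L)
  expect_equal(sum(res$counts$n), nrow(spots))
  bad <- spots; bad$x[1] <- 99
  expect_error(count_spots_per_region(bad, lm), "outside")

  # fixture-level conservation
  run <- fx_run()
  expect_equal(sum(run$counts$n), nrow(run$spots))
})

test_that("cell territories partition mask blobs by geodesic proximity", {
  mask <- matrix(FALSE, 32, 32)
  mask[6:26, 4:30] <- TRUE
  L <- matrix(0L, 32, 32)
  L[14:18, 7:10] <- 1L
  L[14:18, 24:27] <- 2L
  nuclei <- new_labelmap(L, compact = FALSE)
  terr <- expand_cell_territories(nuclei, mask)
  expect_true(all(terr$labels[mask] > 0))
  expect_true(all(terr$labels[L > 0] == L[L > 0]))
  # brute-force multi-source BFS distances as the oracle
  bfs_dist <- function(seed_mask, allowed) {
    d <- matrix(Inf, nrow(allowed), ncol(allowed))
    d[seed_mask] <- 0
    repeat {
      old <- d
      for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nr <- nrow(d); nc <- ncol(d)
        shifted <- matrix(Inf, nr, nc)
        i_src <- max(1, 1 - sh[1]):min(nr, nr - sh[1])
        j_src <- max(1, 1 - sh[2]):min(nc, nc - sh[2])
        shifted[i_src + sh[1], j_src + sh[2]] <- d[i_src, j_src]
        d <- pmin(d, shifted + 1)
      }
      d[!allowed] <- Inf
      if (identical(d, old)) break
    }
    d
  }
  allowed <- mask | L > 0
  d1 <- bfs_dist(L == 1L, allowed)
  d2 <- bfs_dist(L == 2L, allowed)
  oracle <- ifelse(d1 < d2, 1L, ifelse(d2 < d1, 2L, 1L))  # tie -> smaller id
  oracle[!allowed] <- 0L
  expect_equal(terr$labels, oracle)

  # nucleus outside every blob keeps itself as territory
  L2 <- L
  L2[2:4, 2:3] <- 3L
  terr2 <- expand_cell_territories(new_labelmap(L2, compact = FALSE), mask)
  expect_true(all(terr2$labels[L2 == 3L] == 3L))
})

test_that("mature mode counts inside territories instead of nucleus masks", {
  sim <- fx_experiment()
  cfg <- run_config(detect = detection_params(min_mass = fixture_min_mass()),
                    assign = assignment_params(mode = "mature"))
  run <- run_pipeline(sim$experiment, cfg)
  expect_false(is.null(run$territories))
  expect_gte(sum(run$territories$labels > 0), sum(run$labelmap$labels > 0))
  expect_equal(sum(run$counts$n), nrow(run$spots))
  # nascent spots sit inside nuclei, so per-nucleus counts still match truth
  sc <- score_against_truth(run, sim$truth)
  expect_true(all(sc$counts$error == 0))
})
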