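test_that("watershed flood separates distinct intensity maxima deterministically", {
  img <- outer(1:64, 1:64, function(i, j)
    exp(-((i - 32)^2 + (j - 22)^2) / 60) + exp(-((i - 32)^2 + (j - 42)^2) / 60))
  img <- img / max(img)
  lm <- watershed_basins(img)
  expect_equal(nrow(lm$regions), 2L)
  # every pixel in the mask carries exactly one label
  expect_true(all(lm$labels > 0))
  lm2 <- watershed_basins(img)
  expect_identical(lm$labels, lm2$labels)
  # independent implementation agrees on the number of objects
  eb <- EBImage::watershed(EBImage::Image(img), tolerance = 0)
  expect_equal(max(as.integer(eb)), 2L)
})

test_that("shallow-basin merging has identity and total-merge limits", {
  set.seed(21)
  m <- fishcount:::gaussian_smooth(matrix(stats::runif(32 * 32), 32, 32), 1.5)
  m <- (m - min(m)) / (max(m) - min(m))
  base <- watershed_basins(m)
  expect_gt(nrow(base$regions), 3)
  ident <- merge_shallow_basins(base, m, 0)
  expect_true(same_partition(base$labels, ident$labels))
  total <- merge_shallow_basins(base, m, Inf)
  expect_equal(nrow(total$regions), 1L)  # one connected component here
  # relabelling the input does not change the merged partition
  perm <- sample(nrow(base$regions))
  Lp <- base$labels
  Lp[base$labels > 0] <- perm[base$labels[base$labels > 0]]
  merged_a <- merge_shallow_basins(base, m, 0.05)
  merged_b <- merge_shallow_basins(new_labelmap(Lp, compact = FALSE), m, 0.05)
  expect_true(same_partition(merged_a$labels, merged_b$labels))
})

test_that("depth merging equals the h-maxima watershed on saddle surfaces", {
  for (seed in 1:12) {
    bs <- simulate_basin_surface(seed)
    mask <- bs$surface > bs$threshold
    base <- watershed_basins(bs$surface, mask)
    for (h in c(1e-6, 1e-5, 1e-4)) {
      merged <- merge_shallow_basins(base, bs$surface, h)
      oracle <- watershed_basins(hmaxima(bs$surface, h), mask)
      expect_true(same_partition(merged$labels, oracle$labels),
                  label = sprintf("seed %d, h %g", seed, h))
    }
  }
})

test_that("region count decreases monotonically in min_depth and min_size", {
  p <- fixture_params(seed = 2, shape = c(4L, 256L, 256L), touching_pairs = 2,
                      n_nuclei = 2, nuclei_noise_sigma = 0,
                      transcript_means = list(HES1 = c(GFP = 1, mCherry = 1)))
  sim <- simulate_experiment(p)
  nuc <- max_project(normalize_volume(sim$experiment$channels$DAPI))
  counts_depth <- vapply(c(0, 10^seq(-7, -2, by = 1)), function(md)
    nrow(segment_nuclei(nuc, segmentation_params(min_depth = md))$regions),
    integer(1))
  expect_true(all(diff(counts_depth) <= 0))
  counts_size <- vapply(c(0L, 10L, 100L, 400L, 2000L), function(ms)
    nrow(suppressWarnings(
      segment_nuclei(nuc, segmentation_params(min_size = ms)))$regions),
    integer(1))
  expect_true(all(diff(counts_size) <= 0))
})

test_that("size filtering keeps exactly the regions at or above min_size", {
  lm <- labelmap_with_areas(c(5, 50, 500))
  expect_equal(nrow(filter_small_regions(lm, 0)$regions), 3L)
  f10 <- filter_small_regions(lm, 10)
  expect_equal(nrow(f10$regions), 2L)
  expect_equal(sort(f10$regions$area), c(50L, 500L))
  expect_warning(out <- filter_small_regions(lm, 1000), "no regions")
  expect_equal(nrow(out$regions), 0L)
  expect_error(filter_small_regions(lm, -1), "non-negative")
})

test_that("ID-based correction merges, deletes, and validates", {
  lm <- labelmap_with_areas(c(30, 30, 30, 30, 30))
  merged <- correct_segmentation(lm, merges = list(c(3, 4)))
  expect_equal(nrow(merged$regions), 4L)
  expect_equal(sum(merged$regions$area), sum(lm$regions$area))
  audit <- attr(merged, "audit")
  expect_equal(audit$merges, list(c(3L, 4L)))

  deleted <- correct_segmentation(lm, deletions = 2L)
  expect_equal(nrow(deleted$regions), 4L)
  expect_true(all(deleted$labels[lm$labels == 2L] == 0L))

  expect_error(correct_segmentation(lm, deletions = 99L), "valid IDs")
  expect_error(correct_segmentation(lm, merges = list(c(1, 2)), deletions = 2L),
               "both")

  # merge-then-delete commutes with direct deletion of the members
  set.seed(31)
  for (rep in 1:5) {
    L <- matrix(sample(0:5, 30 * 30, replace = TRUE), 30, 30)
    rl <- new_labelmap(L)
    ids <- rl$regions$id
    if (length(ids) < 3) next
    a <- ids[1]; b <- ids[2]
    m1 <- correct_segmentation(rl, merges = list(c(a, b)))
    d1 <- correct_segmentation(m1, deletions = min(a, b))
    d2 <- correct_segmentation(rl, deletions = c(a, b))
    expect_identical(d1$labels > 0, d2$labels > 0)
    expect_true(same_partition(d1$labels, d2$labels))
  }
})

test_that("segmentation rendering is deterministic", {
  lm <- labelmap_with_areas(c(40, 60, 80))
  underlay <- matrix(stats::runif(64 * 64), 64, 64)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.png"); p2 <- file.path(dir, "b.png")
  render_segmentation(lm, underlay, p1)
  render_segmentation(lm, underlay, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  empty <- new_labelmap(matrix(0L, 64, 64))
  expect_no_error(render_segmentation(empty, underlay, file.path(dir, "e.png")))
})
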