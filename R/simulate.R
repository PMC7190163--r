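#' Synthetic experiment parameters
#'
#' Defines the study conditions the generator emulates: a confocal field of
#' view with Gaussian-blob nuclei (optionally deliberately touching pairs
#' with a calibrated intensity saddle), immunostain marker channels covering
#' each cell type's nuclei, and transcript channels with PSF-convolved
#' diffraction-limited spots at Poisson-drawn counts per nucleus, over a
#' smooth background gradient with Gaussian noise.
#'
#' @param shape Stack extents `(z, y, x)` in voxels.
#' @param n_nuclei Number of isolated nuclei.
#' @param nucleus_radius Range (min, max) of nucleus radii, pixels
#'   (half-maximum radius of the blob).
#' @param touching_pairs Number of deliberately abutting nucleus pairs.
#' @param saddle_depth Target intensity saddle depth between the members of
#'   each touching pair, on the normalized scale of the smoothed watershed
#'   surface (see [nuclei_surface()]).
#' @param saddle_smooth_sigma Smoothing (pixels) the saddle depth is
#'   calibrated against; use the `smoothing_sigma` you will segment with.
#' @param cell_types Named fractions of nuclei per cell type; names are the
#'   marker channel names.
#' @param transcript_means Named list: per transcript channel, a named vector
#'   of mean spot counts per cell type (Poisson).
#' @param spot_peak Peak intensity of a rendered spot.
#' @param psf_sigma PSF sigma `(z, y, x)`, voxels.
#' @param spot_min_separation Minimum separation between rendered spots, in
#'   units of the effective blurred spot width `sqrt(psf_sigma^2 + 1)` (the
#'   default 1-voxel detection low-pass included); 3.5 of these units keeps
#'   every pair clearly bimodal, i.e. resolvable by construction, matching
#'   the sparse, well-separated appearance of nascent transcription sites.
#' @param noise_sigma Gaussian noise sigma on transcript and marker channels.
#' @param nuclei_noise_sigma Gaussian noise sigma on the nuclei channel
#'   (default 0: saddle depths at the 1e-5 scale are only resolvable when
#'   residual fluctuations are below that scale).
#' @param background Amplitude of the smooth background gradient on
#'   transcript channels.
#' @param marker_level Marker stain intensity over positive nuclei.
#' @param seed Random seed; the generator is fully reproducible from it.
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(shape = c(16L, 176L, 176L),
                           n_nuclei = 6L,
                           nucleus_radius = c(13, 15),
                           touching_pairs = 0L,
                           saddle_depth = 1e-5,
                           saddle_smooth_sigma = 2,
                           cell_types = c(GFP = 0.5, mCherry = 0.5),
                           transcript_means = list(HES1 = c(GFP = 8, mCherry = 2)),
                           spot_peak = 0.5,
                           psf_sigma = c(1.0, 1.5, 1.5),
                           spot_min_separation = 3.5,
                           noise_sigma = 0.01,
                           nuclei_noise_sigma = 0,
                           background = 0.05,
                           marker_level = 0.8,
                           seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(nucleus_radius) == 2L, nucleus_radius[1] <= nucleus_radius[2],
            length(psf_sigma) == 3L, all(psf_sigma > 0))
  check_number(saddle_depth, "saddle_depth", lower = 0, upper = 1)
  structure(list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 touching_pairs = as.integer(touching_pairs),
                 saddle_depth = saddle_depth,
                 saddle_smooth_sigma = saddle_smooth_sigma,
                 cell_types = cell_types, transcript_means = transcript_means,
                 spot_peak = spot_peak, psf_sigma = psf_sigma,
                 spot_min_separation = spot_min_separation,
                 noise_sigma = noise_sigma,
                 nuclei_noise_sigma = nuclei_noise_sigma,
                 background = background, marker_level = marker_level,
                 seed = as.integer(seed)),
            class = "fixture_params")
}

# radial blob profiles as functions of squared distance.  Nuclei use a
# super-Gaussian (half-maximum at `width`, ~1.5e-5 of the peak at twice the
# radius) so neighbouring nuclei do not tilt each other's saddles; the plain
# Gaussian is used for the small bump-pair test surfaces where `width` is
# the usual sigma.
blob_profile <- function(d2, width, profile = c("nucleus", "gaussian")) {
  profile <- match.arg(profile)
  if (profile == "gaussian") exp(-d2 / (2 * width^2))
  else exp(-log(2) * (d2 / width^2)^2)
}

render_pair_patch <- function(a, width, amp, n, profile = "gaussian") {
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(y, x)
    amp * (blob_profile((y - c0)^2 + (x - c0 - a)^2, width, profile) +
           blob_profile((y - c0)^2 + (x - c0 + a)^2, width, profile)))
}

# saddle depth of a rendered two-blob patch on the pixel grid, measured the
# way the watershed sees it: min of the two discrete peaks minus the saddle
# at the midpoint, optionally after smoothing, optionally relative to the
# raw patch maximum (the scale min-max normalization imposes)
measure_pair_depth <- function(a, width, amp, smooth_sigma = 0, normalized = FALSE,
                               profile = "gaussian") {
  n <- 2L * as.integer(ceiling(a + 4 * (width + smooth_sigma))) + 15L
  p <- render_pair_patch(a, width, amp, n, profile)
  s <- if (smooth_sigma > 0) gaussian_smooth(p, smooth_sigma) else p
  c0 <- (n + 1L) / 2L
  prof <- s[c0, ]
  sad <- prof[c0]
  pkL <- max(prof[1:(c0 - 1L)])
  pkR <- max(prof[(c0 + 1L):n])
  depth <- min(pkL, pkR) - sad
  if (normalized) depth / max(p) else depth
}

# half-separation giving a target saddle depth on the pixel grid
calibrate_pair_offset <- function(depth, width, amp, smooth_sigma = 0,
                                  normalized = FALSE, profile = "gaussian") {
  f <- function(a) {
    measure_pair_depth(a, width, amp, smooth_sigma, normalized, profile) - depth
  }
  if (profile == "gaussian") {
    lo <- width * 1.001
    hi <- 3.5 * (width + smooth_sigma)
  } else {
    lo <- 0.2 * width
    hi <- 2.2 * width + smooth_sigma
  }
  as <- seq(lo, hi, length.out = 250)
  vs <- vapply(as, f, 0)
  i <- which(vs[-1] * vs[-length(vs)] <= 0)[1]
  if (is.na(i)) abort("cannot calibrate the requested saddle depth for this geometry")
  stats::uniroot(f, c(as[i], as[i + 1]), tol = 1e-13)$root
}

place_points <- function(n, lim_y, lim_x, min_dist, margin, max_tries = 20000L) {
  ys <- numeric(0); xs <- numeric(0)
  tries <- 0L
  while (length(ys) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("infeasible geometry: cannot place objects without overlap")
    }
    y <- stats::runif(1, margin, lim_y - margin)
    x <- stats::runif(1, margin, lim_x - margin)
    if (length(ys) && min((ys - y)^2 + (xs - x)^2) < min_dist^2) next
    ys <- c(ys, y); xs <- c(xs, x)
  }
  cbind(y = ys, x = xs)
}

add_blob <- function(img, cy, cx, width, amp, profile = "nucleus") {
  r <- ceiling(if (profile == "gaussian") 4 * width else 2.5 * width)
  ys <- max(1L, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  img[ys, xs] <- img[ys, xs] +
    amp * blob_profile(outer((ys - cy)^2, (xs - cx)^2, `+`), width, profile)
  img
}

add_spot_3d <- function(a, cz, cy, cx, sigma, amp) {
  d <- dim(a)
  r <- ceiling(4 * sigma)
  zs <- max(1L, floor(cz - r[1])):min(d[1], ceiling(cz + r[1]))
  ys <- max(1L, floor(cy - r[2])):min(d[2], ceiling(cy + r[2]))
  xs <- max(1L, floor(cx - r[3])):min(d[3], ceiling(cx + r[3]))
  gz <- exp(-((zs - cz)^2) / (2 * sigma[1]^2))
  gy <- exp(-((ys - cy)^2) / (2 * sigma[2]^2))
  gx <- exp(-((xs - cx)^2) / (2 * sigma[3]^2))
  blk <- a[zs, ys, xs, drop = FALSE]
  a[zs, ys, xs] <- blk + amp * outer(gz, outer(gy, gx))
  a
}

#' Generate a synthetic experiment with full ground truth
#'
#' See [fixture_params()] for the conditions emulated.  Touching pairs are
#' rendered with a grid-calibrated centre separation so that the intensity
#' saddle between the two nuclei, measured on the smoothed normalized
#' surface that [segment_nuclei()] floods, matches `saddle_depth`; all pairs
#' share the same integer-aligned geometry so the calibration holds for each.
#'
#' @param params A [fixture_params()] object.
#' @param render Set `FALSE` to skip image rendering and return ground truth
#'   only (fast, for statistical checks of the generator itself).
#' @return A list with `experiment` (a `fish_experiment`, raw intensities)
#'   and `truth`: `labelmap` (true nuclei `fish_labelmap`), `nuclei` tibble
#'   (`id, y, x, radius, cell_type, is_pair`), `spots` tibble
#'   (`channel, z, y, x, nucleus_id, cell_type`), `pairs` tibble
#'   (`id_a, id_b, target_depth, achieved_depth`), and the parameters.
#' @export
simulate_experiment <- function(params = fixture_params(), render = TRUE) {
  stopifnot(inherits(params, "fixture_params"))
  p <- params
  set.seed(p$seed)
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  rmax <- p$nucleus_radius[2]

  # --- geometry -------------------------------------------------------------
  # touching pairs are rendered as plain Gaussians (log-concave, hence a
  # single well-defined saddle between the two members); isolated nuclei use
  # the compact super-Gaussian profile.  Pair spacing guarantees the render
  # windows of different objects never overlap, so each pair's calibrated
  # saddle is exact in the full image.
  pair_radius <- mean(p$nucleus_radius)
  pair_sigma <- pair_radius / 2
  pair_a <- if (p$touching_pairs > 0L) {
    calibrate_pair_offset(p$saddle_depth, pair_sigma, 1.0,
                          smooth_sigma = p$saddle_smooth_sigma, normalized = TRUE,
                          profile = "gaussian")
  } else 0
  margin <- max(rmax, 4 * pair_sigma) + ceiling(pair_a) + 4
  min_dist <- if (p$touching_pairs > 0L) {
    max(2.6 * rmax, 8 * pair_sigma + 2 * rmax) + 2 * pair_a
  } else {
    2.6 * rmax
  }
  centers <- place_points(p$n_nuclei + p$touching_pairs, ny, nx, min_dist, margin)

  nuclei <- tibble::tibble(id = integer(), y = numeric(), x = numeric(),
                           radius = numeric(), amp = numeric(), is_pair = logical())
  next_id <- 1L
  for (k in seq_len(nrow(centers))) {
    if (k <= p$n_nuclei) {
      nuclei <- dplyr::bind_rows(nuclei, tibble::tibble(
        id = next_id, y = centers[k, "y"], x = centers[k, "x"],
        radius = stats::runif(1, p$nucleus_radius[1], p$nucleus_radius[2]),
        amp = 0.95, is_pair = FALSE))
      next_id <- next_id + 1L
    } else {
      # pair midpoints snapped to the pixel grid so every pair shares the
      # calibrated discrete geometry
      cy <- round(centers[k, "y"]); cx <- round(centers[k, "x"])
      nuclei <- dplyr::bind_rows(nuclei, tibble::tibble(
        id = c(next_id, next_id + 1L), y = c(cy, cy),
        x = c(cx - pair_a, cx + pair_a),
        radius = mean(p$nucleus_radius), amp = 1.0, is_pair = TRUE))
      next_id <- next_id + 2L
    }
  }

  # cell types: exact per-type counts from the fractions, assigned in id order
  types <- names(p$cell_types)
  n_tot <- nrow(nuclei)
  counts_per_type <- diff(c(0, round(cumsum(p$cell_types) / sum(p$cell_types) * n_tot)))
  nuclei$cell_type <- rep(types, counts_per_type)[seq_len(n_tot)]

  # true label map: nearest nucleus within its half-maximum radius
  L <- matrix(0L, ny, nx)
  for (i in seq_len(n_tot)) {
    r <- nuclei$radius[i]
    ys <- max(1L, floor(nuclei$y[i] - r)):min(ny, ceiling(nuclei$y[i] + r))
    xs <- max(1L, floor(nuclei$x[i] - r)):min(nx, ceiling(nuclei$x[i] + r))
    d2 <- outer((ys - nuclei$y[i])^2, (xs - nuclei$x[i])^2, `+`)
    sel <- d2 <= r^2
    blk <- L[ys, xs]
    blk[sel & blk == 0L] <- nuclei$id[i]
    L[ys, xs] <- blk
  }
  true_lm <- new_labelmap(L, compact = FALSE)

  # --- transcript ground truth ---------------------------------------------
  spots <- list()
  for (tc in names(p$transcript_means)) {
    means <- p$transcript_means[[tc]]
    eff_sigma <- sqrt(p$psf_sigma^2 + 1)
    placed_z <- numeric(0); placed_y <- numeric(0); placed_x <- numeric(0)
    for (i in seq_len(n_tot)) {
      lambda <- means[[nuclei$cell_type[i]]]
      n_sp <- stats::rpois(1, lambda)
      for (s in seq_len(n_sp)) {
        ok <- FALSE
        for (try in seq_len(500L)) {
          rr <- 0.7 * nuclei$radius[i] * sqrt(stats::runif(1))
          th <- stats::runif(1, 0, 2 * pi)
          sy <- nuclei$y[i] + rr * sin(th)
          sx <- nuclei$x[i] + rr * cos(th)
          sz <- if (nz > 1) stats::runif(1, 1.5, nz - 0.5) else 1
          if (length(placed_z)) {
            # separation in blurred-spot-width units so pairs stay resolvable
            d2 <- ((placed_z - sz) / eff_sigma[1])^2 +
                  ((placed_y - sy) / eff_sigma[2])^2 +
                  ((placed_x - sx) / eff_sigma[3])^2
            if (min(d2) < p$spot_min_separation^2) next
          }
          ok <- TRUE
          break
        }
        if (!ok) abort("infeasible geometry: cannot place spots at the requested density")
        placed_z <- c(placed_z, sz); placed_y <- c(placed_y, sy); placed_x <- c(placed_x, sx)
        spots[[length(spots) + 1L]] <- tibble::tibble(
          channel = tc, z = sz, y = sy, x = sx,
          nucleus_id = nuclei$id[i], cell_type = nuclei$cell_type[i])
      }
    }
  }
  spots <- if (length(spots)) dplyr::bind_rows(spots) else
    tibble::tibble(channel = character(), z = numeric(), y = numeric(),
                   x = numeric(), nucleus_id = integer(), cell_type = character())

  truth <- list(labelmap = true_lm,
                nuclei = nuclei[c("id", "y", "x", "radius", "cell_type", "is_pair")],
                spots = spots,
                pairs = if (p$touching_pairs > 0L) {
                  pid <- which(nuclei$is_pair)
                  tibble::tibble(id_a = nuclei$id[pid[seq(1, length(pid), 2)]],
                                 id_b = nuclei$id[pid[seq(2, length(pid), 2)]],
                                 target_depth = p$saddle_depth,
                                 achieved_depth = NA_real_)
                } else tibble::tibble(id_a = integer(), id_b = integer(),
                                      target_depth = numeric(),
                                      achieved_depth = numeric()),
                params = p)
  if (!render) return(list(experiment = NULL, truth = truth))

  # --- render channels ------------------------------------------------------
  dapi2d <- matrix(0, ny, nx)
  for (i in seq_len(n_tot)) {
    if (nuclei$is_pair[i]) {
      dapi2d <- add_blob(dapi2d, nuclei$y[i], nuclei$x[i],
                         pair_sigma, nuclei$amp[i], profile = "gaussian")
    } else {
      dapi2d <- add_blob(dapi2d, nuclei$y[i], nuclei$x[i],
                         nuclei$radius[i], nuclei$amp[i], profile = "nucleus")
    }
  }
  dapi <- array(rep(dapi2d, each = nz), dim = c(nz, ny, nx))
  if (p$nuclei_noise_sigma > 0) {
    dapi <- pmax(dapi + array(stats::rnorm(length(dapi), 0, p$nuclei_noise_sigma),
                              dim = dim(dapi)), 0)
  }

  # measure the achieved saddle depth the segmentation surface will see
  if (p$touching_pairs > 0L) {
    surf <- nuclei_surface(max_project(dapi) / max(dapi), p$saddle_smooth_sigma)
    for (k in seq_len(nrow(truth$pairs))) {
      ia <- truth$pairs$id_a[k]; ib <- truth$pairs$id_b[k]
      cy <- round(nuclei$y[nuclei$id == ia])
      x1 <- nuclei$x[nuclei$id == ia]; x2 <- nuclei$x[nuclei$id == ib]
      cx <- round((x1 + x2) / 2)
      span <- ceiling(abs(x2 - x1) / 2 + 3 * pair_sigma)
      prof <- surf[cy, max(1L, cx - span):min(nx, cx + span)]
      mid <- cx - max(1L, cx - span) + 1L
      sad <- prof[mid]
      truth$pairs$achieved_depth[k] <-
        min(max(prof[1:(mid - 1L)]), max(prof[(mid + 1L):length(prof)])) - sad
    }
  }

  markers <- list()
  for (ty in types) {
    m2d <- matrix(0, ny, nx)
    sel <- which(nuclei$cell_type == ty)
    for (i in sel) {
      d2 <- outer((seq_len(ny) - nuclei$y[i])^2, (seq_len(nx) - nuclei$x[i])^2, `+`)
      m2d <- m2d + p$marker_level / (1 + exp((sqrt(d2) - 1.8 * nuclei$radius[i]) / 1.5))
    }
    mk <- array(rep(m2d, each = nz), dim = c(nz, ny, nx))
    if (p$noise_sigma > 0) {
      mk <- pmax(mk + array(stats::rnorm(length(mk), 0, p$noise_sigma), dim = dim(mk)), 0)
    }
    markers[[ty]] <- mk
  }

  grad <- outer(rep(1, ny), seq(0.3, 1, length.out = nx))
  transcripts <- list()
  for (tc in names(p$transcript_means)) {
    a <- array(rep(p$background * grad, each = nz), dim = c(nz, ny, nx))
    ch_spots <- spots[spots$channel == tc, ]
    for (s in seq_len(nrow(ch_spots))) {
      a <- add_spot_3d(a, ch_spots$z[s], ch_spots$y[s], ch_spots$x[s],
                       p$psf_sigma, p$spot_peak)
    }
    if (p$noise_sigma > 0) {
      a <- pmax(a + array(stats::rnorm(length(a), 0, p$noise_sigma), dim = dim(a)), 0)
    }
    transcripts[[tc]] <- a
  }

  specs <- tibble::tibble(
    name = c("DAPI", names(transcripts), names(markers)),
    role = c("nuclei", rep("transcript", length(transcripts)),
             rep("cell_marker", length(markers))))
  channels <- c(list(DAPI = dapi), transcripts, markers)
  exp <- new_experiment(sprintf("sim_seed%d", p$seed), channels, specs)
  list(experiment = exp, truth = truth)
}

#' Generate a volume of isolated synthetic spots with ground truth
#'
#' A transcript-channel-only fixture for validating spot detection: `n_spots`
#' PSF-shaped spots at subpixel positions with a guaranteed minimum pairwise
#' distance, over a background gradient with Gaussian noise.
#'
#' @param n_spots Number of spots.
#' @param shape Stack extents `(z, y, x)`.
#' @param peak Spot peak intensity (peak SNR = `peak / noise_sigma`).
#' @param psf_sigma PSF sigma `(z, y, x)`, voxels.
#' @param min_distance Minimum centre-to-centre distance, voxels.
#' @param noise_sigma Gaussian noise sigma.
#' @param background Background gradient amplitude.
#' @param seed Random seed.
#' @return List with `volume` (raw `fish_volume`) and `truth` tibble
#'   (`z, y, x` true centres).
#' @export
simulate_spot_volume <- function(n_spots = 100L, shape = c(10L, 192L, 192L),
                                 peak = 0.5, psf_sigma = c(1.0, 1.5, 1.5),
                                 min_distance = 6, noise_sigma = 0.02,
                                 background = 0.05, seed = 1L) {
  set.seed(seed)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  margin <- 8
  zs <- numeric(0); ys <- numeric(0); xs <- numeric(0)
  tries <- 0L
  while (length(zs) < n_spots) {
    tries <- tries + 1L
    if (tries > 50000L) abort("infeasible geometry: cannot place spots")
    z <- if (nz > 1) stats::runif(1, 2, nz - 1) else 1
    y <- stats::runif(1, margin, ny - margin)
    x <- stats::runif(1, margin, nx - margin)
    if (length(zs) && min((zs - z)^2 + (ys - y)^2 + (xs - x)^2) < min_distance^2) next
    zs <- c(zs, z); ys <- c(ys, y); xs <- c(xs, x)
  }
  grad <- outer(rep(1, ny), seq(0.3, 1, length.out = nx))
  a <- array(rep(background * grad, each = nz), dim = c(nz, ny, nx))
  for (i in seq_len(n_spots)) {
    a <- add_spot_3d(a, zs[i], ys[i], xs[i], psf_sigma, peak)
  }
  if (noise_sigma > 0) {
    a <- pmax(a + array(stats::rnorm(length(a), 0, noise_sigma), dim = dim(a)), 0)
  }
  list(volume = new_volume(a, channel = "SIM"),
       truth = tibble::tibble(z = zs, y = ys, x = xs))
}

#' Generate a random surface with calibrated shallow saddles
#'
#' Builds a 32 x 32 surface of isolated two-bump components whose saddle
#' depths are drawn log-uniformly (default 10^-6.5 to 10^-3.5) and calibrated
#' on the pixel grid, for validating minimum-depth basin merging against the
#' h-maxima transform.
#'
#' @param seed Random seed.
#' @param n Surface side length.
#' @param depth_range log10 range the saddle depths are drawn from.
#' @return List with `surface`, `depths` (per pair) and `threshold`
#'   (foreground threshold separating the components).
#' @export
simulate_basin_surface <- function(seed = 1L, n = 32L, depth_range = c(-6.5, -3.5)) {
  set.seed(seed)
  ctrs <- list(c(9, 9), c(9, 23), c(23, 9), c(23, 23))[sample(4)]
  npair <- sample(2:4, 1)
  m <- matrix(0, n, n)
  depths <- numeric(0)
  for (k in seq_len(npair)) {
    d <- 10^stats::runif(1, depth_range[1], depth_range[2])
    sig <- stats::runif(1, 1.8, 2.4)
    amp <- stats::runif(1, 0.5, 0.9)
    a <- calibrate_pair_offset(d, sig, amp)
    cy <- ctrs[[k]][1]; cx <- ctrs[[k]][2]
    horiz <- stats::runif(1) < 0.5
    g <- outer(seq_len(n), seq_len(n), function(y, x) {
      if (horiz) {
        amp * (exp(-((y - cy)^2 + (x - cx - a)^2) / (2 * sig^2)) +
               exp(-((y - cy)^2 + (x - cx + a)^2) / (2 * sig^2)))
      } else {
        amp * (exp(-((x - cx)^2 + (y - cy - a)^2) / (2 * sig^2)) +
               exp(-((x - cx)^2 + (y - cy + a)^2) / (2 * sig^2)))
      }
    })
    m <- m + g
    depths <- c(depths, d)
  }
  list(surface = m, depths = depths, threshold = 0.05)
}

#' Optimal assignment (Hungarian algorithm)
#'
#' Minimum-cost matching of rows to columns of a cost matrix, by the
#' Jonker-Volgenant shortest-augmenting-path construction.
#'
#' @param cost Numeric cost matrix.
#' @return Integer vector: for each row, the matched column (`NA` when the
#'   matrix has more rows than columns and the row is unmatched).
#' @export
hungarian_match <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  transposed <- nrow(cost) > ncol(cost)
  if (transposed) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) {
    return(if (transposed) rep(NA_integer_, m) else integer(0))
  }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  row_match <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) row_match[p[j + 1]] <- j
  if (!transposed) return(row_match)
  col_match <- rep(NA_integer_, m)
  ok <- !is.na(row_match)
  col_match[row_match[ok]] <- which(ok)
  col_match
}

# gate-limited spot matching: pairs farther than `gate` voxels are never
# counted as true positives
match_spots <- function(detected, truth, gate = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) {
    return(list(pairs = tibble::tibble(true = integer(), det = integer(),
                                       dist = numeric()),
                n_true = nt, n_det = nd))
  }
  dmat <- sqrt(outer(truth$z, detected$z, `-`)^2 +
               outer(truth$y, detected$y, `-`)^2 +
               outer(truth$x, detected$x, `-`)^2)
  cost <- pmin(dmat, 10 * gate)  # soft cap keeps far pairs from distorting
  asg <- hungarian_match(cost)
  pairs <- tibble::tibble(true = seq_len(nt), det = asg)
  pairs <- pairs[!is.na(pairs$det), ]
  pairs$dist <- dmat[cbind(pairs$true, pairs$det)]
  pairs <- pairs[pairs$dist <= gate, ]
  list(pairs = pairs, n_true = nt, n_det = nd)
}

#' Score pipeline results against a fixture's ground truth
#'
#' Spot recall/precision and localization RMSE (Hungarian matching, 2-voxel
#' gate), segmentation region-count error and IoU of matched nuclei,
#' cell-type assignment accuracy, and per-nucleus count errors.
#'
#' @param results A `fish_run` (from [run_pipeline()]) or a list with any of
#'   `spots`, `labelmap`, `assignments`, `counts`.
#' @param truth The `truth` element of [simulate_experiment()].
#' @param gate Matching gate for spots, voxels.
#' @return A `fish_score` list of tibbles: `spot_metrics`, `nucleus_matches`,
#'   `segmentation`, `assignment`, `counts`.
#' @export
score_against_truth <- function(results, truth, gate = 2) {
  out <- list()

  if (!is.null(results$spots) && nrow(truth$spots) >= 0L) {
    per_ch <- lapply(unique(truth$spots$channel), function(ch) {
      det <- tibble::as_tibble(results$spots)
      det <- det[is.na(det$channel) | det$channel == ch, ]
      tru <- truth$spots[truth$spots$channel == ch, ]
      mm <- match_spots(det, tru, gate)
      tibble::tibble(channel = ch,
                     n_true = mm$n_true, n_detected = mm$n_det,
                     n_matched = nrow(mm$pairs),
                     recall = ifelse(mm$n_true > 0, nrow(mm$pairs) / mm$n_true, NA),
                     precision = ifelse(mm$n_det > 0, nrow(mm$pairs) / mm$n_det, NA),
                     rmse = ifelse(nrow(mm$pairs) > 0,
                                   sqrt(mean(mm$pairs$dist^2)), NA))
    })
    out$spot_metrics <- dplyr::bind_rows(per_ch)
  }

  matches <- NULL
  if (!is.null(results$labelmap)) {
    Lp <- results$labelmap$labels
    Lt <- truth$labelmap$labels
    ids_p <- results$labelmap$regions$id
    ids_t <- truth$labelmap$regions$id
    if (length(ids_p) && length(ids_t)) {
      inter <- table(factor(Lt[Lt > 0L | Lp > 0L], levels = c(0L, ids_t)),
                     factor(Lp[Lt > 0L | Lp > 0L], levels = c(0L, ids_p)))
      at <- rowSums(inter); ap <- colSums(inter)
      iou <- matrix(0, length(ids_t), length(ids_p))
      for (i in seq_along(ids_t)) {
        for (j in seq_along(ids_p)) {
          ov <- inter[i + 1L, j + 1L]
          iou[i, j] <- ov / (at[i + 1L] + ap[j + 1L] - ov)
        }
      }
      asg <- hungarian_match(1 - iou)
      matches <- tibble::tibble(true_id = ids_t,
                                pred_id = ifelse(is.na(asg), NA_integer_, ids_p[asg]),
                                iou = ifelse(is.na(asg), 0, iou[cbind(seq_along(ids_t), asg)]))
      matches$pred_id[matches$iou < 0.3] <- NA_integer_
      matches$iou[is.na(matches$pred_id)] <- 0
    } else {
      matches <- tibble::tibble(true_id = ids_t, pred_id = NA_integer_, iou = 0)
    }
    out$nucleus_matches <- matches
    out$segmentation <- tibble::tibble(
      n_true = length(ids_t), n_predicted = length(ids_p),
      count_error = length(ids_p) - length(ids_t),
      mean_iou = mean(matches$iou))
  }

  if (!is.null(results$assignments) && !is.null(matches)) {
    tt <- truth$nuclei
    acc <- vapply(seq_len(nrow(matches)), function(i) {
      if (is.na(matches$pred_id[i])) return(NA)
      pred <- results$assignments$cell_type[
        results$assignments$nucleus_id == matches$pred_id[i]]
      length(pred) == 1L && pred == tt$cell_type[tt$id == matches$true_id[i]]
    }, logical(1))
    out$assignment <- tibble::tibble(
      n_matched = sum(!is.na(acc)),
      n_correct = sum(acc, na.rm = TRUE),
      accuracy = ifelse(any(!is.na(acc)), mean(acc, na.rm = TRUE), NA))
  }

  if (!is.null(results$counts) && !is.null(matches)) {
    true_counts <- dplyr::count(truth$spots, .data$nucleus_id, name = "n_true")
    cmp <- dplyr::left_join(matches, true_counts,
                            by = c(true_id = "nucleus_id"))
    cmp$n_true[is.na(cmp$n_true)] <- 0L
    cmp <- dplyr::left_join(cmp,
                            dplyr::rename(results$counts, n_pred = "n"),
                            by = c(pred_id = "region_id"))
    cmp$n_pred[is.na(cmp$n_pred)] <- 0L
    cmp$error <- cmp$n_pred - cmp$n_true
    out$counts <- cmp
  }

  structure(out, class = "fish_score")
}

#' @export
print.fish_score <- function(x, ...) {
  cat("<fish_score>\n")
  if (!is.null(x$spot_metrics)) {
    for (i in seq_len(nrow(x$spot_metrics))) {
      r <- x$spot_metrics[i, ]
      cat(sprintf("  spots %s: recall %.3f, precision %.3f, rmse %.3f vox\n",
                  r$channel, r$recall, r$precision, r$rmse))
    }
  }
  if (!is.null(x$segmentation)) {
    cat(sprintf("  segmentation: %d/%d regions, mean IoU %.3f\n",
                x$segmentation$n_predicted, x$segmentation$n_true,
                x$segmentation$mean_iou))
  }
  if (!is.null(x$assignment)) {
    cat(sprintf("  assignment: %d/%d correct (%.1f%%)\n", x$assignment$n_correct,
                x$assignment$n_matched, 100 * x$assignment$accuracy))
  }
  if (!is.null(x$counts)) {
    cat(sprintf("  counts: MAE %.3f\n", mean(abs(x$counts$error))))
  }
  invisible(x)
}
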