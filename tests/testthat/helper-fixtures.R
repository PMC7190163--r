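# Shared fixtures, built lazily once per test session, and small independent
# oracles used to freeze expected values.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_env)) assign(name, builder(), envir = .fx_env)
  get(name, envir = .fx_env)
}

# detection fixture: 100 well-separated spots, peak SNR 25
fx_spot_field <- function() fx("spot_field", function() {
  sv <- simulate_spot_volume(n_spots = 100, seed = 1)
  filtered <- bandpass(normalize_volume(sv$volume), filter_params())
  list(raw = sv$volume, filtered = filtered, truth = sv$truth)
})

# the standard six-nucleus, two-cell-type experiment
fx_experiment <- function() fx("experiment", function() {
  simulate_experiment(fixture_params(seed = 1))
})

fx_run <- function() fx("run", function() {
  run_pipeline(fx_experiment()$experiment,
               run_config(detect = detection_params(min_mass = fixture_min_mass())))
})

# analysis min_mass for fixture runs: a quarter of the nominal integrated
# spot intensity implied by the generator's own parameters
fixture_min_mass <- function(p = fixture_params()) {
  0.25 * p$spot_peak * (2 * pi)^1.5 * prod(p$psf_sigma)
}

# partition equality up to relabelling
same_partition <- function(L1, L2) {
  if (!all((L1 > 0) == (L2 > 0))) return(FALSE)
  f <- L1 > 0
  if (!any(f)) return(TRUE)
  tab <- table(L1[f], L2[f])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# dense direct 3-D convolution with a Gaussian kernel, reflect boundary:
# the brute-force oracle for the separable implementation
dense_gaussian_blur3 <- function(a, sigma, truncate = 4) {
  d <- dim(a)
  r <- max(1L, ceiling(truncate * sigma))
  k1 <- stats::dnorm(-r:r, sd = sigma)
  k1 <- k1 / sum(k1)
  refl <- function(j, n) {
    j0 <- (j - 1L) %% (2L * n)
    if (j0 >= n) j0 <- 2L * n - 1L - j0
    j0 + 1L
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      acc <- acc + k1[dz + r + 1] * k1[dy + r + 1] * k1[dx + r + 1] *
        a[refl(z + dz, d[1]), refl(y + dy, d[2]), refl(x + dx, d[3])]
    }
    out[z, y, x] <- acc
  }
  out
}

# brute-force minimum-cost assignment by permutation enumeration (n <= 7)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n <= 7, n <= ncol(cost))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf; best_p <- NULL
  for (p in perms(seq_len(ncol(cost)))) {
    tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (tot < best) { best <- tot; best_p <- p[seq_len(n)] }
  }
  list(cost = best, assignment = best_p)
}

# direct 2-D spot detection: independent reference for the z = 1 code path.
# Same contract (local maxima, window mass, gate, greedy separation) written
# as plain loops over the slice.
detect_spots_2d_reference <- function(img, radius, min_mass, separation,
                                      percentile_floor) {
  stopifnot(is.matrix(img))
  thr <- stats::quantile(img, percentile_floor, names = FALSE)
  cand <- list()
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
    v <- img[y, x]
    if (v <= thr || v <= 0) next
    nb <- img[max(1, y - 1):min(nrow(img), y + 1),
              max(1, x - 1):min(ncol(img), x + 1)]
    if (v < max(nb)) next
    yr <- max(1, y - radius):min(nrow(img), y + radius)
    xr <- max(1, x - radius):min(ncol(img), x + radius)
    w <- img[yr, xr]
    wt <- pmax(w - min(w), 0)
    cy <- sum(row(w) * wt) / sum(wt) + yr[1] - 1
    cx <- sum(col(w) * wt) / sum(wt) + xr[1] - 1
    cand[[length(cand) + 1L]] <- c(y = cy, x = cx, mass = sum(w))
  }
  if (!length(cand)) return(data.frame(y = numeric(), x = numeric(), mass = numeric()))
  df <- as.data.frame(do.call(rbind, cand))
  df <- df[df$mass >= min_mass, , drop = FALSE]
  df <- df[order(-df$mass, df$y, df$x), , drop = FALSE]
  keep <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in which(keep)) {
      if ((df$y[i] - df$y[j])^2 + (df$x[i] - df$x[j])^2 < separation^2) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  df[keep, , drop = FALSE]
}

# small synthetic label map with specified region areas (squares on a grid)
labelmap_with_areas <- function(areas) {
  n <- 64L
  L <- matrix(0L, n, n)
  x0 <- 2L
  for (i in seq_along(areas)) {
    side <- ceiling(sqrt(areas[i]))
    px <- arrayInd(seq_len(areas[i]), c(side, side))
    L[cbind(2L + px[, 1], x0 + px[, 2])] <- i
    x0 <- x0 + side + 3L
  }
  new_labelmap(L, compact = FALSE)
}
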