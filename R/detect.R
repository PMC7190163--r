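#' Spot detection parameters
#'
#' @param spot_radius Half-size of the fit window per axis, voxels (odd
#'   windows of side `2 * spot_radius + 1`); default 3.
#' @param min_mass Minimum integrated intensity (sum of filtered intensities
#'   over the fit window) for a detection to be retained.  This is the
#'   single most influential detection parameter; use [categorize_spots()]
#'   and the overlay QC image to choose it.
#' @param separation Minimum centre-to-centre distance between retained
#'   spots, voxels; the higher-mass spot wins.
#' @param percentile_floor Candidate local maxima must exceed this intensity
#'   quantile of the filtered volume (default 0.99).
#' @return A `detection_params` list.
#' @export
detection_params <- function(spot_radius = 3L, min_mass = 0.1,
                             separation = 3, percentile_floor = 0.99) {
  check_number(spot_radius, "spot_radius", lower = 1)
  check_number(min_mass, "min_mass", lower = 0)
  check_number(separation, "separation", lower = 1)
  check_number(percentile_floor, "percentile_floor", lower = 0, upper = 1)
  structure(list(spot_radius = as.integer(spot_radius), min_mass = min_mass,
                 separation = separation, percentile_floor = percentile_floor),
            class = "detection_params")
}

# 3x3(x3) maximum filter by running pmax of +-1 shifts along each axis,
# replicating edge values so border maxima are detectable
max_filter3 <- function(a) {
  d <- dim(a)
  for (ax in seq_along(d)) {
    if (d[ax] == 1L) next
    n <- d[ax]
    idx_lo <- c(1L, seq_len(n - 1L))
    idx_hi <- c(seq(2L, n), n)
    pick <- function(i) {
      args <- rep(list(quote(expr = )), length(d))
      args[[ax]] <- i
      do.call(`[`, c(list(a), args, list(drop = FALSE)))
    }
    a <- pmax(pick(idx_lo), a, pick(idx_hi))
    dim(a) <- d
  }
  a
}

empty_spots <- function(channel = NA_character_) {
  tibble::tibble(channel = character(), z = numeric(), y = numeric(),
                 x = numeric(), mass = numeric(), peak = numeric(),
                 sigma_z = numeric(), sigma_y = numeric(), sigma_x = numeric(),
                 fallback = logical(), region_id = integer())
}

# least-squares Gaussian fit over the window; returns subpixel centre and
# sigmas or NULL on failure
fit_gaussian_window <- function(w, z0, y0, x0, radius) {
  d <- dim(w)
  grid <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  grid$v <- as.vector(w)
  fit2d <- d[1] == 1L
  lo <- min(grid$v)
  wt <- grid$v - lo
  tot <- sum(wt)
  if (tot <= 0) return(NULL)
  start <- list(A = max(grid$v) - lo, b = lo,
                cz = sum(grid$z * wt) / tot,
                cy = sum(grid$y * wt) / tot,
                cx = sum(grid$x * wt) / tot,
                sz = 1.2, sy = 1.5, sx = 1.5)
  form <- if (fit2d) {
    v ~ A * exp(-0.5 * (((y - cy) / sy)^2 + ((x - cx) / sx)^2)) + b
  } else {
    v ~ A * exp(-0.5 * (((z - cz) / sz)^2 + ((y - cy) / sy)^2 + ((x - cx) / sx)^2)) + b
  }
  if (fit2d) start <- start[c("A", "b", "cy", "cx", "sy", "sx")]
  lower <- c(A = 0, b = -Inf,
             if (!fit2d) c(cz = 1), cy = 1, cx = 1,
             if (!fit2d) c(sz = 0.1), sy = 0.1, sx = 0.1)
  upper <- c(A = Inf, b = Inf,
             if (!fit2d) c(cz = d[1]), cy = d[2], cx = d[3],
             if (!fit2d) c(sz = 4 * radius), sy = 4 * radius, sx = 4 * radius)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      form, data = grid, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  sig <- c(z = if (fit2d) NA_real_ else unname(cf["sz"]),
           y = unname(cf["sy"]), x = unname(cf["sx"]))
  ok <- all(sig[!is.na(sig)] >= 0.5 & sig[!is.na(sig)] <= 2 * radius)
  if (!ok) return(NULL)
  list(center = c(z = if (fit2d) 1 else unname(cf["cz"]),
                  y = unname(cf["cy"]), x = unname(cf["cx"])),
       sigma = sig)
}

centroid_window <- function(w) {
  d <- dim(w)
  wt <- pmax(w - min(w), 0)
  tot <- sum(wt)
  if (tot <= 0) {
    return(c(z = (d[1] + 1) / 2, y = (d[2] + 1) / 2, x = (d[3] + 1) / 2))
  }
  gz <- slice.index(w, 1); gy <- slice.index(w, 2); gx <- slice.index(w, 3)
  c(z = sum(gz * wt) / tot, y = sum(gy * wt) / tot, x = sum(gx * wt) / tot)
}

#' Detect diffraction-limited spots in a filtered volume
#'
#' Candidate local maxima above the `percentile_floor` quantile are refined
#' to subpixel centres by least-squares 3-D Gaussian fitting (falling back to
#' an intensity-weighted centroid when the fit does not converge or its
#' widths are implausible); each spot's mass is the sum of filtered
#' intensities over its `(2r+1)^3` window; spots with `mass < min_mass` are
#' discarded; finally a minimum `separation` is enforced, keeping the
#' higher-mass spot (ties broken by mass, then z, y, x).  Deterministic
#' given identical input.  A `z = 1` volume is handled as a 2-D image.
#'
#' @param v Band-pass filtered volume (see [bandpass()]).
#' @param params A [detection_params()] object.
#' @param channel Channel name recorded in the table.
#' @return A `fish_spots` tibble: `channel, z, y, x, mass, peak, sigma_z,
#'   sigma_y, sigma_x, fallback, region_id` (one row per retained spot,
#'   `region_id` unset until [count_spots_per_region()]).
#' @export
detect_spots <- function(v, params = detection_params(),
                         channel = attr(v, "channel") %||% NA_character_) {
  stopifnot(inherits(params, "detection_params"))
  v <- as_volume(v)
  d <- dim(v)
  r <- params$spot_radius
  if (2L * r + 1L > max(d[2], d[3])) {
    abort("`spot_radius` window larger than the image plane")
  }
  a <- unclass(v)
  out <- empty_spots()
  if (all(a == 0)) return(structure(out, class = c("fish_spots", class(out))))

  floor_val <- stats::quantile(a, params$percentile_floor, names = FALSE)
  cand <- which(a == max_filter3(a) & a > floor_val & a > 0)
  if (!length(cand)) return(structure(out, class = c("fish_spots", class(out))))
  ijk <- arrayInd(cand, d)

  rows <- lapply(seq_len(nrow(ijk)), function(i) {
    cz <- ijk[i, 1]; cy <- ijk[i, 2]; cx <- ijk[i, 3]
    zr <- max(1L, cz - r):min(d[1], cz + r)
    yr <- max(1L, cy - r):min(d[2], cy + r)
    xr <- max(1L, cx - r):min(d[3], cx + r)
    w <- a[zr, yr, xr, drop = FALSE]
    fit <- fit_gaussian_window(w, cz, cy, cx, r)
    fallback <- is.null(fit)
    ctr <- if (fallback) centroid_window(w) else fit$center
    sig <- if (fallback) c(z = NA_real_, y = NA_real_, x = NA_real_) else fit$sigma
    tibble::tibble(channel = channel,
                   z = zr[1] - 1 + ctr[["z"]],
                   y = yr[1] - 1 + ctr[["y"]],
                   x = xr[1] - 1 + ctr[["x"]],
                   mass = sum(w), peak = a[cz, cy, cx],
                   sigma_z = sig[["z"]], sigma_y = sig[["y"]], sigma_x = sig[["x"]],
                   fallback = fallback, region_id = NA_integer_)
  })
  spots <- dplyr::bind_rows(rows)
  spots <- dplyr::filter(spots, .data$mass >= params$min_mass)
  spots <- dplyr::arrange(spots, dplyr::desc(.data$mass), .data$z, .data$y, .data$x)

  if (nrow(spots) > 1L) {
    keep <- logical(nrow(spots))
    kz <- ky <- kx <- numeric(0)
    for (i in seq_len(nrow(spots))) {
      if (length(kz)) {
        d2 <- (kz - spots$z[i])^2 + (ky - spots$y[i])^2 + (kx - spots$x[i])^2
        if (any(d2 < params$separation^2)) next
      }
      keep[i] <- TRUE
      kz <- c(kz, spots$z[i]); ky <- c(ky, spots$y[i]); kx <- c(kx, spots$x[i])
    }
    spots <- spots[keep, ]
  }
  structure(spots, class = c("fish_spots", class(out)), params = params)
}

#' Categorize detected spots into intensity intervals
#'
#' Bins spots by mass relative to a lower and upper bound, for choosing
#' `min_mass`: inspecting the three classes overlaid on the filtered image
#' shows whether spots near the gate are real.  Typical bound pairs on
#' normalized data are (0.06, 0.07) at a permissive gate and (0.23, 0.24) at
#' a strict one.
#'
#' @param spots A `fish_spots` tibble.
#' @param lower,upper Interval bounds, `lower <= upper`.
#' @return An `interval_report`: the spots with a `bin` column
#'   (`below`/`within`/`above`, partitioning the set), the bounds, and
#'   per-bin counts.
#' @export
categorize_spots <- function(spots, lower, upper) {
  if (lower > upper) abort("`lower` must not exceed `upper`")
  spots$bin <- factor(
    dplyr::case_when(spots$mass < lower ~ "below",
                     spots$mass < upper ~ "within",
                     TRUE ~ "above"),
    levels = c("below", "within", "above"))
  counts <- tidyr::complete(dplyr::count(tibble::as_tibble(spots), .data$bin),
                            bin = factor(c("below", "within", "above"),
                                         levels = c("below", "within", "above")),
                            fill = list(n = 0L))
  structure(list(lower = lower, upper = upper, spots = spots, counts = counts),
            class = "interval_report")
}

#' @export
print.interval_report <- function(x, ...) {
  cat(sprintf("<interval_report> bounds [%g, %g): below %d | within %d | above %d\n",
              x$lower, x$upper, x$counts$n[1], x$counts$n[2], x$counts$n[3]))
  invisible(x)
}

#' @describeIn categorize_spots ggplot of spot masses against the bounds.
#' @param object An `interval_report`.
#' @param ... Ignored.
#' @export
autoplot.interval_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object$spots),
                  ggplot2::aes(x = .data$mass, fill = .data$bin)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "integrated spot intensity (mass)", y = "spots",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn detect_spots ggplot overlay of spots on the max projection.
#' @param object A `fish_spots` tibble.
#' @param volume Optional volume to show as underlay.
#' @param ... Ignored.
#' @export
autoplot.fish_spots <- function(object, volume = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(volume)) {
    m <- max_project(volume)
    df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
    df$value <- m[cbind(df$y, df$x)]
    p <- p + ggplot2::geom_raster(data = df,
                                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p + ggplot2::geom_point(data = tibble::as_tibble(object),
                          ggplot2::aes(.data$x, .data$y, size = .data$mass),
                          shape = 21, colour = "red", fill = NA) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
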