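# Deterministic raster rendering of QC images.  Images are composed as
# H x W x 3 arrays in [0,1] and written with png::writePNG, so re-running a
# pipeline reproduces byte-identical files (no graphics device involved).

# 3 x 5 bitmap digits, enough to print region IDs and counts
digit_font <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(r) {
    do.call(rbind, lapply(r, function(s) as.integer(strsplit(s, "")[[1]]) == 1L))
  })
})

gray_to_rgb <- function(m) {
  m <- pmin(pmax(m, 0), 1)
  array(rep(m, 3L), dim = c(dim(m), 3L))
}

blank_rgb <- function(nr, nc, value = 0) array(value, dim = c(nr, nc, 3L))

set_pixels <- function(rgb, ys, xs, col) {
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  ok <- ys >= 1L & ys <= nr & xs >= 1L & xs <= nc
  ys <- ys[ok]; xs <- xs[ok]
  for (ch in 1:3) rgb[cbind(ys, xs, ch)] <- col[ch]
  rgb
}

draw_ring <- function(rgb, cy, cx, radius, col, width = 1.2) {
  span <- ceiling(radius + width)
  ys <- rep((-span):span, each = 2L * span + 1L)
  xs <- rep((-span):span, times = 2L * span + 1L)
  d <- sqrt(ys^2 + xs^2)
  on <- abs(d - radius) <= width / 2 + 0.35
  set_pixels(rgb, round(cy) + ys[on], round(cx) + xs[on], col)
}

draw_number <- function(rgb, value, y, x, col, scale = 2L) {
  digits <- strsplit(as.character(as.integer(value)), "")[[1]]
  cx <- x
  for (dg in digits) {
    bm <- digit_font[[dg]]
    bm <- bm[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale), drop = FALSE]
    on <- which(bm, arr.ind = TRUE)
    rgb <- set_pixels(rgb, y + on[, 1] - 1L, cx + on[, 2] - 1L, col)
    cx <- cx + 3L * scale + scale
  }
  rgb
}

region_boundaries <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  b <- matrix(FALSE, nr, nc)
  b[-nr, ] <- b[-nr, ] | (labels[-nr, ] != labels[-1, ])
  b[-1, ]  <- b[-1, ]  | (labels[-1, ] != labels[-nr, ])
  b[, -nc] <- b[, -nc] | (labels[, -nc] != labels[, -1])
  b[, -1]  <- b[, -1]  | (labels[, -1] != labels[, -nc])
  b & labels > 0L
}

write_rgb_png <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

bin_colors <- c(below = c(1, 0.25, 0.25), within = c(1, 1, 0.2), above = c(0.2, 1, 0.2))
bin_color <- function(bin) switch(bin,
                                  below = c(1, 0.25, 0.25),
                                  within = c(1, 1, 0.2),
                                  above = c(0.2, 1, 0.2))

#' Render the detection QC overlay
#'
#' Max projection of the filtered volume with a colour-coded ring per spot
#' (red below the lower bound, yellow within the interval, green above) and
#' the three bin counts printed top-left in the matching colours.
#' Deterministic: identical inputs give byte-identical PNG files.
#'
#' @param v Filtered volume the spots were detected in.
#' @param report An `interval_report` from [categorize_spots()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
render_detection_overlay <- function(v, report, path) {
  stopifnot(inherits(report, "interval_report"))
  m <- max_project(v)
  if (max(m) > 0) m <- m / max(m)
  rgb <- gray_to_rgb(m)
  sp <- report$spots
  if (nrow(sp)) {
    for (i in order(sp$mass)) {
      rgb <- draw_ring(rgb, sp$y[i], sp$x[i], radius = 4, col = bin_color(as.character(sp$bin[i])))
    }
  }
  y0 <- 4L
  for (b in c("below", "within", "above")) {
    n <- report$counts$n[report$counts$bin == b]
    rgb <- draw_number(rgb, n, y0, 4L, bin_color(b), scale = 2L)
    y0 <- y0 + 14L
  }
  write_rgb_png(rgb, path)
}

#' Render a segmentation overlay
#'
#' Region boundaries in cyan over the underlay image, with each region's ID
#' printed at its centroid.  Deterministic PNG output.
#'
#' @param labelmap A `fish_labelmap`.
#' @param underlay 2-D image (same shape) shown in grayscale.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
render_segmentation <- function(labelmap, underlay, path) {
  stopifnot(inherits(labelmap, "fish_labelmap"))
  if (!identical(dim(labelmap$labels), dim(underlay))) {
    abort("underlay shape does not match the label map")
  }
  u <- underlay
  if (max(u) > 0) u <- u / max(u)
  rgb <- gray_to_rgb(u)
  bd <- which(region_boundaries(labelmap$labels), arr.ind = TRUE)
  if (nrow(bd)) rgb <- set_pixels(rgb, bd[, 1], bd[, 2], c(0, 1, 1))
  for (i in seq_len(nrow(labelmap$regions))) {
    r <- labelmap$regions[i, ]
    rgb <- draw_number(rgb, r$id, round(r$centroid_y) - 5L, round(r$centroid_x) - 3L,
                       c(1, 1, 0.2), scale = 2L)
  }
  write_rgb_png(rgb, path)
}

# fixed pseudocolours per channel role, cycling for multiple markers
role_palette <- function(specs) {
  marker_cols <- list(c(0.1, 1, 0.1), c(1, 0.1, 1), c(1, 0.6, 0.1), c(0.1, 0.8, 1))
  mi <- 0L
  cols <- list()
  for (i in seq_len(nrow(specs))) {
    cols[[specs$name[i]]] <- switch(specs$role[i],
      nuclei = c(0.25, 0.35, 1),
      transcript = c(1, 1, 1),
      cell_marker = { mi <<- mi + 1L; marker_cols[[(mi - 1L) %% 4L + 1L]] })
  }
  cols
}

#' Render a pseudocolour composite of all channels with counts
#'
#' Additive blend of per-channel max projections (nuclei blue, markers
#' green/magenta/..., transcripts white), nuclei boundaries, and the
#' per-nucleus transcript count printed at each centroid.
#'
#' @param exp A normalized `fish_experiment`.
#' @param labelmap Nuclei `fish_labelmap`.
#' @param counts Count table (`region_id, n`) from [count_spots_per_region()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
render_composite <- function(exp, labelmap, counts, path) {
  cols <- role_palette(exp$specs)
  d <- dim(exp$channels[[1]])[2:3]
  rgb <- blank_rgb(d[1], d[2])
  for (nm in exp$specs$name) {
    m <- max_project(exp$channels[[nm]])
    if (max(m) > 0) m <- m / max(m)
    col <- cols[[nm]]
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] + m * col[ch]
  }
  rgb <- pmin(rgb, 1)
  bd <- which(region_boundaries(labelmap$labels), arr.ind = TRUE)
  if (nrow(bd)) rgb <- set_pixels(rgb, bd[, 1], bd[, 2], c(0.7, 0.7, 0.7))
  for (i in seq_len(nrow(labelmap$regions))) {
    r <- labelmap$regions[i, ]
    n <- counts$n[counts$region_id == r$id]
    if (!length(n)) n <- 0L
    rgb <- draw_number(rgb, n, round(r$centroid_y) - 5L, round(r$centroid_x) - 3L,
                       c(1, 1, 0.2), scale = 2L)
  }
  write_rgb_png(rgb, path)
}

render_filter_qc <- function(before_2d, after_2d, path) {
  norm <- function(m) if (max(m) > 0) m / max(m) else m
  sep <- matrix(0.5, nrow(before_2d), 2L)
  write_rgb_png(gray_to_rgb(cbind(norm(before_2d), sep, norm(after_2d))), path)
}

render_assignment <- function(exp, labelmap, assignments, path) {
  cols <- role_palette(exp$specs)
  d <- dim(exp$channels[[1]])[2:3]
  rgb <- blank_rgb(d[1], d[2])
  for (nm in channel_names(exp, "cell_marker")) {
    m <- max_project(exp$channels[[nm]])
    if (max(m) > 0) m <- m / max(m)
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] + m * cols[[nm]][ch]
  }
  rgb <- pmin(rgb, 1)
  bd <- which(region_boundaries(labelmap$labels), arr.ind = TRUE)
  if (nrow(bd)) rgb <- set_pixels(rgb, bd[, 1], bd[, 2], c(0.7, 0.7, 0.7))
  for (i in seq_len(nrow(labelmap$regions))) {
    r <- labelmap$regions[i, ]
    a <- assignments[assignments$nucleus_id == r$id, ]
    col <- c(1, 1, 1)
    if (nrow(a) && a$cell_type[1] != "unassigned") {
      first <- strsplit(a$cell_type[1], "+", fixed = TRUE)[[1]][1]
      col <- cols[[first]] %||% c(1, 1, 1)
    }
    rgb <- draw_number(rgb, r$id, round(r$centroid_y) - 5L, round(r$centroid_x) - 3L,
                       col, scale = 2L)
  }
  write_rgb_png(rgb, path)
}
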