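#' Nuclei segmentation parameters
#'
#' @param min_depth Minimum basin depth on the normalized intensity scale.
#'   Watershed basins whose depth (difference between the shallower peak and
#'   the brightest point of the shared boundary) is below `min_depth` are
#'   merged, suppressing over-segmentation.  Recommended around 1e-6 to 1e-7
#'   for preventing over-segmentation; deliberately higher values
#'   (5e-6 to 5e-5 for mammalian nuclei) split touching nuclei whose shared
#'   border is shallow, trading over-segmentation (fixable with
#'   [correct_segmentation()]) for under-segmentation (not fixable).
#' @param min_size Minimum region area in pixels; smaller regions (debris,
#'   pyknotic nuclei) are removed.
#' @param threshold_method `"otsu"` (default) or `"fixed"` foreground
#'   threshold on the smoothed projection.
#' @param fixed_threshold Foreground threshold in `[0, 1]` when
#'   `threshold_method = "fixed"`.
#' @param smoothing_sigma Gaussian smoothing of the projection before
#'   thresholding and watershed, pixels.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(min_depth = 1e-6, min_size = 20L,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5, smoothing_sigma = 2) {
  check_number(min_depth, "min_depth", lower = 0)
  check_number(min_size, "min_size", lower = 0)
  threshold_method <- match.arg(threshold_method)
  check_number(fixed_threshold, "fixed_threshold", lower = 0, upper = 1)
  check_number(smoothing_sigma, "smoothing_sigma", lower = 0)
  structure(list(min_depth = min_depth, min_size = as.integer(min_size),
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 smoothing_sigma = smoothing_sigma),
            class = "segmentation_params")
}

region_properties <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    return(tibble::tibble(id = integer(), area = integer(),
                          centroid_y = numeric(), centroid_x = numeric(),
                          ymin = integer(), ymax = integer(),
                          xmin = integer(), xmax = integer()))
  }
  px <- which(labels > 0L)
  ij <- arrayInd(px, dim(labels))
  lab <- labels[px]
  tibble::tibble(id = as.integer(lab), y = ij[, 1], x = ij[, 2]) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(area = dplyr::n(),
                     centroid_y = mean(.data$y), centroid_x = mean(.data$x),
                     ymin = min(.data$y), ymax = max(.data$y),
                     xmin = min(.data$x), xmax = max(.data$x),
                     .groups = "drop") |>
    dplyr::arrange(.data$id)
}

#' Construct a label map
#'
#' A 2-D integer label image (0 = background, k > 0 = region k) with a
#' per-region property table.  Labels are compacted to consecutive positive
#' integers.
#'
#' @param labels Integer matrix of labels.
#' @param compact Renumber labels consecutively (default `TRUE`).
#' @return A `fish_labelmap`: list with `labels` (matrix) and `regions`
#'   (tibble `id, area, centroid_y, centroid_x, ymin, ymax, xmin, xmax`).
#' @export
new_labelmap <- function(labels, compact = TRUE) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (compact) {
    ids <- sort(unique(labels[labels > 0L]))
    if (length(ids) && !identical(ids, seq_along(ids))) {
      remap <- integer(max(ids))
      remap[ids] <- seq_along(ids)
      labels[labels > 0L] <- remap[labels[labels > 0L]]
    }
  }
  structure(list(labels = labels, regions = region_properties(labels)),
            class = "fish_labelmap")
}

#' @export
print.fish_labelmap <- function(x, ...) {
  cat(sprintf("<fish_labelmap> %d x %d, %d regions\n",
              nrow(x$labels), ncol(x$labels), nrow(x$regions)))
  invisible(x)
}

n_regions <- function(lm) nrow(lm$regions)

#' Watershed basins of a 2-D surface
#'
#' Deterministic descending priority-flood from all regional maxima of the
#' surface within the foreground mask (bright-object orientation, 8-connected;
#' every masked pixel is assigned to exactly one basin).  `min_depth` control
#' is applied separately by [merge_shallow_basins()].
#'
#' @param surface Numeric matrix (e.g. smoothed nuclei projection).
#' @param mask Logical matrix of foreground pixels (default: everything).
#' @return A `fish_labelmap` of raw basins (not compacted relative to the
#'   flood order; labels are already consecutive).
#' @export
watershed_basins <- function(surface, mask = NULL) {
  stopifnot(is.matrix(surface))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(surface), ncol(surface))
  if (!identical(dim(surface), dim(mask))) abort("surface/mask shape mismatch")
  lab <- flood_watershed_cpp(surface, mask)
  new_labelmap(lab, compact = FALSE)
}

# basin adjacency edges: for every 8-neighbour pair straddling two labels,
# the contact level is min of the two surface values; per label pair keep the
# maximum contact level (the saddle through which the basins touch highest)
basin_edges <- function(labels, surface) {
  nr <- nrow(labels); nc <- ncol(labels)
  ea <- integer(); eb <- integer(); lev <- numeric()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    di <- s[1]; dj <- s[2]
    i1 <- seq_len(nr - abs(di))
    j1 <- if (dj >= 0L) seq_len(nc - dj) else seq(1L - dj, nc)
    i2 <- i1 + di; j2 <- j1 + dj
    a <- labels[i1, j1]; b <- labels[i2, j2]
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) next
    va <- surface[i1, j1]; vb <- surface[i2, j2]
    ea <- c(ea, pmin(a[sel], b[sel]))
    eb <- c(eb, pmax(a[sel], b[sel]))
    lev <- c(lev, pmin(va[sel], vb[sel]))
  }
  if (!length(ea)) return(NULL)
  key <- paste(ea, eb)
  agg <- tapply(lev, key, max)
  prs <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  list(a = as.integer(prs[, 1]), b = as.integer(prs[, 2]),
       level = as.numeric(agg))
}

#' Merge shallow watershed basins (minimum-depth control)
#'
#' Builds the basin adjacency graph and repeatedly merges the adjacent pair
#' with the smallest depth while that depth is below `min_depth`, recomputing
#' affected edges after every merge ("sequential combination").  The depth of
#' an adjacent pair is `min(peak_A, peak_B) - saddle(A, B)`, where the saddle
#' is the highest contact level along the shared boundary; this equals the
#' classical dynamics criterion, so the result matches a watershed of the
#' h-maxima-suppressed surface (see [hmaxima()]).  Ties are broken by the
#' smaller label pair; the final partition does not depend on the input label
#' numbering.
#'
#' @param labelmap A `fish_labelmap` from [watershed_basins()].
#' @param surface The surface the watershed ran on (same shape).
#' @param min_depth Depth threshold on the surface's intensity scale.
#' @return A merged, compacted `fish_labelmap`.
#' @export
merge_shallow_basins <- function(labelmap, surface, min_depth) {
  stopifnot(inherits(labelmap, "fish_labelmap"))
  L <- labelmap$labels
  if (!identical(dim(L), dim(surface))) abort("surface/labels shape mismatch")
  check_number(min_depth, "min_depth", lower = 0)
  nlab <- max(L, 0L)
  if (nlab <= 1L || min_depth == 0) return(new_labelmap(L))
  peak <- vapply(seq_len(nlab), function(k) max(surface[L == k]), 0)
  e <- basin_edges(L, surface)
  if (is.null(e)) return(new_labelmap(L))
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  repeat {
    ra <- vapply(e$a, find, 0L); rb <- vapply(e$b, find, 0L)
    keep <- ra != rb
    if (!any(keep)) break
    pa <- pmin(ra, rb)[keep]; pb <- pmax(ra, rb)[keep]; lv <- e$level[keep]
    key <- paste(pa, pb)
    agg <- tapply(lv, key, max)
    prs <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    ua <- as.integer(prs[, 1]); ub <- as.integer(prs[, 2])
    depth <- pmin(peak[ua], peak[ub]) - as.numeric(agg)
    ord <- order(depth, ua, ub)
    if (depth[ord[1]] >= min_depth) break
    i <- ord[1]
    lo <- min(ua[i], ub[i]); hi <- max(ua[i], ub[i])
    parent[hi] <- lo
    peak[lo] <- max(peak[lo], peak[hi])
  }
  roots <- vapply(seq_len(nlab), find, 0L)
  out <- L
  out[L > 0L] <- roots[L[L > 0L]]
  new_labelmap(out)
}

#' h-maxima transform
#'
#' Suppresses every regional maximum whose dynamics (height above the
#' highest saddle connecting it to a higher maximum) is below `h`, by
#' morphological reconstruction-by-dilation of `img - h` under `img`
#' (8-connected).  Watershed of the transformed surface is the classical
#' equivalent of depth-thresholded basin merging and serves as an
#' independent cross-check of [merge_shallow_basins()].
#'
#' @param img Numeric matrix.
#' @param h Suppression height.
#' @return The transformed matrix.
#' @export
hmaxima <- function(img, h) {
  stopifnot(is.matrix(img))
  check_number(h, "h", lower = 0)
  J <- img - h
  nr <- nrow(img); nc <- ncol(img)
  dilate8 <- function(M) {
    D <- M
    D[-1, ] <- pmax(D[-1, ], M[-nr, ])
    D[-nr, ] <- pmax(D[-nr, ], M[-1, ])
    E <- D
    E[, -1] <- pmax(E[, -1], D[, -nc])
    E[, -nc] <- pmax(E[, -nc], D[, -1])
    E
  }
  repeat {
    Jold <- J
    J <- pmin(dilate8(J), img)
    if (identical(J, Jold)) break
  }
  J
}

#' Remove regions smaller than a minimum size
#'
#' Regions with fewer than `min_size` pixels are set to background and the
#' remaining labels compacted.  Warns when nothing survives.
#'
#' @param labelmap A `fish_labelmap`.
#' @param min_size Minimum area, pixels.
#' @return A filtered `fish_labelmap`.
#' @export
filter_small_regions <- function(labelmap, min_size) {
  stopifnot(inherits(labelmap, "fish_labelmap"))
  if (min_size < 0) abort("`min_size` must be non-negative")
  if (min_size == 0 || !n_regions(labelmap)) return(labelmap)
  small <- labelmap$regions$id[labelmap$regions$area < min_size]
  L <- labelmap$labels
  if (length(small)) L[L %in% small] <- 0L
  out <- new_labelmap(L)
  if (!n_regions(out)) warn("no regions survive `min_size` filtering")
  out
}

#' Segment nuclei from a 2-D projection
#'
#' Pipeline: Gaussian smoothing, foreground threshold (Otsu or fixed),
#' watershed flood on the smoothed intensity restricted to foreground,
#' minimum-depth basin merging, minimum-size filtering, label compaction.
#'
#' @param nuclei_2d Normalized 2-D nuclei image (max projection of the
#'   normalized nuclei channel).
#' @param params A [segmentation_params()] object.
#' @return A `fish_labelmap`.
#' @export
segment_nuclei <- function(nuclei_2d, params = segmentation_params()) {
  stopifnot(is.matrix(nuclei_2d), inherits(params, "segmentation_params"))
  s <- nuclei_surface(nuclei_2d, params$smoothing_sigma)
  thr <- if (params$threshold_method == "otsu") {
    EBImage::otsu(EBImage::Image(s), range = range(0, max(s, 1e-12)))
  } else {
    params$fixed_threshold
  }
  fg <- s >= thr
  if (!any(fg)) {
    warn("empty foreground: no nuclei segmented")
    return(new_labelmap(matrix(0L, nrow(nuclei_2d), ncol(nuclei_2d))))
  }
  basins <- watershed_basins(s, fg)
  merged <- merge_shallow_basins(basins, s, params$min_depth)
  filter_small_regions(merged, params$min_size)
}

#' @rdname segment_nuclei
#' @details `nuclei_surface()` is the smoothed intensity surface the
#'   watershed runs on; `min_depth` values refer to this surface's scale.
#' @param smoothing_sigma Smoothing width in pixels.
#' @export
nuclei_surface <- function(nuclei_2d, smoothing_sigma = 2) {
  stopifnot(is.matrix(nuclei_2d))
  if (smoothing_sigma <= 0) return(nuclei_2d)
  gaussian_smooth(nuclei_2d, smoothing_sigma)
}

#' Declarative correction of a segmentation by region IDs
#'
#' Merges each set of region IDs into one region (the lowest ID wins) and
#' deletes listed regions, then compacts labels.  The applied edits are
#' returned in the `audit` attribute (and recorded in run metadata by
#' [run_pipeline()]).
#'
#' @param labelmap A `fish_labelmap`.
#' @param merges List of integer vectors of region IDs to merge.
#' @param deletions Integer vector of region IDs to delete.
#' @return Corrected `fish_labelmap` with an `audit` attribute.
#' @export
correct_segmentation <- function(labelmap, merges = list(), deletions = integer()) {
  stopifnot(inherits(labelmap, "fish_labelmap"))
  ids <- labelmap$regions$id
  referenced <- c(unlist(merges), deletions)
  unknown <- setdiff(referenced, ids)
  if (length(unknown)) {
    abort(sprintf("unknown region ID(s) %s; valid IDs: %s",
                  paste(unknown, collapse = ", "), paste(ids, collapse = ", ")))
  }
  if (length(intersect(unlist(merges), deletions))) {
    abort("a region ID appears in both a merge set and the deletions")
  }
  if (length(merges) > 1L && anyDuplicated(unlist(merges))) {
    abort("merge sets must be pairwise disjoint")
  }
  L <- labelmap$labels
  for (m in merges) {
    m <- sort(as.integer(m))
    if (length(m) > 1L) L[L %in% m] <- m[1]
  }
  if (length(deletions)) L[L %in% as.integer(deletions)] <- 0L
  out <- new_labelmap(L)
  attr(out, "audit") <- list(merges = lapply(merges, as.integer),
                             deletions = as.integer(deletions))
  out
}

#' Write a label map as 16-bit TIFF plus a regions CSV
#'
#' @param labelmap A `fish_labelmap`.
#' @param tiff_path Output TIFF path (single page, 16-bit labels).
#' @param csv_path Optional regions CSV path (`id, area, centroid_y,
#'   centroid_x`).
#' @return Invisibly, `tiff_path`.
#' @export
write_labelmap <- function(labelmap, tiff_path, csv_path = NULL) {
  stopifnot(inherits(labelmap, "fish_labelmap"))
  if (max(labelmap$labels) > 65535L) abort("more than 65535 labels")
  tiff::writeTIFF(labelmap$labels / 65535, tiff_path, bits.per.sample = 16L)
  if (!is.null(csv_path)) {
    readr::write_csv(labelmap$regions[c("id", "area", "centroid_y", "centroid_x")],
                     csv_path)
  }
  invisible(tiff_path)
}

#' Read a label map written by [write_labelmap()]
#'
#' @param tiff_path Path to the 16-bit label TIFF.
#' @return A `fish_labelmap`.
#' @export
read_labelmap <- function(tiff_path) {
  if (!file.exists(tiff_path)) abort(sprintf("label map not found: %s", tiff_path))
  m <- tiff::readTIFF(tiff_path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  new_labelmap(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)),
               compact = FALSE)
}

#' @describeIn segment_nuclei ggplot of a label map (regions coloured, IDs at
#'   centroids).
#' @param object A `fish_labelmap`.
#' @param ... Ignored.
#' @export
autoplot.fish_labelmap <- function(object, ...) {
  L <- object$labels
  df <- tidyr::expand_grid(y = seq_len(nrow(L)), x = seq_len(ncol(L)))
  df$label <- factor(L[cbind(df$y, df$x)])
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(.data$x, .data$y, fill = .data$label),
                         show.legend = FALSE) +
    ggplot2::geom_text(data = object$regions,
                       ggplot2::aes(.data$centroid_x, .data$centroid_y,
                                    label = .data$id), colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
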