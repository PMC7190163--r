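#' Cell-type assignment parameters
#'
#' @param marker_threshold Named numeric vector (or single number applied to
#'   every marker): intensity threshold in `[0, 1]` above which a smoothed
#'   marker projection is considered positive.
#' @param min_overlap_fraction Fraction of a nucleus' area that must fall
#'   inside a marker-positive region for the nucleus to be called positive
#'   for that marker; default 0.5 (majority overlap).
#' @param mode `"nascent"` (transcripts counted inside nucleus masks;
#'   intronic probes give nuclear signal) or `"mature"` (counted inside
#'   expanded cell territories; processed mRNA fills the cytoplasm).
#' @param smoothing_sigma Smoothing applied to marker projections before
#'   thresholding, pixels.
#' @param min_region_size Marker-positive components smaller than this are
#'   discarded, pixels.
#' @return An `assignment_params` list.
#' @export
assignment_params <- function(marker_threshold = 0.3, min_overlap_fraction = 0.5,
                              mode = c("nascent", "mature"),
                              smoothing_sigma = 2, min_region_size = 20L) {
  if (!is.numeric(marker_threshold) ||
      any(marker_threshold < 0 | marker_threshold > 1)) {
    abort("`marker_threshold` values must lie in [0, 1]")
  }
  check_number(min_overlap_fraction, "min_overlap_fraction", lower = 0, upper = 1)
  mode <- match.arg(mode)
  check_number(smoothing_sigma, "smoothing_sigma", lower = 0)
  check_number(min_region_size, "min_region_size", lower = 0)
  structure(list(marker_threshold = marker_threshold,
                 min_overlap_fraction = min_overlap_fraction, mode = mode,
                 smoothing_sigma = smoothing_sigma,
                 min_region_size = as.integer(min_region_size)),
            class = "assignment_params")
}

marker_threshold_for <- function(params, channel) {
  th <- params$marker_threshold
  if (!is.null(names(th)) && channel %in% names(th)) return(unname(th[channel]))
  unname(th[1])
}

#' Threshold a marker channel into a positive-region mask
#'
#' The smoothed 2-D marker projection is thresholded at `threshold`;
#' connected components smaller than `min_size` pixels are removed.
#'
#' @param marker_2d Normalized 2-D marker image (max projection).
#' @param threshold Intensity threshold in `[0, 1]`.
#' @param min_size Minimum component size, pixels.
#' @param smoothing_sigma Pre-threshold smoothing, pixels.
#' @return Logical matrix mask.
#' @export
detect_positive_regions <- function(marker_2d, threshold, min_size = 20L,
                                    smoothing_sigma = 2) {
  stopifnot(is.matrix(marker_2d))
  check_number(threshold, "threshold", lower = 0, upper = 1)
  s <- if (smoothing_sigma > 0) gaussian_smooth(marker_2d, smoothing_sigma) else marker_2d
  mask <- s >= threshold
  if (min_size > 0 && any(mask)) {
    cc <- EBImage::bwlabel(EBImage::Image(mask * 1))
    cc <- matrix(as.integer(cc), nrow(mask), ncol(mask))
    sizes <- tabulate(cc[cc > 0L])
    drop <- which(sizes < min_size)
    if (length(drop)) mask[cc %in% drop] <- FALSE
  }
  mask
}

#' Assign nuclei to marker-positive cell types
#'
#' For every nucleus and marker, the overlap fraction is the share of the
#' nucleus' pixels inside the marker mask; the nucleus is positive for the
#' marker when the fraction reaches `min_overlap_fraction`.  Nuclei positive
#' for several markers are reported as such (`multi = TRUE`), nuclei positive
#' for none are retained as `"unassigned"`.
#'
#' @param nuclei A `fish_labelmap` of nuclei.
#' @param masks Named list of logical marker masks
#'   (see [detect_positive_regions()]).
#' @param params An [assignment_params()] object.
#' @return A tibble with one row per nucleus: `nucleus_id`, one
#'   `frac_<marker>` and `pos_<marker>` column pair per marker, `cell_type`
#'   (positive markers joined with `"+"`, or `"unassigned"`), and `multi`.
#' @export
assign_nuclei <- function(nuclei, masks, params = assignment_params()) {
  stopifnot(inherits(nuclei, "fish_labelmap"))
  L <- nuclei$labels
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dim(L))) {
      abort(sprintf("marker mask %s does not match the label map shape", nm))
    }
  }
  ids <- nuclei$regions$id
  out <- tibble::tibble(nucleus_id = ids)
  fg <- L > 0L
  lab_fg <- L[fg]
  area <- tabulate(lab_fg, nbins = max(ids, 0L))
  pos_mat <- matrix(FALSE, length(ids), length(masks),
                    dimnames = list(NULL, names(masks)))
  for (nm in names(masks)) {
    inside <- tabulate(lab_fg[masks[[nm]][fg]], nbins = max(ids, 0L))
    frac <- ifelse(area[ids] > 0, inside[ids] / area[ids], 0)
    out[[paste0("frac_", nm)]] <- frac
    pos <- frac >= params$min_overlap_fraction
    out[[paste0("pos_", nm)]] <- pos
    pos_mat[, nm] <- pos
  }
  out$cell_type <- vapply(seq_along(ids), function(i) {
    p <- names(masks)[pos_mat[i, ]]
    if (!length(p)) "unassigned" else paste(p, collapse = "+")
  }, character(1))
  out$multi <- rowSums(pos_mat) > 1L
  out
}

#' Count spots per segmented region
#'
#' Each spot's `(y, x)` centre (z is collapsed because segmentation is 2-D)
#' is looked up in the label map; `region_id` 0 means background.  Background
#' spots are reported, never dropped: the counts always satisfy
#' `sum(per-region) + background = total`.
#'
#' @param spots A `fish_spots` tibble.
#' @param labelmap A `fish_labelmap` (nuclei or territories).
#' @return List with `spots` (the table with `region_id` filled) and
#'   `counts` (tibble `region_id, n`, one row per region plus
#'   `region_id = 0` for background).
#' @export
count_spots_per_region <- function(spots, labelmap) {
  stopifnot(inherits(labelmap, "fish_labelmap"))
  L <- labelmap$labels
  ids <- labelmap$regions$id
  if (nrow(spots)) {
    yi <- as.integer(round(spots$y)); xi <- as.integer(round(spots$x))
    if (any(yi < 1L | yi > nrow(L) | xi < 1L | xi > ncol(L))) {
      abort("spot coordinates fall outside the image")
    }
    spots$region_id <- L[cbind(yi, xi)]
  }
  counts <- tibble::tibble(region_id = c(0L, ids),
                           n = vapply(c(0L, ids),
                                      function(k) sum(spots$region_id == k),
                                      integer(1)))
  list(spots = spots, counts = counts)
}

#' Expand nuclei into cell territories (mature-mRNA mode)
#'
#' Grows each nucleus into the marker-positive mask by multi-source
#' breadth-first propagation (geodesic nearest-nucleus partition inside the
#' mask, 4-connected; ties go to the smaller nucleus ID).  Mask pixels not
#' reachable from any nucleus stay unowned; a nucleus outside every mask
#' component keeps its own pixels as its territory.  Territories are
#' pairwise disjoint and each contains its nucleus.
#'
#' @param nuclei A `fish_labelmap` of nuclei.
#' @param marker_mask Logical matrix from [detect_positive_regions()].
#' @return A `fish_labelmap` of territories (same IDs as the nuclei).
#' @export
expand_cell_territories <- function(nuclei, marker_mask) {
  stopifnot(inherits(nuclei, "fish_labelmap"))
  L <- nuclei$labels
  if (!identical(dim(L), dim(marker_mask))) abort("mask/labels shape mismatch")
  if (!n_regions(nuclei)) {
    warn("no nuclei to expand")
    return(nuclei)
  }
  if (!any(marker_mask & L > 0L)) {
    warn("no nucleus overlaps the marker mask; territories equal nucleus masks")
  }
  terr <- L
  allowed <- marker_mask | L > 0L
  nr <- nrow(L); nc <- ncol(L)
  shift <- function(M, di, dj, fill) {
    out <- matrix(fill, nr, nc)
    i_src <- max(1L, 1L - di):min(nr, nr - di)
    j_src <- max(1L, 1L - dj):min(nc, nc - dj)
    out[i_src + di, j_src + dj] <- M[i_src, j_src]
    out
  }
  repeat {
    cand <- pmin(ifelse(shift(terr, 1L, 0L, 0L) > 0L, shift(terr, 1L, 0L, 0L), Inf),
                 ifelse(shift(terr, -1L, 0L, 0L) > 0L, shift(terr, -1L, 0L, 0L), Inf),
                 ifelse(shift(terr, 0L, 1L, 0L) > 0L, shift(terr, 0L, 1L, 0L), Inf),
                 ifelse(shift(terr, 0L, -1L, 0L) > 0L, shift(terr, 0L, -1L, 0L), Inf))
    new <- allowed & terr == 0L & is.finite(cand)
    if (!any(new)) break
    terr[new] <- as.integer(cand[new])
  }
  new_labelmap(terr, compact = FALSE)
}
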