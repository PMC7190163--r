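#' Construct a channel volume
#'
#' A volume is a plain 3-D numeric array in `(z, y, x)` order carrying its
#' voxel size and channel name as attributes.  Indices are 1-based, with
#' integer coordinates at pixel centres.
#'
#' @param data Numeric 3-D array `(z, y, x)`; a matrix is promoted to `z = 1`.
#' @param voxel_size Numeric length-3 `(dz, dy, dx)` in micrometres.
#'   Voxel sizes are metadata only; all pipeline distances are in voxels.
#' @param channel Channel name.
#' @return A numeric array of class `fish_volume`.
#' @export
new_volume <- function(data, voxel_size = c(0.4, 0.285, 0.285), channel = NA_character_) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array in (z, y, x) order")
  }
  if (any(!is.finite(data))) abort("volume contains non-finite values")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(data,
            voxel_size = as.numeric(voxel_size),
            channel = channel,
            class = c("fish_volume", "array"))
}

as_volume <- function(x, template = NULL) {
  if (inherits(x, "fish_volume")) return(x)
  new_volume(x,
             voxel_size = attr(template, "voxel_size") %||% c(0.4, 0.285, 0.285),
             channel = attr(template, "channel") %||% NA_character_)
}

# rebuild a volume with new data but the same metadata
volume_like <- function(data, template) {
  structure(data,
            voxel_size = attr(template, "voxel_size"),
            channel = attr(template, "channel"),
            class = c("fish_volume", "array"))
}

#' @export
print.fish_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fish_volume> channel %s, %d x %d x %d (z,y,x), range [%.4g, %.4g]\n",
              attr(x, "channel"), d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

validate_specs <- function(specs) {
  specs <- tibble::as_tibble(specs)
  needed <- c("name", "role")
  if (!all(needed %in% names(specs))) {
    abort("channel manifest needs `name` and `role` for every channel")
  }
  roles <- c("transcript", "nuclei", "cell_marker")
  bad <- setdiff(specs$role, roles)
  if (length(bad)) {
    abort(sprintf("unknown channel role(s): %s (must be one of %s)",
                  paste(bad, collapse = ", "), paste(roles, collapse = ", ")))
  }
  if (anyDuplicated(specs$name)) abort("channel names must be unique")
  n_nuc <- sum(specs$role == "nuclei")
  if (n_nuc != 1L) {
    abort(sprintf("manifest must declare exactly one nuclei channel (found %d)", n_nuc))
  }
  if (!any(specs$role == "transcript")) {
    abort("manifest must declare at least one transcript channel")
  }
  specs
}

#' Construct an experiment from in-memory volumes
#'
#' An experiment is one field of view: a named set of channel volumes plus a
#' manifest row per channel giving its role (`transcript`, `nuclei` or
#' `cell_marker`).  Exactly one nuclei channel and at least one transcript
#' channel are required; all channels must share the same `(y, x)` extent.
#'
#' @param id Sample identifier.
#' @param channels Named list of volumes (3-D arrays, `(z, y, x)`).
#' @param specs Data frame with columns `name`, `role` (one row per channel).
#' @param voxel_size `(dz, dy, dx)` in micrometres, applied to channels
#'   lacking their own.
#' @return A `fish_experiment`.
#' @export
new_experiment <- function(id, channels, specs,
                           voxel_size = c(0.4, 0.285, 0.285)) {
  specs <- validate_specs(specs)
  if (!setequal(names(channels), specs$name)) {
    abort("channel list and manifest name different channels")
  }
  channels <- channels[specs$name]
  channels <- lapply(seq_along(channels), function(i) {
    v <- channels[[i]]
    if (!inherits(v, "fish_volume")) v <- new_volume(v, voxel_size, specs$name[i])
    attr(v, "channel") <- specs$name[i]
    v
  })
  names(channels) <- specs$name
  yx <- t(vapply(channels, function(v) dim(v)[2:3], integer(2)))
  if (nrow(unique(yx)) != 1L) {
    first <- specs$name[1]
    other <- specs$name[which(yx[, 1] != yx[1, 1] | yx[, 2] != yx[1, 2])[1]]
    abort(sprintf("channels %s and %s have different (y, x) shapes", first, other))
  }
  structure(list(id = id, channels = channels, specs = specs,
                 voxel_size = as.numeric(voxel_size)),
            class = "fish_experiment")
}

#' @export
print.fish_experiment <- function(x, ...) {
  cat(sprintf("<fish_experiment> %s: %d channels\n", x$id, length(x$channels)))
  for (i in seq_len(nrow(x$specs))) {
    d <- dim(x$channels[[x$specs$name[i]]])
    cat(sprintf("  %-12s %-11s %d x %d x %d\n", x$specs$name[i], x$specs$role[i],
                d[1], d[2], d[3]))
  }
  invisible(x)
}

channel_names <- function(exp, role) exp$specs$name[exp$specs$role == role]

read_tiff_stack <- function(path, pages = NULL) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  bits <- info$bits.per.sample[1]
  sl <- tiff::readTIFF(path, all = TRUE)
  # 8/16-bit TIFFs hold integer counts that readTIFF rescales to [0,1];
  # undo that so raw intensities survive until normalize.  32-bit pages are
  # floating point and come through exactly.
  if (!is.na(bits) && bits <= 16L) {
    sl <- if (is.list(sl)) {
      lapply(sl, function(m) round(m * (2^bits - 1)))
    } else {
      round(sl * (2^bits - 1))
    }
  }
  if (!is.list(sl)) sl <- list(sl)
  if (!is.null(pages)) {
    if (any(pages < 1L) || any(pages > length(sl))) {
      abort(sprintf("page range [%s] outside 1..%d in %s",
                    paste(range(pages), collapse = ", "), length(sl), path))
    }
    sl <- sl[pages]
  }
  sl <- lapply(sl, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
  arr <- array(0, dim = c(length(sl), nrow(sl[[1]]), ncol(sl[[1]])))
  for (i in seq_along(sl)) arr[i, , ] <- sl[[i]]
  arr
}

#' Load an experiment from TIFF files and a channel manifest
#'
#' The manifest is a YAML (or JSON) file, or an equivalent list, with
#' top-level `voxel_size`, optional `id`, optional `axes` (page interleave for
#' a shared multi-page stack, `"zcyx"` default or `"czyx"`) and a `channels`
#' sequence.  Each channel entry has `name`, `role` and either its own `path`
#' (optionally with a `pages: [from, to]` range) or, when a top-level `path`
#' is given, its pages are inferred from the interleave order.
#'
#' Raw integer intensities are preserved as read; call
#' [normalize_experiment()] before filtering.
#'
#' @param manifest Path to a manifest file, or a list with the same structure.
#' @param dir Directory that relative channel paths are resolved against.
#' @return A `fish_experiment`.
#' @examples
#' \dontrun{
#' exp <- load_experiment("manifest.yaml", dir = "images/")
#' }
#' @export
load_experiment <- function(manifest, dir = ".") {
  m <- if (is.character(manifest)) {
    if (!file.exists(manifest)) abort(sprintf("manifest not found: %s", manifest))
    yaml::read_yaml(manifest)
  } else manifest
  if (is.null(m$channels)) abort("manifest has no `channels` section")
  specs <- dplyr::bind_rows(lapply(m$channels, function(ch) {
    tibble::tibble(name = ch$name %||% NA_character_,
                   role = ch$role %||% NA_character_,
                   path = ch$path %||% m$path %||% NA_character_)
  }))
  specs_chk <- validate_specs(specs[c("name", "role")])
  voxel_size <- as.numeric(m$voxel_size %||% c(0.4, 0.285, 0.285))
  axes <- tolower(m$axes %||% "zcyx")
  nchan <- length(m$channels)

  shared <- !is.null(m$path)
  shared_pages <- NULL
  if (shared) {
    p <- file.path(dir, m$path)
    if (!file.exists(p)) abort(sprintf("image file not found: %s", p))
    n_pages <- length(tiff::readTIFF(p, all = TRUE, payload = FALSE))
    if (n_pages %% nchan != 0L) {
      abort(sprintf("%d pages in %s not divisible by %d channels", n_pages, p, nchan))
    }
    nz <- n_pages %/% nchan
    shared_pages <- lapply(seq_len(nchan), function(i) {
      if (axes == "zcyx") seq(i, by = nchan, length.out = nz)
      else if (axes == "czyx") seq((i - 1L) * nz + 1L, length.out = nz)
      else abort(sprintf("unknown axes order '%s' (use zcyx or czyx)", axes))
    })
  }

  channels <- lapply(seq_len(nchan), function(i) {
    ch <- m$channels[[i]]
    if (!is.null(ch$path)) {
      pages <- if (!is.null(ch$pages)) seq(ch$pages[[1]], ch$pages[[2]]) else NULL
      arr <- read_tiff_stack(file.path(dir, ch$path), pages)
    } else if (shared) {
      arr <- read_tiff_stack(file.path(dir, m$path), shared_pages[[i]])
    } else {
      abort(sprintf("channel %s has no `path` and the manifest has no shared `path`", ch$name))
    }
    new_volume(arr, voxel_size, ch$name)
  })
  names(channels) <- specs_chk$name
  new_experiment(m$id %||% tools::file_path_sans_ext(basename(
                   if (is.character(manifest)) manifest else "experiment")),
                 channels, specs_chk, voxel_size)
}

#' Write an experiment's channels as multi-page TIFF files
#'
#' One 32-bit float multi-page TIFF per channel (page = z slice), named
#' `<id>_<channel>.tif`.  Reloading with [load_experiment()] reproduces the
#' arrays exactly.
#'
#' @param exp A `fish_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(exp$specs$name, function(nm) {
    v <- exp$channels[[nm]]
    pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
    path <- file.path(dir, sprintf("%s_%s.tif", exp$id, nm))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    path
  }, character(1))
  invisible(paths)
}

#' Min-max normalize a volume to the unit interval
#'
#' Linear per-channel rescaling `(x - min) / (max - min)`.  A constant
#' channel maps to all zeros.  This fixes the intensity scale that the
#' detection (`min_mass`) and segmentation (`min_depth`) thresholds are
#' quoted on.
#'
#' @param v A volume (3-D array).
#' @return The rescaled volume; idempotent.
#' @export
normalize_volume <- function(v) {
  v <- as_volume(v)
  if (length(v) == 0L || all(is.na(v))) abort("cannot normalize an empty volume")
  lo <- min(v); hi <- max(v)
  out <- if (hi > lo) (v - lo) / (hi - lo) else array(0, dim(v))
  volume_like(out, v)
}

#' @rdname normalize_volume
#' @param exp A `fish_experiment`.
#' @export
normalize_experiment <- function(exp) {
  exp$channels <- lapply(exp$channels, normalize_volume)
  exp
}

#' Maximum-intensity projection along z
#'
#' @param v A volume `(z, y, x)`.
#' @return A `(y, x)` matrix of per-pixel maxima over z.
#' @export
max_project <- function(v) {
  if (is.matrix(v)) return(v)
  stopifnot(length(dim(v)) == 3L)
  slices <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  m <- Reduce(pmax, slices)
  dim(m) <- dim(v)[2:3]
  m
}
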