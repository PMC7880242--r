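#' Physical metadata for a volumetric time-lapse acquisition
#'
#' Captures the voxel geometry and temporal sampling shared by every channel
#' of a co-registered multiphoton series. Axial step and frame interval
#' default to the acquisition geometry typical of intravital volumetric
#' mosaics (5 um axial step, 5 min between volumes); the lateral pixel size
#' depends on the scan optics and must always be supplied.
#'
#' @param voxel_size_xy Lateral pixel size in um/pixel (strictly positive).
#' @param voxel_size_z Axial slice spacing in um/slice. Default 5.
#' @param frame_interval Minutes between consecutive time points. Default 5.
#' @param channels Character vector of channel identifiers, e.g.
#'   `c("TPF", "SHG")`.
#' @return An object of class `volume_metadata`.
#' @export
volume_metadata <- function(voxel_size_xy, voxel_size_z = 5,
                            frame_interval = 5, channels = character()) {
  stopifnot(is.numeric(voxel_size_xy), length(voxel_size_xy) == 1L,
            is.finite(voxel_size_xy), voxel_size_xy > 0,
            is.numeric(voxel_size_z), is.finite(voxel_size_z),
            voxel_size_z > 0,
            is.numeric(frame_interval), is.finite(frame_interval),
            frame_interval > 0)
  structure(
    list(voxel_size_xy = as.numeric(voxel_size_xy),
         voxel_size_z = as.numeric(voxel_size_z),
         frame_interval = as.numeric(frame_interval),
         channels = as.character(channels)),
    class = "volume_metadata")
}

#' @export
print.volume_metadata <- function(x, ...) {
  cat(sprintf(
    "volume_metadata: %.4g um/px lateral, %.4g um/slice axial, %.4g min/frame\n",
    x$voxel_size_xy, x$voxel_size_z, x$frame_interval))
  if (length(x$channels))
    cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Co-registered multichannel volumetric time series
#'
#' Bundles one 4D array per channel, all indexed `[t, z, y, x]`, with shared
#' physical metadata. Identical shape across channels is the co-registration
#' contract that every downstream cross-modality analysis relies on: a pixel
#' coordinate means the same physical location in every channel.
#'
#' @param channels Named list of 4D numeric arrays, each with dimensions
#'   (t, z, y, x). All arrays must share one shape and be non-negative.
#' @param metadata A [volume_metadata()] object.
#' @return An object of class `volume_series` with elements `channels`,
#'   `metadata` and `dim` (the common (t, z, y, x) shape).
#' @export
volume_series <- function(channels, metadata) {
  if (!inherits(metadata, "volume_metadata"))
    stop("`metadata` must be a volume_metadata object")
  if (!is.list(channels) || length(channels) == 0L)
    stop("`channels` must be a non-empty named list of 4D arrays")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named")
  dims <- lapply(channels, function(a) {
    if (!is.array(a) || length(dim(a)) != 4L)
      stop("each channel must be a 4D (t, z, y, x) array")
    dim(a)
  })
  ref <- dims[[1L]]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], ref))
      stop(sprintf(
        "co-registration error: channel '%s' has shape (%s) but '%s' has (%s)",
        names(channels)[i], paste(dims[[i]], collapse = ","),
        names(channels)[1L], paste(ref, collapse = ",")))
  }
  if (ref[1L] < 1L || ref[2L] < 1L)
    stop("series needs at least one time point and one slice")
  for (nm in names(channels)) {
    if (anyNA(channels[[nm]]) || min(channels[[nm]]) < 0)
      stop(sprintf("channel '%s' contains NA or negative intensities", nm))
  }
  metadata$channels <- names(channels)
  structure(list(channels = channels, metadata = metadata,
                 dim = as.integer(ref)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("volume_series: %d channel(s) [%s], shape (t=%d, z=%d, y=%d, x=%d)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$dim[1], x$dim[2], x$dim[3], x$dim[4]))
  print(x$metadata)
  invisible(x)
}

#' Single-depth FLIM image pair
#'
#' A fluorescence-lifetime acquisition at one depth: a photon-count intensity
#' image and the per-pixel mean lifetime in nanoseconds on the same grid.
#' Lifetimes are only meaningful where photons were collected, so lifetime
#' values at zero-intensity pixels are tolerated but treated as masked by all
#' statistics.
#'
#' @param intensity Numeric matrix (y, x) of non-negative intensities.
#' @param lifetime Numeric matrix (y, x) of lifetimes in ns, same shape.
#' @param pixel_size Lateral pixel size in um/pixel.
#' @return An object of class `flim_image`.
#' @export
flim_image <- function(intensity, lifetime, pixel_size = 1) {
  stopifnot(is.matrix(intensity), is.matrix(lifetime))
  if (!identical(dim(intensity), dim(lifetime)))
    stop("intensity and lifetime images must have identical shapes")
  if (anyNA(intensity) || min(intensity) < 0)
    stop("intensity must be finite and non-negative")
  lit <- intensity > 0
  if (any(!is.finite(lifetime[lit])) || any(lifetime[lit] < 0))
    stop("lifetime must be finite and >= 0 wherever intensity > 0")
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(intensity = intensity, lifetime = lifetime,
                 pixel_size = as.numeric(pixel_size)),
            class = "flim_image")
}

#' Rectangular region of interest
#'
#' An axis-aligned lateral crop window stored as 1-based inclusive pixel
#' bounds (R indexing convention). A single `roi_spec` is the contract that
#' ties analyses together across modalities: the window recorded when cells
#' are cropped for tracking is re-applied index-exactly to the SHG and FLIM
#' channels of the same lateral frame.
#'
#' @param x_min,x_max,y_min,y_max Integer pixel bounds, 1-based, inclusive;
#'   `x` indexes columns, `y` rows. Must satisfy `x_min <= x_max`,
#'   `y_min <= y_max`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x_min, x_max, y_min, y_max) {
  v <- c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
  if (any(v != round(v)) || any(v < 1))
    stop("roi bounds must be positive integers (1-based, inclusive)")
  if (x_min > x_max || y_min > y_max)
    stop("roi requires x_min <= x_max and y_min <= y_max")
  v <- as.integer(v)
  names(v) <- c("x_min", "x_max", "y_min", "y_max")
  structure(as.list(v), class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("roi_spec: x [%d, %d], y [%d, %d] (1-based, inclusive)\n",
              x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

roi_check_bounds <- function(roi, ny, nx) {
  if (roi$x_max > nx || roi$y_max > ny)
    stop(sprintf(
      "roi out of bounds: x up to %d, y up to %d on a %d x %d (y, x) image",
      roi$x_max, roi$y_max, ny, nx))
  invisible(TRUE)
}

#' Apply a stored region of interest across modalities
#'
#' Crops the lateral (y, x) extent of a [volume_series()], a single matrix, or
#' a [flim_image()] with the same `roi_spec`, guaranteeing pixel-identical
#' bounds in every channel. Cropping is index-exact: re-applying a stored ROI
#' to the same parent always yields the same array.
#'
#' @param x A `volume_series`, `flim_image`, or numeric matrix.
#' @param roi A [roi_spec()].
#' @return The cropped object, same class as `x`, with the applied ROI
#'   attached as attribute `"roi"`.
#' @export
apply_roi <- function(x, roi) {
  if (!inherits(roi, "roi_spec")) stop("`roi` must be a roi_spec")
  ys <- roi$y_min:roi$y_max
  xs <- roi$x_min:roi$x_max
  out <- if (inherits(x, "volume_series")) {
    roi_check_bounds(roi, x$dim[3], x$dim[4])
    ch <- lapply(x$channels, function(a) a[, , ys, xs, drop = FALSE])
    volume_series(ch, x$metadata)
  } else if (inherits(x, "flim_image")) {
    roi_check_bounds(roi, nrow(x$intensity), ncol(x$intensity))
    flim_image(x$intensity[ys, xs, drop = FALSE],
               x$lifetime[ys, xs, drop = FALSE], x$pixel_size)
  } else if (is.matrix(x)) {
    roi_check_bounds(roi, nrow(x), ncol(x))
    x[ys, xs, drop = FALSE]
  } else {
    stop("`x` must be a volume_series, flim_image, or matrix")
  }
  attr(out, "roi") <- roi
  out
}

# scale to [0,1] for 16-bit TIFF storage; power-of-two scale keeps the
# transform exact in binary floating point
tiff_scale_for <- function(mx) {
  if (!is.finite(mx) || mx <= 1) 1 else 2^ceiling(log2(mx))
}

# snap values onto the 16-bit storage grid (scale * k / 65535), the sample
# format of the TIFF stacks (and of real multiphoton acquisitions, whose
# digitizers are 12-16 bit). Synthetic generators pass their output through
# this so that writing and re-reading a fixture is bit-exact.
quantize_storage <- function(x, scale = tiff_scale_for(max(x))) {
  round(x / scale * 65535) / 65535 * scale
}

write_stack_pages <- function(pages, path, scale) {
  pages <- lapply(pages, function(p) p / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
}

#' Write a multichannel series as per-channel TIFF stacks
#'
#' One multi-page 16-bit TIFF per channel, pages ordered t-major then z
#' (all slices of t = 1, then t = 2, ...). Values are divided by a
#' power-of-two scale chosen per channel so they fit the [0, 1] storage
#' range; the scale, stack shape and physical metadata are written to a JSON
#' sidecar so [read_volume_series()] can reverse the transform. Data already
#' on the 16-bit grid (all generator output) round-trips bit-exactly.
#'
#' @param series A [volume_series()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix, default `"series"`.
#' @return Invisibly, a named character vector of written channel paths.
#' @export
write_volume_series <- function(series, dir, prefix = "series") {
  stopifnot(inherits(series, "volume_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- series$dim
  paths <- character(0)
  scales <- list()
  for (nm in names(series$channels)) {
    a <- series$channels[[nm]]
    scale <- tiff_scale_for(max(a))
    pages <- vector("list", d[1] * d[2])
    k <- 1L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
      pages[[k]] <- a[t, z, , ]
      k <- k + 1L
    }
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    write_stack_pages(pages, p, scale)
    paths[nm] <- p
    scales[[nm]] <- scale
  }
  meta <- list(
    shape = list(t = d[1], z = d[2], y = d[3], x = d[4]),
    voxel_size_xy = series$metadata$voxel_size_xy,
    voxel_size_z = series$metadata$voxel_size_z,
    frame_interval = series$metadata$frame_interval,
    channels = as.list(paths), scales = scales)
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_meta.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a multichannel series from per-channel TIFF stacks
#'
#' The inverse of [write_volume_series()]. Either point `paths` at the
#' per-channel TIFF files and supply `metadata` plus the (t, z) page layout,
#' or point `meta_json` at a sidecar written by [write_volume_series()], which
#' carries all of that.
#'
#' @param paths Named character vector, channel name to TIFF path.
#' @param metadata A [volume_metadata()].
#' @param n_time,n_z Page layout: pages must number `n_time * n_z`, t-major.
#' @param meta_json Path to a `*_meta.json` sidecar; overrides the other
#'   arguments.
#' @param scales Optional named list of per-channel intensity scales (values
#'   on disk are multiplied by these); defaults to 1.
#' @return A [volume_series()].
#' @export
read_volume_series <- function(paths = NULL, metadata = NULL, n_time = NULL,
                               n_z = NULL, meta_json = NULL, scales = NULL) {
  if (!is.null(meta_json)) {
    if (!file.exists(meta_json))
      stop(sprintf("series sidecar '%s' not found", meta_json))
    meta <- jsonlite::read_json(meta_json, simplifyVector = TRUE)
    paths <- unlist(meta$channels)
    # sidecar paths are relative to its own directory when not absolute
    rel <- !file.exists(paths)
    paths[rel] <- file.path(dirname(meta_json), basename(paths[rel]))
    names(paths) <- names(meta$channels)
    metadata <- volume_metadata(meta$voxel_size_xy, meta$voxel_size_z,
                                meta$frame_interval, names(paths))
    n_time <- meta$shape$t
    n_z <- meta$shape$z
    scales <- meta$scales
  }
  stopifnot(!is.null(paths), !is.null(metadata), !is.null(n_time),
            !is.null(n_z))
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("`paths` must be named by channel")
  channels <- list()
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]]))
      stop(sprintf("cannot read channel '%s': file '%s' not found",
                   nm, paths[[nm]]))
    pages <- tiff::readTIFF(paths[[nm]], all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != n_time * n_z)
      stop(sprintf("channel '%s': %d pages but expected t*z = %d",
                   nm, length(pages), n_time * n_z))
    sc <- if (!is.null(scales) && !is.null(scales[[nm]])) scales[[nm]] else 1
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    a <- array(0, c(n_time, n_z, ny, nx))
    k <- 1L
    for (t in seq_len(n_time)) for (z in seq_len(n_z)) {
      a[t, z, , ] <- pages[[k]] * sc
      k <- k + 1L
    }
    channels[[nm]] <- a
  }
  volume_series(channels, metadata)
}

#' Assemble single-position volumes into a grid mosaic
#'
#' Places tiles acquired on a regular stage grid onto one canvas at offsets of
#' `step_um` per grid position, emulating volumetric mosaic acquisition. No
#' registration or blending is performed: when the step is smaller than the
#' tile, later tiles (row-major order) overwrite the overlap.
#'
#' @param tiles List of 4D (t, z, y, x) arrays, row-major grid order, all the
#'   same shape.
#' @param grid_dim Integer vector `c(rows, cols)`.
#' @param step_um Lateral stage step in um; must convert to a whole number of
#'   pixels via `metadata$voxel_size_xy`.
#' @param metadata A [volume_metadata()].
#' @param channel Name for the single output channel, default `"mosaic"`.
#' @return A [volume_series()] spanning the grid extent.
#' @export
assemble_mosaic <- function(tiles, grid_dim, step_um, metadata,
                            channel = "mosaic") {
  stopifnot(is.list(tiles), length(grid_dim) == 2L,
            inherits(metadata, "volume_metadata"))
  grid_dim <- as.integer(grid_dim)
  if (length(tiles) != prod(grid_dim))
    stop("number of tiles must equal prod(grid_dim)")
  d <- dim(tiles[[1]])
  if (length(d) != 4L) stop("tiles must be 4D (t, z, y, x) arrays")
  for (tl in tiles) if (!identical(dim(tl), d)) stop("all tiles must share one shape")
  step_px <- step_um / metadata$voxel_size_xy
  if (abs(step_px - round(step_px)) > 1e-9)
    stop(sprintf(paste0(
      "mosaic step of %g um is %.6g pixels at %g um/px; resample the tiles ",
      "or fix voxel_size_xy so the step is a whole pixel count"),
      step_um, step_px, metadata$voxel_size_xy))
  step_px <- as.integer(round(step_px))
  ny <- (grid_dim[1] - 1L) * step_px + d[3]
  nx <- (grid_dim[2] - 1L) * step_px + d[4]
  canvas <- array(0, c(d[1], d[2], ny, nx))
  k <- 1L
  for (r in seq_len(grid_dim[1])) for (cc in seq_len(grid_dim[2])) {
    y0 <- (r - 1L) * step_px
    x0 <- (cc - 1L) * step_px
    canvas[, , y0 + seq_len(d[3]), x0 + seq_len(d[4])] <- tiles[[k]]
    k <- k + 1L
  }
  ch <- list(canvas)
  names(ch) <- channel
  volume_series(ch, metadata)
}

#' Read or write a FLIM intensity/lifetime image pair as TIFF
#'
#' The pair is stored as two single-page 16-bit TIFFs. Lifetimes in
#' nanoseconds exceed the [0, 1] storage range, so values are
#' divided by a power-of-two `scale` on write (recorded in a JSON sidecar
#' next to the lifetime file) and multiplied back on read; powers of two
#' keep the transform exact.
#'
#' @param flim A [flim_image()].
#' @param intensity_path,lifetime_path TIFF file paths.
#' @param pixel_size um/pixel for the reconstructed [flim_image()].
#' @param scale Lifetime scale override for files without a sidecar.
#' @return `write_flim_image` invisibly returns the two paths;
#'   `read_flim_image` returns a [flim_image()].
#' @export
write_flim_image <- function(flim, intensity_path, lifetime_path) {
  stopifnot(inherits(flim, "flim_image"))
  is <- tiff_scale_for(max(flim$intensity))
  ls <- tiff_scale_for(max(flim$lifetime))
  write_stack_pages(list(flim$intensity), intensity_path, is)
  write_stack_pages(list(flim$lifetime), lifetime_path, ls)
  jsonlite::write_json(
    list(intensity_scale = is, lifetime_scale = ls,
         pixel_size = flim$pixel_size),
    paste0(lifetime_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(intensity = intensity_path, lifetime = lifetime_path))
}

#' @rdname write_flim_image
#' @export
read_flim_image <- function(intensity_path, lifetime_path, pixel_size = 1,
                            scale = NULL) {
  for (p in c(intensity_path, lifetime_path))
    if (!file.exists(p)) stop(sprintf("cannot read FLIM file '%s'", p))
  is <- 1; ls <- if (is.null(scale)) 1 else scale
  sidecar <- paste0(lifetime_path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    is <- sc$intensity_scale
    ls <- sc$lifetime_scale
    if (!is.null(sc$pixel_size)) pixel_size <- sc$pixel_size
  }
  flim_image(tiff::readTIFF(intensity_path) * is,
             tiff::readTIFF(lifetime_path) * ls, pixel_size)
}

#' Persist or load a region of interest as JSON
#'
#' @param roi A [roi_spec()].
#' @param path JSON file path.
#' @return `write_roi` invisibly returns `path`; `read_roi` returns the
#'   [roi_spec()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_spec"))
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_spec(v$x_min, v$x_max, v$y_min, v$y_max)
}
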