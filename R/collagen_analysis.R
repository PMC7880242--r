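# centre the zero-frequency component of a 2D spectrum
fftshift2 <- function(m) {
  sh <- function(n) if (n > 1) c((floor(n / 2) + 1):n, 1:floor(n / 2)) else 1L
  m[sh(nrow(m)), sh(ncol(m)), drop = FALSE]
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Moment-based ellipse fit of a binary mask
#'
#' Fits an ellipse to the point set of TRUE pixels via second-order central
#' moments (with the standard 1/12 per-pixel variance correction), the same
#' construction behind region-props ellipse fits. Angles use the
#' mathematical convention: counter-clockwise from +x with the image-row
#' axis flipped.
#'
#' @param mask Logical matrix.
#' @return List with `eccentricity` (focal distance / major axis length, in
#'   [0, 1]), `angle_deg` (major-axis orientation in [0, 180)),
#'   `major_axis`, `minor_axis` (full lengths in pixels), `n_pixels`.
#' @export
fit_ellipse_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("empty mask: no pixels to fit")
  x <- idx[, 2]
  y <- -idx[, 1]  # math convention: y up
  mx <- mean(x); my <- mean(y)
  uxx <- mean((x - mx)^2) + 1 / 12
  uyy <- mean((y - my)^2) + 1 / 12
  uxy <- mean((x - mx) * (y - my))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(uxx + uyy - common)
  ecc <- sqrt(max(0, 1 - (minor / major)^2))
  angle <- (0.5 * atan2(2 * uxy, uxx - uyy) * 180 / pi) %% 180
  list(eccentricity = ecc, angle_deg = angle,
       major_axis = major, minor_axis = minor, n_pixels = n)
}

#' Extract an SHG tile centered on a tracked cell
#'
#' Cuts a `tile_size` x `tile_size` lateral window around a cell's centroid
#' from the slice nearest the cell's own depth (`z = round(z_px)`), so the
#' collagen analysed is at the same depth as the tracked cell. Windows that
#' run off the image edge are clipped, never padded; `valid_fraction`
#' records how much of the nominal window survived.
#'
#' @param shg_volume Numeric (z, y, x) array: the SHG channel at one time
#'   point.
#' @param centroid A one-row data frame (or list) with `x_px`, `y_px`,
#'   `z_px`, and optionally `track_id` and `t`.
#' @param tile_size Window side in pixels, default 200.
#' @return An object of class `collagen_tile`: `image`, `z_index`, `bounds`
#'   (x_min/x_max/y_min/y_max actually used, 1-based inclusive),
#'   `valid_fraction`, `track_id`, `t`.
#' @export
extract_tile <- function(shg_volume, centroid, tile_size = 200) {
  stopifnot(is.array(shg_volume), length(dim(shg_volume)) == 3L,
            tile_size >= 1)
  d <- dim(shg_volume)
  cx <- round(centroid$x_px)
  cy <- round(centroid$y_px)
  cz <- as.integer(min(max(round(centroid$z_px), 1L), d[1]))
  if (cx < 1 || cx > d[3] || cy < 1 || cy > d[2])
    stop("centroid lies outside the volume")
  lo_off <- floor((tile_size - 1) / 2)
  hi_off <- ceiling((tile_size - 1) / 2)
  x0 <- as.integer(max(1L, cx - lo_off)); x1 <- as.integer(min(d[3], cx + hi_off))
  y0 <- as.integer(max(1L, cy - lo_off)); y1 <- as.integer(min(d[2], cy + hi_off))
  img <- shg_volume[cz, y0:y1, x0:x1, drop = TRUE]
  if (is.null(dim(img))) img <- matrix(img, nrow = y1 - y0 + 1)
  structure(list(
    image = img, z_index = cz,
    bounds = c(x_min = x0, x_max = x1, y_min = y0, y_max = y1),
    valid_fraction = ((x1 - x0 + 1) * (y1 - y0 + 1)) / tile_size^2,
    track_id = if (!is.null(centroid$track_id)) centroid$track_id else NA,
    t = if (!is.null(centroid$t)) centroid$t else NA),
    class = "collagen_tile")
}

#' Collagen alignment from the 2D Fourier magnitude of an SHG tile
#'
#' Quantifies how strongly local collagen fibers share one orientation. The
#' tile's mean is subtracted (the raw spectrum is otherwise dominated by its
#' DC term), an optional Hann window suppresses edge ringing, and the 2D
#' Fourier magnitude is thresholded at `threshold_frac` of its maximum. An
#' ellipse is fitted to the binary mask by second-order moments; its
#' eccentricity — focal distance over major axis length — is the alignment
#' score: near 0 for isotropically oriented fibers, near 1 for strongly
#' aligned ones. Because spectral energy concentrates perpendicular to image
#' stripes, the inferred fiber orientation is the FT major axis rotated by
#' 90 degrees.
#'
#' @param tile A [extract_tile()] result or a plain numeric matrix.
#' @param threshold_frac Fraction of the maximum FT magnitude kept in the
#'   binary mask, in (0, 1); default 0.2, which keeps the central spectral
#'   lobe rather than only its peak and makes the eccentricity stable and
#'   discriminative across anisotropy levels (see the methods vignette for
#'   the sensitivity of the score to this choice).
#' @param window `"hann"` (default) or `"none"`.
#' @param remove_dc Subtract the tile mean first; default TRUE.
#' @return An object of class `alignment_result`: `eccentricity`,
#'   `ft_angle_deg` (FT-ellipse major axis, [0, 180)), `fiber_angle_deg`
#'   (`(ft_angle_deg + 90) %% 180`), `n_mask` (pixels in the binary mask),
#'   `unreliable` (TRUE when the mask has fewer than 5 pixels),
#'   `threshold_frac`.
#' @export
ft_alignment <- function(tile, threshold_frac = 0.2,
                         window = c("hann", "none"), remove_dc = TRUE) {
  window <- match.arg(window)
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  img <- if (inherits(tile, "collagen_tile")) tile$image else tile
  stopifnot(is.matrix(img))
  if (diff(range(img)) == 0)
    stop("degenerate input: constant tile has no orientation content")
  if (remove_dc) img <- img - mean(img)
  if (window == "hann")
    img <- img * outer(hann_window(nrow(img)), hann_window(ncol(img)))
  if (diff(range(img)) == 0)
    stop("degenerate input: tile is constant after preprocessing")
  mag <- Mod(fftshift2(stats::fft(img)))
  mask <- mag >= threshold_frac * max(mag)
  fit <- fit_ellipse_mask(mask)
  structure(list(
    eccentricity = fit$eccentricity,
    ft_angle_deg = fit$angle_deg,
    fiber_angle_deg = (fit$angle_deg + 90) %% 180,
    n_mask = fit$n_pixels,
    unreliable = fit$n_pixels < 5L,
    threshold_frac = threshold_frac), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment_result: eccentricity %.3f, fiber angle %.1f deg (FT axis %.1f), mask %d px%s\n",
    x$eccentricity, x$fiber_angle_deg, x$ft_angle_deg, x$n_mask,
    if (x$unreliable) " [unreliable]" else ""))
  invisible(x)
}

#' Collagen alignment at every tracked cell
#'
#' For each detection of each track, extracts the SHG tile centered on the
#' cell at the cell's own depth and computes [ft_alignment()]. Degenerate
#' tiles (e.g. a cell over empty background) and heavily clipped edge tiles
#' produce flagged rows instead of aborting the batch, so the output joins
#' row-for-row onto the motility table by (track_id, t).
#'
#' @param tracks Result of [link_tracks()].
#' @param shg_series A [volume_series()] sharing the lateral frame with the
#'   tracking channel (co-registration contract).
#' @param channel Channel name of the SHG data in `shg_series`.
#' @param tile_size,threshold_frac,window Passed to [extract_tile()] and
#'   [ft_alignment()].
#' @param min_valid_fraction Tiles with a smaller in-bounds fraction are
#'   flagged `"low_valid_fraction"`; default 0.5.
#' @return Data frame with columns `track_id`, `t`, `z_index`,
#'   `eccentricity`, `ft_angle_deg`, `fiber_angle_deg`, `valid_fraction`,
#'   `flag` (empty string for clean rows).
#' @export
per_cell_alignment <- function(tracks, shg_series, channel = "SHG",
                               tile_size = 200, threshold_frac = 0.2,
                               window = "hann", min_valid_fraction = 0.5) {
  stopifnot(inherits(shg_series, "volume_series"))
  if (!channel %in% names(shg_series$channels))
    stop(sprintf("channel '%s' not present in series", channel))
  arr <- shg_series$channels[[channel]]
  rows <- vector("list", nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    row <- tracks[i, , drop = FALSE]
    vol <- arr[row$t, , , , drop = TRUE]
    if (length(dim(vol)) != 3L)
      vol <- array(vol, dim(arr)[2:4])
    tile <- extract_tile(vol, row, tile_size)
    res <- tryCatch(ft_alignment(tile, threshold_frac, window),
                    error = function(e) NULL)
    flag <- if (is.null(res)) {
      "degenerate"
    } else if (tile$valid_fraction < min_valid_fraction) {
      "low_valid_fraction"
    } else if (res$unreliable) {
      "unreliable_mask"
    } else ""
    rows[[i]] <- data.frame(
      track_id = row$track_id, t = row$t, z_index = tile$z_index,
      eccentricity = if (is.null(res)) NA_real_ else res$eccentricity,
      ft_angle_deg = if (is.null(res)) NA_real_ else res$ft_angle_deg,
      fiber_angle_deg = if (is.null(res)) NA_real_ else res$fiber_angle_deg,
      valid_fraction = tile$valid_fraction, flag = flag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export cell-centered SHG tiles for external fiber extraction
#'
#' Writes each tile as a single-page grayscale 16-bit TIFF (the format
#' curvelet-based fiber extraction tools ingest) plus a manifest CSV mapping
#' each filename to its source cell and pixel bounds. Duplicate
#' (track_id, t) keys get a numeric suffix so the manifest stays
#' unambiguous.
#'
#' @param tiles List of [extract_tile()] results.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the manifest data frame (also written to
#'   `manifest.csv` in `dir`): columns file, track_id, t, z_index,
#'   x_min, x_max, y_min, y_max, valid_fraction, scale.
#' @export
export_tiles_for_ctfire <- function(tiles, dir) {
  stopifnot(is.list(tiles), length(tiles) > 0L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seen <- character(0)
  rows <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    tl <- tiles[[i]]
    stopifnot(inherits(tl, "collagen_tile"))
    base <- sprintf("tile_track%s_t%s", tl$track_id, tl$t)
    name <- base
    k <- 1L
    while (name %in% seen) {
      k <- k + 1L
      name <- sprintf("%s_%d", base, k)
    }
    seen <- c(seen, name)
    scale <- tiff_scale_for(max(tl$image))
    path <- file.path(dir, paste0(name, ".tif"))
    write_stack_pages(list(tl$image), path, scale)
    rows[[i]] <- data.frame(
      file = basename(path), track_id = tl$track_id, t = tl$t,
      z_index = tl$z_index,
      x_min = tl$bounds[["x_min"]], x_max = tl$bounds[["x_max"]],
      y_min = tl$bounds[["y_min"]], y_max = tl$bounds[["y_max"]],
      valid_fraction = tl$valid_fraction, scale = scale)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
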