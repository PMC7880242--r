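#' Default intensity mask threshold for a FLIM image
#'
#' Lifetime estimates at near-zero photon counts are noise, so statistics
#' exclude dim pixels. The default cutoff is the 5th percentile of the
#' nonzero intensities; zero-intensity pixels are always excluded.
#'
#' @param flim A [flim_image()].
#' @return Intensity threshold (same units as the intensity image).
#' @export
default_intensity_min <- function(flim) {
  stopifnot(inherits(flim, "flim_image"))
  nz <- flim$intensity[flim$intensity > 0]
  if (length(nz) == 0L) return(Inf)
  as.numeric(stats::quantile(nz, 0.05, names = FALSE))
}

#' Mean NADH lifetime over a region of interest
#'
#' Arithmetic mean of the lifetime image over the ROI pixels whose intensity
#' passes the mask threshold.
#'
#' @param flim A [flim_image()].
#' @param roi A [roi_spec()] within the image bounds.
#' @param intensity_min Minimum intensity for a pixel to count; `NULL`
#'   (default) uses [default_intensity_min()]. Zero-intensity pixels are
#'   excluded regardless.
#' @return List with `mean_ns`, `n_pixels` (unmasked pixels used), and
#'   `masked_fraction` (fraction of ROI pixels excluded by the mask).
#' @export
roi_mean_lifetime <- function(flim, roi, intensity_min = NULL) {
  stopifnot(inherits(flim, "flim_image"), inherits(roi, "roi_spec"))
  roi_check_bounds(roi, nrow(flim$intensity), ncol(flim$intensity))
  if (is.null(intensity_min)) intensity_min <- default_intensity_min(flim)
  ys <- roi$y_min:roi$y_max
  xs <- roi$x_min:roi$x_max
  inten <- flim$intensity[ys, xs]
  life <- flim$lifetime[ys, xs]
  ok <- inten > 0 & inten >= intensity_min
  if (!any(ok))
    stop("undefined mean: every pixel in the ROI is intensity-masked")
  list(mean_ns = mean(life[ok]), n_pixels = sum(ok),
       masked_fraction = 1 - sum(ok) / length(ok))
}

#' Region-level lifetime statistics: unweighted mean of area means
#'
#' For each named region, computes the mean lifetime of each of its areas
#' via [roi_mean_lifetime()] and summarises the region as the unweighted
#' arithmetic mean of those per-area means (mean of means), which is
#' insensitive to area size. The pixel-pooled mean is reported alongside for
#' reference; the two coincide exactly when all areas hold equal unmasked
#' pixel counts. A fully masked area is flagged and dropped from the region
#' mean with a warning rather than failing the region.
#'
#' @param flim A [flim_image()].
#' @param selection Named list: region name -> list of [roi_spec()] areas.
#' @param intensity_min As in [roi_mean_lifetime()].
#' @return Object of class `region_lifetime_stats`: `areas` (data frame:
#'   region, area, mean_ns, n_pixels, masked_fraction, flag), `regions`
#'   (data frame: region, mean_of_means_ns, pooled_mean_ns, n_areas_used,
#'   masked_fraction), and `intensity_min`.
#' @export
region_mean_of_means <- function(flim, selection, intensity_min = NULL) {
  stopifnot(inherits(flim, "flim_image"), is.list(selection),
            length(selection) > 0L)
  if (is.null(names(selection)) || any(!nzchar(names(selection))))
    stop("`selection` must be a named list of regions")
  if (is.null(intensity_min)) intensity_min <- default_intensity_min(flim)
  area_rows <- list()
  region_rows <- list()
  for (rg in names(selection)) {
    areas <- selection[[rg]]
    if (length(areas) == 0L) stop(sprintf("region '%s' has no areas", rg))
    means <- numeric(0)
    pooled_sum <- 0
    pooled_n <- 0L
    roi_px <- 0L
    for (i in seq_along(areas)) {
      st <- tryCatch(roi_mean_lifetime(flim, areas[[i]], intensity_min),
                     error = function(e) NULL)
      a <- areas[[i]]
      npx_roi <- (a$x_max - a$x_min + 1L) * (a$y_max - a$y_min + 1L)
      roi_px <- roi_px + npx_roi
      if (is.null(st)) {
        warning(sprintf(
          "region '%s' area %d fully masked; dropped from region mean",
          rg, i))
        area_rows[[length(area_rows) + 1L]] <- data.frame(
          region = rg, area = i, mean_ns = NA_real_, n_pixels = 0L,
          masked_fraction = 1, flag = "fully_masked")
      } else {
        means <- c(means, st$mean_ns)
        pooled_sum <- pooled_sum + st$mean_ns * st$n_pixels
        pooled_n <- pooled_n + st$n_pixels
        area_rows[[length(area_rows) + 1L]] <- data.frame(
          region = rg, area = i, mean_ns = st$mean_ns,
          n_pixels = st$n_pixels, masked_fraction = st$masked_fraction,
          flag = "")
      }
    }
    if (length(means) == 0L)
      stop(sprintf("region '%s': every area is fully masked", rg))
    region_rows[[length(region_rows) + 1L]] <- data.frame(
      region = rg, mean_of_means_ns = mean(means),
      pooled_mean_ns = pooled_sum / pooled_n,
      n_areas_used = length(means),
      masked_fraction = 1 - pooled_n / roi_px)
  }
  structure(list(areas = do.call(rbind, area_rows),
                 regions = do.call(rbind, region_rows),
                 intensity_min = intensity_min),
            class = "region_lifetime_stats")
}

#' @export
print.region_lifetime_stats <- function(x, ...) {
  cat("region_lifetime_stats (unweighted mean of area means):\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Sample random non-overlapping square areas inside a region mask
#'
#' Draws `n` axis-aligned `area_size` x `area_size` boxes, each fully inside
#' the TRUE part of `region_mask` and pairwise disjoint, by bounded
#' rejection sampling. Reproducible when `seed` is given (the caller's RNG
#' state is restored afterwards).
#'
#' @param region_mask Logical matrix marking the region.
#' @param n Number of areas, default 5.
#' @param area_size Box side in pixels.
#' @param seed Optional integer seed.
#' @param max_tries Sampling attempts before giving up, default `200 * n`.
#' @return List of `n` [roi_spec()] boxes.
#' @export
sample_random_areas <- function(region_mask, n = 5, area_size, seed = NULL,
                                max_tries = 200 * n) {
  stopifnot(is.matrix(region_mask), is.logical(region_mask), n >= 1,
            area_size >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  ny <- nrow(region_mask); nx <- ncol(region_mask)
  if (area_size > ny || area_size > nx)
    stop("infeasible: region smaller than one area; use a smaller area_size")
  # candidate top-left corners whose whole box lies inside the mask
  ok_corner <- function(y0, x0) {
    all(region_mask[y0:(y0 + area_size - 1L), x0:(x0 + area_size - 1L)])
  }
  chosen <- list()
  occupied <- matrix(FALSE, ny, nx)
  tries <- 0L
  while (length(chosen) < n && tries < max_tries) {
    tries <- tries + 1L
    y0 <- sample.int(ny - area_size + 1L, 1L)
    x0 <- sample.int(nx - area_size + 1L, 1L)
    ys <- y0:(y0 + area_size - 1L)
    xs <- x0:(x0 + area_size - 1L)
    if (!ok_corner(y0, x0)) next
    if (any(occupied[ys, xs])) next
    occupied[ys, xs] <- TRUE
    chosen[[length(chosen) + 1L]] <- roi_spec(x0, x0 + area_size - 1L,
                                              y0, y0 + area_size - 1L)
  }
  if (length(chosen) < n)
    stop(sprintf(
      "could not place %d non-overlapping %dx%d areas after %d tries; try smaller areas",
      n, area_size, area_size, max_tries))
  chosen
}
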