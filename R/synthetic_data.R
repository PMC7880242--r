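# run expr with a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# von Mises sampler (rejection against a uniform proposal; acceptance
# ~ I0(k) e^-k, adequate for the k <= ~30 used in fiber fields)
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    th <- stats::runif(m, 0, 2 * pi)
    u <- stats::runif(m)
    acc <- u < exp(kappa * (cos(th - mu) - 1))
    out <- c(out, th[acc])
  }
  out[seq_len(n)] %% (2 * pi)
}

#' Configuration for a synthetic migrating-cell scene
#'
#' Describes a ground-truthed emulation of an intravital two-photon
#' time-lapse: bright GFP-like cells (soft-edged spheres) moving through a
#' shallow volumetric stack over a dim noisy background. Defaults mirror a
#' typical acquisition geometry — a 5-slice stack at 5 um axial step, 5 min
#' frame interval — at a scale small enough for fast closed-loop tests.
#' Cell depth is snapped to slice positions and held fixed (the axial
#' sampling is far coarser than the lateral), so motion models act in the
#' lateral plane.
#'
#' @param n_time,n_z,ny,nx Scene dimensions (frames, slices, rows, cols).
#' @param voxel_size_xy,voxel_size_z,frame_interval Physical metadata
#'   (um/px, um/slice, min).
#' @param n_cells Cells present at the first frame.
#' @param cell_radius_um Cell radius; default 7 (macrophage-scale).
#' @param min_separation_um Minimum initial centre-to-centre distance;
#'   default `2 * cell_radius_um + 2 * voxel_size_xy`, and at least 25 so
#'   tracking scenes stay well-separated.
#' @param motion List describing the motion model: `list(model =
#'   "drift", speed_um_min =, heading_deg =)` for shared straight-line
#'   drift; `list(model = "random-walk", speed_um_min =)` for independent
#'   fixed-step random direction walks; `list(model = "attract",
#'   wound_xy_um = c(x, y), speed_um_min =)` for motion toward a wound
#'   focus. Headings use the mathematical convention (CCW from +x, y up).
#' @param birth_per_frame New cells appearing at each frame after the
#'   first (influx), default 0.
#' @param background_level,noise_sd,amplitude Background mean, Gaussian
#'   noise sd, and cell peak amplitude (image is clipped to [0, 1]).
#' @param edge_um Softness of the sphere edge, default 0.5.
#' @param seed Default seed used by [generate_cell_scene()].
#' @return Validated list of class `scene_config`.
#' @export
scene_config <- function(n_time = 6, n_z = 5, ny = 200, nx = 200,
                         voxel_size_xy = 1, voxel_size_z = 5,
                         frame_interval = 5, n_cells = 10,
                         cell_radius_um = 7, min_separation_um = NULL,
                         motion = list(model = "drift", speed_um_min = 2,
                                       heading_deg = 30),
                         birth_per_frame = 0, background_level = 0.05,
                         noise_sd = 0.02, amplitude = 0.9, edge_um = 0.5,
                         seed = 1L) {
  if (is.null(min_separation_um))
    min_separation_um <- max(2 * cell_radius_um + 2 * voxel_size_xy, 25)
  cfg <- list(n_time = as.integer(n_time), n_z = as.integer(n_z),
              ny = as.integer(ny), nx = as.integer(nx),
              voxel_size_xy = voxel_size_xy, voxel_size_z = voxel_size_z,
              frame_interval = frame_interval, n_cells = as.integer(n_cells),
              cell_radius_um = cell_radius_um,
              min_separation_um = min_separation_um, motion = motion,
              birth_per_frame = as.integer(birth_per_frame),
              background_level = background_level, noise_sd = noise_sd,
              amplitude = amplitude, edge_um = edge_um,
              seed = as.integer(seed))
  with(cfg, stopifnot(
    n_time >= 1, n_z >= 1, ny >= 8, nx >= 8, voxel_size_xy > 0,
    voxel_size_z > 0, frame_interval > 0, n_cells >= 0, cell_radius_um > 0,
    min_separation_um > 0, birth_per_frame >= 0, background_level >= 0,
    noise_sd >= 0, amplitude > 0, amplitude + background_level <= 1.2,
    edge_um > 0))
  if (!cfg$motion$model %in% c("drift", "random-walk", "attract"))
    stop("motion$model must be drift, random-walk or attract")
  structure(cfg, class = "scene_config")
}

# total lateral displacement of one cell from birth frame to scene end, in
# index-space um (dy follows row index; drift heading is converted here)
motion_step <- function(motion, frame_interval) {
  switch(motion$model,
    drift = {
      s <- motion$speed_um_min * frame_interval
      c(s * cos(motion$heading_deg * pi / 180),
        -s * sin(motion$heading_deg * pi / 180))
    },
    c(0, 0))
}

place_cells <- function(n, existing, lo, hi, min_sep, max_tries = 4000L) {
  pts <- existing
  added <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(added) < n && tries < max_tries) {
    tries <- tries + 1L
    p <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    if (nrow(pts) == 0L ||
        min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= min_sep) {
      pts <- rbind(pts, p)
      added <- rbind(added, p)
    }
  }
  if (nrow(added) < n)
    stop("infeasible packing: cannot place cells at the requested separation")
  added
}

#' Generate a ground-truthed synthetic cell migration scene
#'
#' Renders the scene described by a [scene_config()]: soft-edged spheres at
#' continuously valued trajectory positions, over a Gaussian-noise
#' background, as a single-channel (`"TPF"`) [volume_series()]. Trajectories
#' are confined to the field of view (drift scenes are seeded so the whole
#' path fits; random walks reflect at the margins). The same (config, seed)
#' pair always yields bit-identical output (intensities are quantised to
#' the 16-bit on-disk TIFF sample grid).
#'
#' @param config A [scene_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List with `series` (a [volume_series()]) and `truth`: a list with
#'   `trajectories` (data frame: cell, t, x_um, y_um, z_um), `birth_t` (per
#'   cell), `heading_deg` (drift scenes), and the config.
#' @export
generate_cell_scene <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scene_config"))
  with_local_seed(seed, {
    vxy <- config$voxel_size_xy
    r <- config$cell_radius_um
    ext <- c((config$nx - 1) * vxy, (config$ny - 1) * vxy)
    step <- motion_step(config$motion, config$frame_interval)
    walk_step <- if (config$motion$model %in% c("random-walk", "attract"))
      config$motion$speed_um_min * config$frame_interval else 0
    margin <- r + vxy
    # allowed initial box so that a drifting cell never leaves the volume
    place_box <- function(frames_left) {
      drift <- step * frames_left
      lo <- c(margin - min(0, drift[1]), margin - min(0, drift[2]))
      hi <- c(ext[1] - margin - max(0, drift[1]),
              ext[2] - margin - max(0, drift[2]))
      if (any(hi <= lo)) stop("scene too small for the requested drift")
      list(lo = lo, hi = hi)
    }
    z_slices <- seq_len(config$n_z)
    pos <- matrix(numeric(0), ncol = 2)   # lateral um, index convention
    zs <- numeric(0)
    birth <- integer(0)
    traj <- list()
    spawn <- function(n, t) {
      if (n <= 0L) return(invisible())
      b <- place_box(config$n_time - t)
      np <- place_cells(n, pos, b$lo, b$hi, config$min_separation_um)
      pos <<- rbind(pos, np)
      zmid <- pmin(pmax(sample(z_slices, n, replace = TRUE), 2L),
                   max(config$n_z - 1L, 1L))
      zs <<- c(zs, (zmid - 1) * config$voxel_size_z)
      birth <<- c(birth, rep(t, n))
    }
    spawn(config$n_cells, 1L)
    d <- c(config$n_time, config$n_z, config$ny, config$nx)
    vol <- array(0, d)
    xg <- (seq_len(config$nx) - 1) * vxy
    yg <- (seq_len(config$ny) - 1) * vxy
    zg <- (seq_len(config$n_z) - 1) * config$voxel_size_z
    render_cell <- function(t, p, z0) {
      zi <- which(abs(zg - z0) <= r + 2)
      yi <- which(abs(yg - p[2]) <= r + 2)
      xi <- which(abs(xg - p[1]) <= r + 2)
      if (!length(zi) || !length(yi) || !length(xi)) return(invisible())
      dz2 <- (zg[zi] - z0)^2
      dy2 <- (yg[yi] - p[2])^2
      dx2 <- (xg[xi] - p[1])^2
      dist <- sqrt(outer(outer(dz2, dy2, "+"), dx2, "+"))
      blob <- config$amplitude * stats::plogis((r - dist) / config$edge_um)
      vol[t, zi, yi, xi] <<- vol[t, zi, yi, xi] + blob
    }
    for (t in seq_len(config$n_time)) {
      if (t > 1L) {
        # move cells alive before this frame
        for (i in seq_len(nrow(pos))) {
          if (birth[i] >= t) next
          pos[i, ] <- switch(config$motion$model,
            drift = pos[i, ] + step,
            "random-walk" = {
              th <- stats::runif(1, 0, 2 * pi)
              p <- pos[i, ] + walk_step * c(cos(th), sin(th))
              # reflect at margins
              for (k in 1:2) {
                if (p[k] < margin) p[k] <- 2 * margin - p[k]
                if (p[k] > ext[k] - margin) p[k] <- 2 * (ext[k] - margin) - p[k]
              }
              p
            },
            attract = {
              w <- config$motion$wound_xy_um
              v <- w - pos[i, ]
              dst <- sqrt(sum(v^2))
              if (dst < 1e-9) pos[i, ]
              else pos[i, ] + v / dst * min(walk_step, dst)
            })
        }
        spawn(config$birth_per_frame, t)
      }
      alive <- which(birth <= t)
      for (i in alive) render_cell(t, pos[i, ], zs[i])
      if (length(alive))
        traj[[t]] <- data.frame(cell = alive, t = t,
                                x_um = pos[alive, 1], y_um = pos[alive, 2],
                                z_um = zs[alive])
    }
    noise <- array(stats::rnorm(prod(d), config$background_level,
                                config$noise_sd), d)
    vol <- quantize_storage(pmin(pmax(vol + noise, 0), 1))
    meta <- volume_metadata(vxy, config$voxel_size_z, config$frame_interval,
                            "TPF")
    truth <- list(
      trajectories = {
        tj <- do.call(rbind, traj)
        rownames(tj) <- NULL
        tj[order(tj$cell, tj$t), ]
      },
      birth_t = birth,
      heading_deg = if (config$motion$model == "drift")
        config$motion$heading_deg else NA_real_,
      config = config)
    list(series = volume_series(list(TPF = vol), meta), truth = truth)
  })
}

#' Generate an SHG-like fiber field with controlled orientation anisotropy
#'
#' Draws anti-aliased straight fiber segments whose orientations follow an
#' axial von Mises distribution: concentration `kappa = 0` gives an
#' isotropic field, large `kappa` gives fibers tightly aligned around
#' `mean_angle_deg`. Angles use the mathematical convention (CCW from +x,
#' y up) and are axial (defined modulo 180 degrees).
#'
#' @param ny,nx Field size in pixels.
#' @param mean_angle_deg Mean fiber orientation.
#' @param kappa von Mises concentration (>= 0).
#' @param n_fibers Number of segments; 0 yields a constant background.
#' @param fiber_length_px,fiber_width_px Segment length and Gaussian
#'   half-width.
#' @param n_z Number of independently drawn slices; 1 (default) returns a
#'   matrix, otherwise a (z, y, x) array.
#' @param background,noise_sd,amplitude Background level, additive noise sd,
#'   per-fiber peak amplitude (result clipped to [0, 1]).
#' @param seed Integer seed.
#' @return List with `image` (16-bit-grid quantised matrix or array) and
#'   `truth` (list: `orientations_deg` per fiber (per slice), parameters).
#' @export
generate_fiber_field <- function(ny = 200, nx = 200, mean_angle_deg = 30,
                                 kappa = 4, n_fibers = 60,
                                 fiber_length_px = 120, fiber_width_px = 2,
                                 n_z = 1, background = 0.02,
                                 noise_sd = 0.01, amplitude = 0.7,
                                 seed = 1L) {
  stopifnot(kappa >= 0, n_fibers >= 0, ny >= 8, nx >= 8)
  with_local_seed(seed, {
    draw_slice <- function() {
      img <- matrix(0, ny, nx)
      if (n_fibers == 0L)
        return(list(img = img, ang = numeric(0)))
      # axial orientations: sample on the doubled circle, halve
      th <- rvonmises(n_fibers, 2 * mean_angle_deg * pi / 180, kappa) / 2
      cx <- stats::runif(n_fibers, 1, nx)
      cy <- stats::runif(n_fibers, 1, ny)
      for (i in seq_len(n_fibers)) {
        ux <- cos(th[i]); uy <- -sin(th[i])  # row axis points down
        h <- fiber_length_px / 2
        x0 <- cx[i] - h * ux; x1 <- cx[i] + h * ux
        y0 <- cy[i] - h * uy; y1 <- cy[i] + h * uy
        pad <- 3 * fiber_width_px
        xs <- max(1L, floor(min(x0, x1) - pad)):min(nx, ceiling(max(x0, x1) + pad))
        ys <- max(1L, floor(min(y0, y1) - pad)):min(ny, ceiling(max(y0, y1) + pad))
        if (!length(xs) || !length(ys)) next
        px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
        py <- matrix(ys, length(ys), length(xs))
        # distance from pixel to segment
        wx <- px - x0; wy <- py - y0
        sx <- x1 - x0; sy <- y1 - y0
        tt <- pmin(pmax((wx * sx + wy * sy) / (sx^2 + sy^2), 0), 1)
        dist2 <- (wx - tt * sx)^2 + (wy - tt * sy)^2
        img[ys, xs] <- img[ys, xs] +
          amplitude * exp(-dist2 / fiber_width_px^2)
      }
      list(img = img, ang = (th * 180 / pi) %% 180)
    }
    if (n_z == 1L) {
      s <- draw_slice()
      img <- s$img + matrix(stats::rnorm(ny * nx, background, noise_sd),
                            ny, nx)
      img <- quantize_storage(pmin(pmax(img, 0), 1))
      list(image = img,
           truth = list(orientations_deg = s$ang,
                        mean_angle_deg = mean_angle_deg, kappa = kappa))
    } else {
      arr <- array(0, c(n_z, ny, nx))
      angs <- vector("list", n_z)
      for (z in seq_len(n_z)) {
        s <- draw_slice()
        arr[z, , ] <- s$img + matrix(stats::rnorm(ny * nx, background,
                                                  noise_sd), ny, nx)
        angs[[z]] <- s$ang
      }
      arr <- quantize_storage(pmin(pmax(arr, 0), 1))
      list(image = arr,
           truth = list(orientations_deg = angs,
                        mean_angle_deg = mean_angle_deg, kappa = kappa))
    }
  })
}

#' Generate a two-region synthetic FLIM lifetime map
#'
#' Builds a [flim_image()] whose lifetime is a per-region constant plus
#' Gaussian noise (clipped at 0), emulating tissue regions of differing
#' metabolic state (e.g. near versus far from a wound edge). The intensity
#' image is bright inside the regions, with an optional fraction of dark
#' (zero-intensity) pixels emulating photon-starved areas; pixels outside
#' every region have zero intensity.
#'
#' @param ny,nx Image size.
#' @param region_masks Named list of disjoint logical matrices. `NULL`
#'   (default) splits the image into left/right halves named
#'   `"Region 1"`, `"Region 2"`.
#' @param region_means_ns Named numeric vector of true mean lifetimes (ns),
#'   names matching `region_masks`; default `c("Region 1" = 1.2,
#'   "Region 2" = 0.9)`.
#' @param noise_sd Lifetime noise sd in ns, default 0.05.
#' @param dark_fraction Fraction of in-region pixels with zero intensity.
#' @param intensity_level Intensity of lit pixels, default 0.9.
#' @param seed Integer seed.
#' @return List with `flim` (a [flim_image()]) and `truth` (region masks,
#'   true means, dark fraction).
#' @export
generate_lifetime_map <- function(ny = 128, nx = 128, region_masks = NULL,
                                  region_means_ns = c("Region 1" = 1.2,
                                                      "Region 2" = 0.9),
                                  noise_sd = 0.05, dark_fraction = 0,
                                  intensity_level = 0.9, seed = 1L) {
  stopifnot(noise_sd >= 0, dark_fraction >= 0, dark_fraction < 1,
            all(region_means_ns > 0))
  if (is.null(region_masks)) {
    half <- floor(nx / 2)
    left <- matrix(FALSE, ny, nx); left[, seq_len(half)] <- TRUE
    right <- matrix(FALSE, ny, nx); right[, (half + 1):nx] <- TRUE
    region_masks <- list(left, right)
    names(region_masks) <- names(region_means_ns)
  }
  stopifnot(length(region_masks) == length(region_means_ns),
            identical(names(region_masks), names(region_means_ns)))
  total <- Reduce(`+`, lapply(region_masks, function(m) m * 1L))
  if (any(total > 1L)) stop("region masks must be disjoint")
  with_local_seed(seed, {
    lt <- matrix(0, ny, nx)
    for (rg in names(region_masks)) {
      m <- region_masks[[rg]]
      n <- sum(m)
      lt[m] <- pmax(region_means_ns[[rg]] + stats::rnorm(n, 0, noise_sd), 0)
    }
    inten <- matrix(0, ny, nx)
    lit <- total == 1L
    inten[lit] <- intensity_level
    if (dark_fraction > 0) {
      litidx <- which(lit)
      dark <- sample(litidx, round(dark_fraction * length(litidx)))
      inten[dark] <- 0
    }
    fl <- flim_image(quantize_storage(inten), quantize_storage(lt), pixel_size = 1)
    list(flim = fl,
         truth = list(region_masks = region_masks,
                      region_means_ns = region_means_ns,
                      noise_sd = noise_sd, dark_fraction = dark_fraction))
  })
}
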