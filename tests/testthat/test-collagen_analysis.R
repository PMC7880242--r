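draw_ellipse_mask <- function(ny, nx, cy, cx, a, b, angle_deg = 0) {
  yy <- matrix(rep(seq_len(ny), nx), ny, nx)
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  th <- angle_deg * pi / 180
  # math convention: y up
  u <- (xx - cx) * cos(th) + (-(yy - cy)) * sin(th)
  v <- -(xx - cx) * sin(th) + (-(yy - cy)) * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

stripes <- function(ny, nx, fiber_angle_deg, period = 10) {
  yy <- matrix(rep(seq_len(ny), nx), ny, nx)
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  nrm <- (fiber_angle_deg + 90) * pi / 180  # normal to the stripes
  phase <- xx * cos(nrm) + (-yy) * sin(nrm)
  0.5 + 0.4 * sin(2 * pi * phase / period)
}

rot90cw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

test_that("moment ellipse fit matches the analytic eccentricity and angle", {
  cases <- list(c(a = 80, b = 40, ang = 0), c(a = 80, b = 40, ang = 30),
                c(a = 60, b = 50, ang = 120), c(a = 70, b = 70, ang = 0))
  for (cs in cases) {
    mask <- draw_ellipse_mask(200, 200, 100, 100, cs["a"], cs["b"],
                              cs["ang"])
    fit <- fit_ellipse_mask(mask)
    e_true <- sqrt(1 - (cs[["b"]] / cs[["a"]])^2)
    expect_lt(abs(fit$eccentricity - e_true), 0.02)
    if (cs[["a"]] > cs[["b"]]) {
      dev <- (fit$angle_deg - cs[["ang"]] + 90) %% 180 - 90
      expect_lt(abs(dev), 2)
    }
  }
  # the 2:1 closed form from the definition e = c / a
  mask <- draw_ellipse_mask(200, 200, 100, 100, 80, 40)
  expect_lt(abs(fit_ellipse_mask(mask)$eccentricity - sqrt(3) / 2), 0.02)
})

test_that("tile extraction is centered, depth-faithful and clip-aware", {
  set.seed(8)
  vol <- array(runif(5 * 400 * 400), c(5, 400, 400))
  tile <- extract_tile(vol, list(x_px = 300, y_px = 300, z_px = 2.4), 200)
  expect_identical(tile$z_index, 2L)
  expect_identical(unname(tile$bounds),
                   c(201L, 400L, 201L, 400L))
  expect_equal(tile$valid_fraction, 1.0)
  expect_identical(tile$image, vol[2, 201:400, 201:400])
  # near-corner centroid: clipped to 150 x 150 of the nominal 200 x 200
  tile2 <- extract_tile(vol, list(x_px = 50, y_px = 50, z_px = 1), 200)
  expect_equal(tile2$valid_fraction, 0.5625)
  expect_identical(dim(tile2$image), c(150L, 150L))
  # odd tile size stays exactly tile_size when in bounds
  tile3 <- extract_tile(vol, list(x_px = 200, y_px = 200, z_px = 3), 7)
  expect_identical(dim(tile3$image), c(7L, 7L))
  expect_identical(tile3$image, vol[3, 197:203, 197:203])
})

test_that("tile depth always tracks the rounded centroid z", {
  set.seed(9)
  vol <- array(runif(5 * 64 * 64), c(5, 64, 64))
  for (i in 1:25) {
    z <- runif(1, 1, 5)
    tile <- extract_tile(vol, list(x_px = 32, y_px = 32, z_px = z), 16)
    expect_identical(tile$z_index, as.integer(round(z)))
  }
})

test_that("parallel stripes give near-unity eccentricity at the stripe angle", {
  for (ang in c(0, 30, 90, 120)) {
    r <- ft_alignment(stripes(200, 200, ang))
    expect_gt(r$eccentricity, 0.9)
    dev <- (r$fiber_angle_deg - ang + 90) %% 180 - 90
    expect_lt(abs(dev), 3)
  }
})

test_that("eccentricity is invariant to rotation and intensity scaling", {
  img <- stripes(200, 200, 30)
  base <- ft_alignment(img)
  rot <- ft_alignment(rot90cw(img))
  expect_lt(abs(rot$eccentricity - base$eccentricity), 1e-6)
  dev <- (rot$ft_angle_deg - base$ft_angle_deg - 90) %% 180
  expect_lt(min(dev, 180 - dev), 1e-3)
  scaled <- ft_alignment(img * 7.3)
  expect_equal(scaled$eccentricity, base$eccentricity)
  expect_equal(scaled$n_mask, base$n_mask)
})

test_that("fiber orientation is the FT axis rotated a quarter turn", {
  r <- ft_alignment(stripes(128, 128, 40))
  expect_equal(r$fiber_angle_deg, (r$ft_angle_deg + 90) %% 180)
  expect_gte(r$eccentricity, 0)
  expect_lte(r$eccentricity, 1)
})

test_that("constant tiles raise the degenerate-input error", {
  expect_error(ft_alignment(matrix(0.3, 64, 64)), "degenerate")
  ff <- generate_fiber_field(n_fibers = 0, noise_sd = 0, background = 0.3,
                             seed = 1)
  expect_error(ft_alignment(ff$image), "degenerate")
})

test_that("mean eccentricity rises with orientation concentration", {
  kappas <- c(0, 4, 16)
  means <- vapply(kappas, function(k) {
    mean(vapply(1:5, function(s)
      ft_alignment(generate_fiber_field(kappa = k, seed = s)$image)$eccentricity,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("aligned fiber fields report the generator mean angle", {
  devs <- vapply(1:8, function(s) {
    ff <- generate_fiber_field(kappa = 16, mean_angle_deg = 30, seed = s)
    a <- ft_alignment(ff$image)$fiber_angle_deg
    (a - 30 + 90) %% 180 - 90
  }, numeric(1))
  expect_lt(abs(mean(devs)), 3)
})

test_that("per-cell alignment yields one joinable row per detection", {
  set.seed(10)
  tracks <- do.call(rbind, lapply(1:3, function(id)
    data.frame(track_id = id, t = 1:4, label = id,
               x_px = 60 + 20 * id, y_px = 60 + 15 * id, z_px = 2,
               x_um = 0, y_um = 0, z_um = 0, voxels = 50)))
  class(tracks) <- c("mmd_tracks", "data.frame")
  ff <- generate_fiber_field(ny = 160, nx = 160, kappa = 30,
                             mean_angle_deg = 30, n_z = 3, seed = 3)
  shg <- array(0, c(4, 3, 160, 160))
  for (t in 1:4) shg[t, , , ] <- ff$image
  series <- volume_series(list(SHG = shg), volume_metadata(1, 5, 5, "SHG"))
  res <- per_cell_alignment(tracks, series, tile_size = 100)
  expect_identical(nrow(res), 12L)
  expect_identical(res[, c("track_id", "t")],
                   tracks[, c("track_id", "t")], ignore_attr = TRUE)
  clean <- res[res$flag == "", ]
  expect_gt(nrow(clean), 0)
  devs <- (clean$fiber_angle_deg - 30 + 90) %% 180 - 90
  expect_lt(abs(mean(devs)), 5)
})

test_that("a cell over empty background is flagged, not fatal", {
  tracks <- data.frame(track_id = 1L, t = 1L, label = 1L,
                       x_px = 50, y_px = 50, z_px = 1,
                       x_um = 0, y_um = 0, z_um = 0, voxels = 10)
  shg <- array(0, c(1, 2, 100, 100))
  series <- volume_series(list(SHG = shg), volume_metadata(1))
  res <- per_cell_alignment(tracks, series)
  expect_identical(res$flag, "degenerate")
  expect_true(is.na(res$eccentricity))
})

test_that("tile export writes one TIFF per tile with a faithful manifest", {
  set.seed(11)
  ff <- generate_fiber_field(ny = 120, nx = 120, seed = 5)
  vol <- array(ff$image, c(1, 120, 120))
  vol3 <- aperm(array(vol, c(1, 120, 120)), c(1, 2, 3))
  tiles <- lapply(1:12, function(i)
    extract_tile(vol3, list(x_px = 30 + 5 * i, y_px = 60, z_px = 1,
                            track_id = ((i - 1) %% 6) + 1,
                            t = ((i - 1) %/% 6) + 1), 40))
  dir <- withr::local_tempdir()
  manifest <- export_tiles_for_ctfire(tiles, dir)
  expect_identical(nrow(manifest), 12L)
  expect_length(list.files(dir, pattern = "\\.tif$"), 12L)
  expect_false(any(duplicated(manifest$file)))
  # round-trip: re-reading an exported tile reproduces the array bit-exactly
  i <- 7
  back <- tiff::readTIFF(file.path(dir, manifest$file[i])) *
    manifest$scale[i]
  expect_identical(back, tiles[[i]]$image)
})

test_that("duplicate (track, t) keys get unambiguous suffixes", {
  img <- matrix(runif(100), 10, 10)
  vol <- array(img, c(1, 10, 10))
  tiles <- lapply(1:3, function(i)
    extract_tile(vol, list(x_px = 5, y_px = 5, z_px = 1,
                           track_id = 1, t = 1), 6))
  dir <- withr::local_tempdir()
  manifest <- export_tiles_for_ctfire(tiles, dir)
  expect_identical(length(unique(manifest$file)), 3L)
})
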