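meta1 <- volume_metadata(1, 5, 5, "TPF")

# hard-edged sphere volume for segmentation tests, centers in voxel indices
sphere_volume <- function(d, centers_px, radius_px, value = 1) {
  vol <- array(0, d)
  idx <- arrayInd(seq_along(vol), d)
  for (i in seq_len(nrow(centers_px))) {
    c_ <- centers_px[i, ]
    inside <- (idx[, 1] - c_[1])^2 + (idx[, 2] - c_[2])^2 +
      (idx[, 3] - c_[3])^2 <= radius_px^2
    vol[idx[inside, , drop = FALSE]] <- value
  }
  vol
}

test_that("two well-separated spheres give two detections at their centers", {
  d <- c(11, 40, 40)
  centers <- rbind(c(6, 10, 10), c(6, 30, 30))  # (z, y, x)
  vol <- sphere_volume(d, centers, 5)
  seg <- segment_cells(vol, meta1, threshold = 0.5, min_voxels = 27)
  det <- seg$detections
  expect_identical(nrow(det), 2L)
  expect_identical(det$label, 1:2)
  expect_lt(abs(det$y_px[1] - 10), 0.5)
  expect_lt(abs(det$x_px[1] - 10), 0.5)
  expect_lt(abs(det$z_px[1] - 6), 0.5)
  expect_lt(abs(det$x_px[2] - 30), 0.5)
  # physical conversion uses the anisotropic spacings
  expect_equal(det$z_um[1], (det$z_px[1] - 1) * 5)
  expect_equal(det$x_um[1], (det$x_px[1] - 1) * 1)
})

test_that("all-zero volume yields zero detections, not an error", {
  seg <- segment_cells(array(0, c(3, 8, 8)), meta1, threshold = 0.5)
  expect_identical(nrow(seg$detections), 0L)
  expect_true(all(seg$labels == 0L))
  expect_error(segment_cells(array(0, c(0, 8, 8)), meta1), "non-empty")
})

test_that("labels are contiguous and match the labeled volume", {
  d <- c(9, 30, 60)
  centers <- rbind(c(5, 15, 10), c(5, 15, 30), c(5, 15, 50))
  vol <- sphere_volume(d, centers, 4)
  seg <- segment_cells(vol, meta1, threshold = 0.5, min_voxels = 27)
  labs <- sort(unique(as.vector(seg$labels)))
  expect_identical(labs, c(0L, seg$detections$label))
  expect_identical(seg$detections$label, seq_len(nrow(seg$detections)))
  expect_identical(seg$detections$voxels,
                   as.integer(tabulate(seg$labels[seg$labels > 0])))
})

test_that("segmentation is invariant to below-threshold background noise", {
  set.seed(5)
  d <- c(7, 32, 32)
  vol <- sphere_volume(d, rbind(c(4, 16, 16)), 3)
  noisy <- vol + array(runif(prod(d), 0, 0.4), d)
  a <- segment_cells(vol, meta1, threshold = 0.5, min_voxels = 10)
  b <- segment_cells(noisy, meta1, threshold = 0.5, min_voxels = 10)
  expect_identical(a$detections$voxels, b$detections$voxels)
  expect_equal(a$detections$x_px, b$detections$x_px)
  expect_identical(a$labels, b$labels)
})

test_that("connectivity changes which diagonal voxels join a component", {
  vol <- array(0, c(3, 3, 3))
  vol[1, 1, 1] <- 1
  vol[2, 2, 2] <- 1  # corner-adjacent only
  lab26 <- label_components_3d(vol > 0, 26)
  lab6 <- label_components_3d(vol > 0, 6)
  expect_identical(max(lab26), 1L)
  expect_identical(max(lab6), 2L)
})

test_that("synthetic scene of 20 separated cells is recovered one-to-one", {
  cfg <- scene_config(n_cells = 20, n_time = 1, ny = 300, nx = 300,
                      motion = list(model = "drift", speed_um_min = 0,
                                    heading_deg = 0))
  scene <- generate_cell_scene(cfg, seed = 21)
  vol <- array(scene$series$channels$TPF[1, , , ], scene$series$dim[2:4])
  det <- segment_cells(vol, scene$series$metadata, time_index = 1)$detections
  expect_identical(nrow(det), 20L)
  truth <- scene$truth$trajectories
  d <- outer(seq_len(20), seq_len(20), Vectorize(function(i, j)
    sqrt((det$x_um[i] - truth$x_um[j])^2 + (det$y_um[i] - truth$y_um[j])^2 +
         (det$z_um[i] - truth$z_um[j])^2)))
  nearest <- apply(d, 1, which.min)
  expect_identical(sort(nearest), 1:20)           # a bijection
  expect_lt(max(apply(d, 1, min)), 1)             # each within 1 um
})

test_that("nearest link is chosen and ties break to the lowest label", {
  f1 <- data.frame(label = 1L, t = 1L, x_um = 0, y_um = 0, z_um = 0)
  f2 <- data.frame(label = 1:2, t = 2L, x_um = c(1, 5), y_um = c(0, 5),
                   z_um = c(0, 5))
  tr <- link_tracks(list(f1, f2), policy = "independent-nearest")
  expect_identical(tr$label[tr$track_id == 1], c(1L, 1L))
  expect_identical(tr$x_um[tr$track_id == 1][2], 1)
  # forced tie at distance 1
  f2b <- data.frame(label = c(2L, 1L), t = 2L, x_um = c(1, 0),
                    y_um = c(0, 1), z_um = c(0, 0))
  trb <- link_tracks(list(f1, f2b), policy = "independent-nearest")
  expect_identical(trb$label[trb$track_id == 1][2], 1L)
  trc <- link_tracks(list(f1, f2b), policy = "one-to-one-greedy")
  expect_identical(trc$label[trc$track_id == 1][2], 1L)
})

test_that("unclaimed detections seed new tracks; gated tracks terminate", {
  f1 <- data.frame(label = 1L, t = 1L, x_um = 0, y_um = 0, z_um = 0)
  f2 <- data.frame(label = 1:2, t = 2L, x_um = c(2, 50), y_um = 0, z_um = 0)
  tr <- link_tracks(list(f1, f2), gate_um = 10)
  st <- track_status(tr)
  expect_identical(nrow(st), 2L)
  expect_identical(st$start_t, c(1, 2))
  expect_true(all(st$complete))
  # tighten the gate: the original track terminates, both at t2 seed anew
  tr2 <- link_tracks(list(f1, f2), gate_um = 1)
  st2 <- track_status(tr2)
  expect_identical(nrow(st2), 3L)
  expect_true(st2$terminated_by_gate[1])
  expect_false(st2$complete[1])
})

test_that("independent-nearest linking matches the brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    frames <- random_detection_scene(sample(3:12, 1), sample(3:6, 1))
    got <- track_set_strings(
      link_tracks(frames, policy = "independent-nearest"))
    want <- bruteforce_nearest_tracks(frames)
    expect_identical(got, want)
  }
})

test_that("one-to-one-greedy claims each detection at most once", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    frames <- random_detection_scene(sample(3:10, 1), 4)
    tr <- link_tracks(frames, policy = "one-to-one-greedy")
    dup <- duplicated(tr[, c("t", "label")])
    expect_false(any(dup))
  }
})

test_that("instantaneous velocity follows the 3-4-5 identity", {
  tr <- data.frame(track_id = 1L, t = 1:2, x_um = c(0, 6), y_um = c(0, 8),
                   z_um = c(0, 0))
  expect_equal(instantaneous_velocity(tr, 5), 2.0)
  # stationary
  tr2 <- data.frame(track_id = 1L, t = 1:4, x_um = 1, y_um = 2, z_um = 3)
  expect_equal(instantaneous_velocity(tr2, 5), c(0, 0, 0))
  # single point -> empty series
  expect_length(instantaneous_velocity(tr[1, ], 5), 0)
})

test_that("velocity of a random walk equals independent pairwise distances", {
  set.seed(6)
  p <- matrix(cumsum(rnorm(15)), ncol = 3)
  tr <- data.frame(track_id = 1L, t = 1:5, x_um = p[, 1], y_um = p[, 2],
                   z_um = p[, 3])
  v <- instantaneous_velocity(tr, 2.5)
  manual <- vapply(1:4, function(i)
    sqrt(sum((p[i + 1, ] - p[i, ])^2)) / 2.5, numeric(1))
  expect_equal(v, manual)
  # path length >= net displacement (triangle inequality)
  expect_gte(sum(v) * 2.5, total_displacement(tr))
})

test_that("total displacement is net, not path length", {
  out_back <- data.frame(track_id = 1L, t = 1:3, x_um = c(0, 5, 0),
                         y_um = 0, z_um = 0)
  expect_equal(total_displacement(out_back), 0)
  straight <- data.frame(track_id = 1L, t = 1:3, x_um = c(0, 2, 4),
                         y_um = 0, z_um = 0)
  expect_equal(total_displacement(straight), 4)
  expect_warning(d <- total_displacement(straight[1, ]), "single-point")
  expect_equal(as.numeric(d), 0)
})

test_that("migration direction follows the flipped-y math convention", {
  mk <- function(dx, dy_phys) data.frame(
    track_id = 1L, t = 1:2, x_um = c(0, dx), y_um = c(0, -dy_phys),
    z_um = 0)
  expect_equal(migration_direction(mk(1, 1)), 45)
  expect_equal(migration_direction(mk(0, 1)), 90)
  expect_equal(migration_direction(mk(-1, 0)), 180)
  expect_equal(migration_direction(mk(0, -1)), 270)
  still <- mk(0, 0)
  ang <- migration_direction(still)
  expect_true(is.na(ang))
  expect_true(attr(ang, "undefined"))
})

test_that("population curve reports counts and fractional change", {
  det <- data.frame(t = rep(1:2, c(10, 15)), label = c(1:10, 1:15))
  pc <- population_curve(det)
  expect_equal(pc$count, c(10, 15))
  expect_equal(pc$fractional_change, c(0, 0.5))
  flat <- data.frame(t = rep(1:3, each = 4), label = rep(1:4, 3))
  expect_equal(population_curve(flat)$fractional_change, c(0, 0, 0))
  # empty first frame: undefined baseline flagged
  d0 <- data.frame(t = c(2L, 2L), label = 1:2)
  f1 <- data.frame(t = integer(0), label = integer(0))
  pc0 <- population_curve(rbind(f1, d0))
  expect_identical(pc0$count[1], 2L)  # frame 1 absent entirely
})

test_that("population counts match the generator birth schedule exactly", {
  cfg <- scene_config(n_cells = 5, n_time = 4, birth_per_frame = 2,
                      noise_sd = 0)
  scene <- generate_cell_scene(cfg, seed = 31)
  dets <- lapply(1:4, function(t)
    segment_cells(array(scene$series$channels$TPF[t, , , ],
                        scene$series$dim[2:4]),
                  scene$series$metadata, time_index = t)$detections)
  pc <- population_curve(dets)
  expect_equal(pc$count, c(5, 7, 9, 11))
  expect_equal(pc$fractional_change, (c(5, 7, 9, 11) - 5) / 5)
})

test_that("direction histogram bins tracks and excludes stationary ones", {
  mk <- function(id, dx, dy_phys) data.frame(
    track_id = id, t = 1:2, x_um = c(0, dx), y_um = c(0, -dy_phys), z_um = 0)
  tracks <- do.call(rbind, lapply(1:4, function(i) mk(i, 1, 1)))  # all 45 deg
  h <- direction_histogram(tracks, n_bins = 8)
  expect_equal(unname(h$counts[2]), 4)  # [45, 90)
  expect_equal(sum(h$counts), 4)
  expect_equal(h$excluded, 0)
  still <- do.call(rbind, lapply(1:3, function(i) mk(i, 0, 0)))
  h2 <- direction_histogram(still, n_bins = 8)
  expect_equal(sum(h2$counts), 0)
  expect_equal(h2$excluded, 3)
})

test_that("uniform directions give an approximately flat histogram", {
  set.seed(7)
  n <- 720
  ang <- runif(n, 0, 360)
  tracks <- do.call(rbind, lapply(seq_len(n), function(i) data.frame(
    track_id = i, t = 1:2, x_um = c(0, cos(ang[i] * pi / 180)),
    y_um = c(0, -sin(ang[i] * pi / 180)), z_um = 0)))
  h <- direction_histogram(tracks, n_bins = 8)
  p <- stats::chisq.test(h$counts)$p.value
  expect_gt(p, 0.001)
})

test_that("drift scenes recover speed and heading from pixels to physics", {
  res <- run_drift_recovery(seed = 41)
  expect_equal(link_accuracy(res$tracks, res$truth), 1)
  ms <- res$motility
  expect_lt(abs(mean(ms$mean_velocity_um_min) - 2) / 2, 0.05)
  dev <- (circ_mean_deg(ms$direction_deg) - 30 + 180) %% 360 - 180
  expect_lt(abs(dev), 5)
})
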