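# Independent brute-force oracle for nearest-neighbour linking, written as
# plain loops over all pairs so it shares no code with link_tracks().
# frames: list of data.frames with columns label, x_um, y_um, z_um.
# Returns a sorted character set, one string per track:
# "<start_t>:<label1>,<label2>,..."
bruteforce_nearest_tracks <- function(frames) {
  tracks <- list()   # each: list(start, labels, last_pos, last_t)
  f1 <- frames[[1]]
  for (i in order(f1$label)) {
    tracks[[length(tracks) + 1L]] <- list(
      start = 1L, labels = f1$label[i],
      pos = c(f1$x_um[i], f1$y_um[i], f1$z_um[i]), last_t = 1L)
  }
  for (f in seq_along(frames)[-1]) {
    det <- frames[[f]]
    claimed <- rep(FALSE, nrow(det))
    for (k in seq_along(tracks)) {
      if (tracks[[k]]$last_t != f - 1L) next
      best_d <- Inf
      best_i <- NA_integer_
      for (i in seq_len(nrow(det))) {
        d <- sqrt((det$x_um[i] - tracks[[k]]$pos[1])^2 +
                  (det$y_um[i] - tracks[[k]]$pos[2])^2 +
                  (det$z_um[i] - tracks[[k]]$pos[3])^2)
        if (d < best_d ||
            (d == best_d && det$label[i] < det$label[best_i])) {
          best_d <- d
          best_i <- i
        }
      }
      if (!is.na(best_i)) {
        tracks[[k]]$labels <- c(tracks[[k]]$labels, det$label[best_i])
        tracks[[k]]$pos <- c(det$x_um[best_i], det$y_um[best_i],
                             det$z_um[best_i])
        tracks[[k]]$last_t <- f
        claimed[best_i] <- TRUE
      }
    }
    for (i in which(!claimed)[order(det$label[!claimed])]) {
      tracks[[length(tracks) + 1L]] <- list(
        start = f, labels = det$label[i],
        pos = c(det$x_um[i], det$y_um[i], det$z_um[i]), last_t = f)
    }
  }
  sort(vapply(tracks, function(tr)
    sprintf("%d:%s", tr$start, paste(tr$labels, collapse = ",")),
    character(1)))
}

# canonical track-set string from a link_tracks() result, for comparison
# with the oracle
track_set_strings <- function(tracks) {
  sort(unname(vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$t), ]
    sprintf("%d:%s", min(tr$t), paste(tr$label, collapse = ","))
  }, character(1))))
}

# random detection-level scene: cells appear/disappear, labels shuffled
# per frame
random_detection_scene <- function(n_cells, n_frames, step_max = 15,
                                   extent = 100) {
  pos <- matrix(runif(n_cells * 3, 0, extent), ncol = 3)
  alive_from <- sample(c(rep(1L, max(1L, n_cells - 2L)),
                         sample.int(n_frames, min(2L, n_cells - 1L),
                                    replace = TRUE)))[seq_len(n_cells)]
  alive_to <- pmax(alive_from,
                   n_frames - sample(c(0L, 0L, 0L, 1L), n_cells,
                                     replace = TRUE))
  # cell 1 spans the whole movie so no frame is ever empty
  alive_from[1] <- 1L
  alive_to[1] <- n_frames
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (f > 1L) {
      step <- matrix(runif(n_cells * 3, -step_max, step_max), ncol = 3)
      pos <- pmin(pmax(pos + step, 0), extent)
    }
    idx <- which(alive_from <= f & f <= alive_to)
    labs <- sample(seq_along(idx))
    frames[[f]] <- data.frame(label = labs, t = f,
                              x_um = pos[idx, 1], y_um = pos[idx, 2],
                              z_um = pos[idx, 3])[order(labs), ]
  }
  frames
}

circ_mean_deg <- function(deg) {
  r <- deg * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

# drift scene -> (tracks, motility, truth); shared by unit and acceptance
# tests
run_drift_recovery <- function(seed, n_cells = 10, n_time = 6) {
  cfg <- scene_config(n_cells = n_cells, n_time = n_time)
  scene <- generate_cell_scene(cfg, seed = seed)
  meta <- scene$series$metadata
  d <- scene$series$dim
  dets <- lapply(seq_len(d[1]), function(t)
    segment_cells(array(scene$series$channels$TPF[t, , , ], d[2:4]),
                  meta, time_index = t)$detections)
  tracks <- link_tracks(dets, policy = "independent-nearest")
  list(tracks = tracks,
       motility = motility_summary(tracks, meta$frame_interval),
       truth = scene$truth, meta = meta)
}

# fraction of links agreeing with ground truth: every track must follow one
# true cell for its whole life (match by nearest true position per frame)
link_accuracy <- function(tracks, truth, tol_um = 2) {
  ok_tracks <- vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$t), ]
    ids <- vapply(seq_len(nrow(tr)), function(i) {
      tt <- truth$trajectories[truth$trajectories$t == tr$t[i], ]
      d <- sqrt((tt$x_um - tr$x_um[i])^2 + (tt$y_um - tr$y_um[i])^2 +
                (tt$z_um - tr$z_um[i])^2)
      if (min(d) > tol_um) return(NA_integer_)
      tt$cell[which.min(d)]
    }, integer(1))
    !anyNA(ids) && length(unique(ids)) == 1L
  }, logical(1))
  mean(ok_tracks)
}
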