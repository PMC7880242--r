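# half-neighbourhood voxel offsets (dz, dy, dx); scanning only the "forward"
# half of each neighbourhood visits every voxel pair once
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1,
    "18" = rowSums(abs(g)) <= 2,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be one of 6, 18, 26"))
  g <- g[keep, , drop = FALSE]
  # lexicographically positive half
  half <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g[half, , drop = FALSE]
}

#' Label connected components in a 3D binary mask
#'
#' Connected-component labelling of foreground voxels under 6-, 18- or
#' 26-connectivity. Labels are contiguous from 1 and assigned in order of
#' each component's first voxel in array scan order, so relabelling is
#' deterministic across runs.
#'
#' @param mask Logical (z, y, x) array.
#' @param connectivity One of 6, 18, 26 (face / face+edge / full neighbours).
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  n <- length(fg)
  if (n == 0L) return(lab)
  idmap <- array(0L, d)
  idmap[fg] <- seq_len(n)
  coord <- arrayInd(fg, d)
  offs <- connectivity_offsets(connectivity)
  from <- vector("list", nrow(offs))
  to <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nz <- coord[, 1] + offs[k, 1]
    ny <- coord[, 2] + offs[k, 2]
    nx <- coord[, 3] + offs[k, 3]
    ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] & nx >= 1L & nx <= d[3]
    if (!any(ok)) next
    nb <- idmap[cbind(nz[ok], ny[ok], nx[ok])]
    hit <- nb > 0L
    from[[k]] <- which(ok)[hit]
    to[[k]] <- nb[hit]
  }
  from <- unlist(from)
  to <- unlist(to)
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel so component 1 owns the smallest linear voxel index
  first <- vapply(split(fg, memb), min, numeric(1))
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  lab[fg] <- relab[memb]
  lab
}

otsu_threshold <- function(volume) {
  rng <- range(volume)
  if (diff(rng) == 0) return(rng[2])  # constant volume: nothing above
  v01 <- (as.vector(volume) - rng[1]) / diff(rng)
  th01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1L)),
                        range = c(0, 1))
  rng[1] + th01 * diff(rng)
}

#' Threshold-based 3D cell segmentation
#'
#' Segments bright cells in a single-channel, single-time-point volume:
#' voxels strictly above the threshold are grouped into connected components,
#' components smaller than `min_voxels` are discarded as noise, and each
#' surviving component becomes a detection carrying a numerical tag and its
#' 3D centroid. Centroids are the unweighted mean voxel position, reported
#' both as 1-based voxel indices and in physical micrometres
#' (`(index - 1) * spacing`); the micrometre form is canonical for all
#' distance computations because axial and lateral samplings differ.
#'
#' @param volume Numeric (z, y, x) array, one channel at one time point.
#' @param metadata A [volume_metadata()] supplying voxel sizes.
#' @param threshold Numeric intensity cutoff, or `"otsu"` (default) for an
#'   automatic histogram threshold computed on this volume.
#' @param min_voxels Minimum component size kept, default 27 (about a 3^3
#'   neighbourhood) to suppress shot noise.
#' @param connectivity Voxel connectivity for components: 6, 18 or 26
#'   (default).
#' @param time_index 1-based frame number recorded on each detection.
#' @return An object of class `segmentation_result`: `labels` (integer
#'   (z, y, x) array, labels contiguous from 1), `detections` (data frame
#'   with columns label, t, x_px, y_px, z_px, x_um, y_um, z_um, voxels), and
#'   `params`. No above-threshold voxels yields zero detections, not an
#'   error.
#' @export
segment_cells <- function(volume, metadata, threshold = "otsu",
                          min_voxels = 27, connectivity = 26,
                          time_index = 1L) {
  if (!is.array(volume) || length(dim(volume)) != 3L || length(volume) == 0L)
    stop("`volume` must be a non-empty (z, y, x) array")
  stopifnot(inherits(metadata, "volume_metadata"), min_voxels >= 1)
  if (identical(threshold, "otsu") || identical(threshold, "auto")) {
    thr <- otsu_threshold(volume)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    thr <- threshold
  }
  lab <- label_components_3d(volume > thr, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0L) {
    lab[] <- 0L
    det <- data.frame(label = integer(0), t = integer(0),
                      x_px = numeric(0), y_px = numeric(0), z_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      voxels = integer(0))
  } else {
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
    idx <- which(lab > 0L)
    coord <- arrayInd(idx, dim(lab))
    lb <- lab[idx]
    cz <- vapply(split(coord[, 1], lb), mean, numeric(1))
    cy <- vapply(split(coord[, 2], lb), mean, numeric(1))
    cx <- vapply(split(coord[, 3], lb), mean, numeric(1))
    det <- data.frame(
      label = sort(unique(lb)), t = as.integer(time_index),
      x_px = cx, y_px = cy, z_px = cz,
      x_um = (cx - 1) * metadata$voxel_size_xy,
      y_um = (cy - 1) * metadata$voxel_size_xy,
      z_um = (cz - 1) * metadata$voxel_size_z,
      voxels = sizes[keep], row.names = NULL)
  }
  structure(list(labels = lab, detections = det,
                 params = list(threshold = thr, min_voxels = min_voxels,
                               connectivity = connectivity)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result: %d detection(s), threshold %.4g, min %d voxels, %d-connectivity\n",
    nrow(x$detections), x$params$threshold, x$params$min_voxels,
    x$params$connectivity))
  invisible(x)
}

# detections for all time points into one canonical data frame
bind_detections <- function(detections_by_time) {
  if (is.data.frame(detections_by_time)) return(detections_by_time)
  dfs <- lapply(detections_by_time, function(d) {
    if (inherits(d, "segmentation_result")) d$detections else d
  })
  do.call(rbind, dfs)
}

#' Link detections across time by nearest-neighbour centroid distance
#'
#' Builds time-lapse tracks frame to frame: each tracked cell at time t is
#' matched to the detection at t + 1 that minimises 3D Euclidean distance in
#' physical micrometres. Two assignment policies are available.
#' `"independent-nearest"` applies the minimum-distance rule to every track
#' independently, so in dense fields two tracks may claim the same cell.
#' `"one-to-one-greedy"` (default) sorts all candidate pairs by distance and
#' claims each detection at most once, which avoids that failure mode.
#' Detections at t + 1 claimed by no track seed new tracks; a track with no
#' candidate within `gate_um` terminates.
#'
#' Ties in distance are broken by the lowest candidate label, so reruns are
#' deterministic.
#'
#' @param detections_by_time A list of per-frame detection sets (data frames
#'   or `segmentation_result`s), or one combined data frame with a `t`
#'   column. Frames are 1-based and consecutive.
#' @param gate_um Maximum allowed link distance in um; `Inf` (default)
#'   disables gating, matching the plain nearest-neighbour rule. A practical
#'   gate is about 3x the median per-frame displacement.
#' @param policy `"one-to-one-greedy"` or `"independent-nearest"`.
#' @return A data frame of class `mmd_tracks` with columns `track_id`,
#'   `t`, `label`, `x_px`, `y_px`, `z_px`, `x_um`, `y_um`, `z_um`, `voxels`,
#'   sorted by (track_id, t), with a per-track `status` data frame attached
#'   as attribute `"status"` (columns track_id, start_t, end_t, n_points,
#'   complete, terminated_by_gate).
#' @export
link_tracks <- function(detections_by_time, gate_um = Inf,
                        policy = c("one-to-one-greedy",
                                   "independent-nearest")) {
  policy <- match.arg(policy)
  det <- bind_detections(detections_by_time)
  need <- c("label", "t", "x_um", "y_um", "z_um")
  if (!all(need %in% names(det)))
    stop("detections need columns: ", paste(need, collapse = ", "))
  for (col in setdiff(c("x_px", "y_px", "z_px", "voxels"), names(det)))
    det[[col]] <- NA_real_
  times <- sort(unique(det$t))
  rows_of <- function(t) det[det$t == t, , drop = FALSE]
  next_id <- 1L
  tracks <- list()   # track_id -> data.frame of detection rows
  gated <- logical(0)
  seed_tracks <- function(rows) {
    rows <- rows[order(rows$label), , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      tracks[[next_id]] <<- rows[i, , drop = FALSE]
      gated[next_id] <<- FALSE
      next_id <<- next_id + 1L
    }
  }
  if (length(times) > 0L) seed_tracks(rows_of(times[1]))
  for (ti in seq_along(times)[-1]) {
    cand <- rows_of(times[ti])
    cand <- cand[order(cand$label), , drop = FALSE]
    active <- which(vapply(tracks, function(tr) max(tr$t), numeric(1)) ==
                      times[ti - 1])
    claimed <- logical(nrow(cand))
    if (length(active) > 0L && nrow(cand) > 0L) {
      last <- do.call(rbind, lapply(tracks[active],
                                    function(tr) tr[nrow(tr), c("x_um", "y_um", "z_um")]))
      dmat <- outer(seq_len(nrow(last)), seq_len(nrow(cand)),
                    Vectorize(function(i, j)
                      sqrt(sum((as.numeric(last[i, ]) -
                                  as.numeric(cand[j, c("x_um", "y_um", "z_um")]))^2))))
      if (policy == "independent-nearest") {
        for (i in seq_along(active)) {
          j <- which.min(dmat[i, ])  # ties: first index = lowest label
          if (dmat[i, j] <= gate_um) {
            tracks[[active[i]]] <- rbind(tracks[[active[i]]],
                                         cand[j, , drop = FALSE])
            claimed[j] <- TRUE
          } else {
            gated[active[i]] <- TRUE
          }
        }
      } else {
        ord <- order(as.vector(dmat))  # column-major: ties fall to lower track
        used_tr <- logical(length(active))
        for (k in ord) {
          i <- (k - 1L) %% nrow(dmat) + 1L
          j <- (k - 1L) %/% nrow(dmat) + 1L
          if (used_tr[i] || claimed[j]) next
          if (dmat[i, j] > gate_um) break
          tracks[[active[i]]] <- rbind(tracks[[active[i]]],
                                       cand[j, , drop = FALSE])
          used_tr[i] <- TRUE
          claimed[j] <- TRUE
        }
        gated[active[!used_tr]] <- TRUE
      }
    }
    if (any(!claimed)) seed_tracks(cand[!claimed, , drop = FALSE])
  }
  if (length(tracks) == 0L) {
    out <- data.frame(track_id = integer(0), t = integer(0))
    attr(out, "status") <- data.frame()
    class(out) <- c("mmd_tracks", "data.frame")
    return(out)
  }
  out <- do.call(rbind, Map(function(id, tr) {
    tr$track_id <- id
    tr
  }, seq_along(tracks), tracks))
  out <- out[, c("track_id", setdiff(names(out), "track_id"))]
  out <- out[order(out$track_id, out$t), , drop = FALSE]
  rownames(out) <- NULL
  t_end <- if (length(times)) max(times) else NA_integer_
  status <- data.frame(
    track_id = seq_along(tracks),
    start_t = vapply(tracks, function(tr) min(tr$t), numeric(1)),
    end_t = vapply(tracks, function(tr) max(tr$t), numeric(1)),
    n_points = vapply(tracks, nrow, integer(1)))
  status$complete <- status$end_t == t_end
  status$terminated_by_gate <- gated[status$track_id]
  attr(out, "status") <- status
  class(out) <- c("mmd_tracks", "data.frame")
  out
}

#' Per-track status table from a linking result
#'
#' @param tracks Result of [link_tracks()].
#' @return Data frame with one row per track: start/end frame, length,
#'   whether the track reached the final frame, and whether it was
#'   terminated by the distance gate.
#' @export
track_status <- function(tracks) attr(tracks, "status")

track_one <- function(tracks, track_id = NULL) {
  tr <- if (!is.null(track_id)) tracks[tracks$track_id == track_id, ,
                                       drop = FALSE] else tracks
  if (!is.null(tr$track_id) && length(unique(tr$track_id)) > 1L)
    stop("supply `track_id` when `tracks` holds more than one track")
  tr[order(tr$t), , drop = FALSE]
}

#' Instantaneous velocity along a track
#'
#' Frame-to-frame speed: the 3D Euclidean centroid displacement in um divided
#' by the frame interval in minutes.
#'
#' @param tracks A track data frame (one track, or pass `track_id`).
#' @param frame_interval Minutes between frames.
#' @param track_id Track to select when `tracks` holds several.
#' @return Numeric vector of um/min, one element per frame pair (length
#'   `n_points - 1`; empty for a single-point track).
#' @export
instantaneous_velocity <- function(tracks, frame_interval, track_id = NULL) {
  stopifnot(frame_interval > 0)
  tr <- track_one(tracks, track_id)
  n <- nrow(tr)
  if (n < 2L) return(numeric(0))
  p <- as.matrix(tr[, c("x_um", "y_um", "z_um")])
  unname(sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))) /
    frame_interval
}

#' Total (net) displacement of a track
#'
#' Straight-line 3D distance in um between the first and last centroid —
#' net displacement, not path length, so an out-and-back excursion scores 0.
#'
#' @inheritParams instantaneous_velocity
#' @return Length of the first-to-last displacement vector in um. For a
#'   single-point track, 0 with attribute `single_point = TRUE` and a
#'   warning.
#' @export
total_displacement <- function(tracks, track_id = NULL) {
  tr <- track_one(tracks, track_id)
  if (nrow(tr) < 2L) {
    warning("single-point track: total displacement reported as 0")
    return(structure(0, single_point = TRUE))
  }
  p <- as.matrix(tr[, c("x_um", "y_um", "z_um")])
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' Migration direction of a track
#'
#' Four-quadrant inverse tangent of the net lateral displacement, in degrees
#' counter-clockwise from +x in [0, 360). Because row indices grow downward
#' in image arrays, the y component is negated first so angles follow the
#' mathematical convention (90 degrees points "up" in the displayed image).
#'
#' @inheritParams instantaneous_velocity
#' @return Angle in degrees, or `NA` with attribute `undefined = TRUE` when
#'   the track has no net lateral displacement.
#' @export
migration_direction <- function(tracks, track_id = NULL) {
  tr <- track_one(tracks, track_id)
  dx <- tr$x_um[nrow(tr)] - tr$x_um[1]
  dy <- -(tr$y_um[nrow(tr)] - tr$y_um[1])  # flip image-row axis to math y
  if (dx == 0 && dy == 0)
    return(structure(NA_real_, undefined = TRUE))
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Cell population counts and fractional change over time
#'
#' @param detections_by_time Per-frame detection sets (as in
#'   [link_tracks()]) or a combined data frame with a `t` column.
#' @return Data frame with columns `t`, `count`, `fractional_change` where
#'   `fractional_change = (count_t - count_1) / count_1`. If the first frame
#'   has zero detections the fractional change is `NA` and attribute
#'   `undefined_baseline = TRUE` is set.
#' @export
population_curve <- function(detections_by_time) {
  det <- bind_detections(detections_by_time)
  times <- sort(unique(det$t))
  if (length(times) == 0L) stop("no detections supplied")
  counts <- vapply(times, function(t) sum(det$t == t), integer(1))
  out <- data.frame(t = times, count = counts)
  if (counts[1] == 0L) {
    out$fractional_change <- NA_real_
    attr(out, "undefined_baseline") <- TRUE
  } else {
    out$fractional_change <- (counts - counts[1]) / counts[1]
  }
  out
}

#' Polar histogram of track migration directions
#'
#' Bins per-track [migration_direction()] angles into equal-width sectors
#' over [0, 360). Tracks without a defined direction (no net lateral motion)
#' are excluded and counted separately.
#'
#' @param tracks Result of [link_tracks()].
#' @param n_bins Number of angular bins, default 8.
#' @return List with `counts` (named by sector `[lo,hi)`), `breaks` in
#'   degrees, and `excluded` (number of undefined-direction tracks).
#' @export
direction_histogram <- function(tracks, n_bins = 8) {
  stopifnot(n_bins >= 1)
  ids <- unique(tracks$track_id)
  ang <- vapply(ids, function(id) migration_direction(tracks, id), numeric(1))
  ok <- !is.na(ang)
  breaks <- seq(0, 360, length.out = n_bins + 1)
  counts <- if (any(ok)) {
    tabulate(findInterval(ang[ok], breaks, rightmost.closed = FALSE),
             nbins = n_bins)
  } else {
    integer(n_bins)
  }
  names(counts) <- sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1])
  list(counts = counts, breaks = breaks, excluded = sum(!ok))
}

#' Per-track motility summary
#'
#' One row per track: mean and maximum instantaneous velocity, net
#' displacement, and migration direction.
#'
#' @param tracks Result of [link_tracks()].
#' @param frame_interval Minutes between frames.
#' @return Data frame with columns `track_id`, `n_points`,
#'   `mean_velocity_um_min`, `max_velocity_um_min`, `total_displacement_um`,
#'   `direction_deg`, `direction_defined`.
#' @export
motility_summary <- function(tracks, frame_interval) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- track_one(tracks, id)
    v <- instantaneous_velocity(tr, frame_interval)
    disp <- if (nrow(tr) >= 2L) total_displacement(tr) else 0
    ang <- migration_direction(tr)
    data.frame(track_id = id, n_points = nrow(tr),
               mean_velocity_um_min = if (length(v)) mean(v) else NA_real_,
               max_velocity_um_min = if (length(v)) max(v) else NA_real_,
               total_displacement_um = as.numeric(disp),
               direction_deg = as.numeric(ang),
               direction_defined = !is.na(ang))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
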