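config_error <- function(msg) {
  stop(structure(class = c("mmd_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

data_error <- function(msg) {
  stop(structure(class = c("mmd_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    config_error(sprintf("unknown key(s) in %s: %s", where,
                         paste(extra, collapse = ", ")))
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' A pipeline run is described by one configuration (typically a YAML file):
#' where the data comes from (a synthetic scene block or input file paths),
#' an optional shared ROI, and one parameter block per analysis stage.
#' Unknown keys anywhere are rejected before any computation so typos fail
#' fast. Omitting a stage block skips that stage (and its output columns).
#'
#' @param x Path to a YAML file, or a list with (any of) the fields `seed`,
#'   `out_dir`, `simulate` (sub-blocks `cells`, `fibers`, `flim` with
#'   generator arguments), `inputs` (`meta_json`, `flim` with
#'   `intensity`/`lifetime` paths), `roi` (x_min/x_max/y_min/y_max),
#'   `segmentation` (`threshold`, `min_voxels`, `connectivity`), `tracking`
#'   (`gate_um`, `policy`), `collagen` (`tile_size`, `threshold_frac`,
#'   `window`, `min_valid_fraction`, `export_dir`), `flim` (`n_areas`,
#'   `area_size`, `intensity_min`, `areas_json`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) config_error(sprintf("config file '%s' not found", x))
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) config_error("config must be a list or a YAML file path")
  check_keys(x, c("seed", "out_dir", "simulate", "inputs", "roi",
                  "segmentation", "tracking", "collagen", "flim"), "config")
  if (is.null(x$seed)) x$seed <- 1L
  x$seed <- as.integer(x$seed)
  if (is.null(x$simulate) && is.null(x$inputs))
    config_error("config needs either a `simulate` or an `inputs` block")
  if (!is.null(x$simulate)) {
    check_keys(x$simulate, c("cells", "fibers", "flim"), "simulate")
    if (!is.null(x$simulate$cells))
      check_keys(x$simulate$cells, names(formals(scene_config)),
                 "simulate$cells")
    if (!is.null(x$simulate$fibers))
      check_keys(x$simulate$fibers, names(formals(generate_fiber_field)),
                 "simulate$fibers")
    if (!is.null(x$simulate$flim))
      check_keys(x$simulate$flim, names(formals(generate_lifetime_map)),
                 "simulate$flim")
  }
  if (!is.null(x$inputs))
    check_keys(x$inputs, c("meta_json", "flim"), "inputs")
  if (!is.null(x$roi))
    check_keys(x$roi, c("x_min", "x_max", "y_min", "y_max"), "roi")
  if (!is.null(x$segmentation))
    check_keys(x$segmentation, c("threshold", "min_voxels", "connectivity"),
               "segmentation")
  if (!is.null(x$tracking))
    check_keys(x$tracking, c("gate_um", "policy"), "tracking")
  if (!is.null(x$collagen))
    check_keys(x$collagen, c("tile_size", "threshold_frac", "window",
                             "min_valid_fraction", "export_dir"), "collagen")
  if (!is.null(x$flim))
    check_keys(x$flim, c("n_areas", "area_size", "intensity_min",
                         "areas_json"), "flim")
  structure(x, class = "pipeline_config")
}

# canonical JSON -> md5, so logically identical configs hash identically;
# out_dir is excluded because the analysis does not depend on it
config_hash <- function(config) {
  config$out_dir <- NULL
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(canon(unclass(config)), tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# mmd %s config_hash=%s seed=%d",
                     as.character(utils::packageVersion("mmd")), hash, seed),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

arg_or <- function(block, name, default) {
  if (is.null(block) || is.null(block[[name]])) default else block[[name]]
}

#' Run the multimodal analysis pipeline
#'
#' Orchestrates the full workflow on one co-registered dataset: segment
#' cells per frame on the tracking channel, link them into tracks, derive
#' motility statistics, quantify cell-centered collagen alignment on the
#' SHG channel, compute area-based FLIM region statistics, and join
#' everything into one multimodal table keyed by (track_id, t). All outputs
#' are written to `out_dir` as CSVs stamped with the package version, a
#' config hash and the seed; a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config A [pipeline_config()] (or list / YAML path coerced by it).
#' @param stages Character subset of `c("segment", "track", "collagen",
#'   "flim")`; prerequisites are added automatically. Default: all stages
#'   whose inputs and config blocks are present.
#' @return Invisibly, a list: `table` (the multimodal data frame), `tracks`,
#'   `motility`, `collagen`, `flim`, `population`, `paths` of written files,
#'   `config_hash`.
#' @export
run_pipeline <- function(config, stages = c("segment", "track", "collagen",
                                            "flim")) {
  config <- pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  if ("collagen" %in% stages) stages <- union(stages, "track")
  if ("track" %in% stages) stages <- union(stages, "segment")
  hash <- config_hash(config)
  seed <- config$seed
  out_dir <- if (is.null(config$out_dir)) tempfile("mmd_run_") else
    config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  log_lines <- c(sprintf("mmd pipeline, config_hash=%s seed=%d", hash, seed))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      data_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  set.seed(seed)

  # ---- acquire ----
  flim <- NULL
  flim_truth <- NULL
  series <- NULL
  stage("acquire", {
    if (!is.null(config$simulate)) {
      cells_cfg <- do.call(scene_config,
                           c(arg_or(config$simulate, "cells", list()),
                             list(seed = seed)))
      scene <- generate_cell_scene(cells_cfg)
      channels <- scene$series$channels
      if (!is.null(config$simulate$fibers)) {
        fargs <- config$simulate$fibers
        fargs$ny <- cells_cfg$ny; fargs$nx <- cells_cfg$nx
        fargs$n_z <- cells_cfg$n_z
        fargs$seed <- seed + 1L
        ff <- do.call(generate_fiber_field, fargs)
        shg <- array(0, dim(channels$TPF))
        for (t in seq_len(cells_cfg$n_time)) shg[t, , , ] <- ff$image
        channels$SHG <- shg
      }
      series <- volume_series(channels, scene$series$metadata)
      if (!is.null(config$simulate$flim)) {
        margs <- config$simulate$flim
        margs$ny <- cells_cfg$ny; margs$nx <- cells_cfg$nx
        margs$seed <- seed + 2L
        lm <- do.call(generate_lifetime_map, margs)
        flim <- lm$flim
        flim_truth <- lm$truth
      }
      truth_csv <- file.path(out_dir, "ground_truth.csv")
      write_stamped_csv(scene$truth$trajectories, truth_csv, hash, seed)
      paths["ground_truth"] <- truth_csv
      say("acquire: simulated scene, %d frames, %d initial cells",
          cells_cfg$n_time, cells_cfg$n_cells)
    } else {
      series <- read_volume_series(meta_json = config$inputs$meta_json)
      if (!is.null(config$inputs$flim))
        flim <- read_flim_image(config$inputs$flim$intensity,
                                 config$inputs$flim$lifetime,
                                 arg_or(config$inputs$flim, "pixel_size", 1))
      say("acquire: read %d channel(s) from disk", length(series$channels))
    }
  })

  # ---- shared ROI ----
  roi <- NULL
  if (!is.null(config$roi)) {
    stage("roi", {
      roi <- roi_spec(config$roi$x_min, config$roi$x_max,
                       config$roi$y_min, config$roi$y_max)
      series <- apply_roi(series, roi)
      if (!is.null(flim)) flim <- apply_roi(flim, roi)
      if (!is.null(flim_truth))
        flim_truth$region_masks <- lapply(flim_truth$region_masks,
                                           function(m) apply_roi(m, roi))
      write_roi(roi, file.path(out_dir, "roi.json"))
      paths["roi"] <- file.path(out_dir, "roi.json")
      say("roi: x [%d, %d], y [%d, %d] applied to all modalities",
          roi$x_min, roi$x_max, roi$y_min, roi$y_max)
    })
  }

  meta <- series$metadata
  detections <- NULL
  tracks <- NULL
  motility <- NULL
  pop <- NULL
  collagen <- NULL
  flim_stats <- NULL

  if ("segment" %in% stages) stage("segment", {
    if (!"TPF" %in% names(series$channels))
      stop("no TPF channel to segment")
    seg_par <- config$segmentation
    dets <- lapply(seq_len(series$dim[1]), function(t) {
      vol <- array(series$channels$TPF[t, , , ], series$dim[2:4])
      segment_cells(vol, meta,
                    threshold = arg_or(seg_par, "threshold", "otsu"),
                    min_voxels = arg_or(seg_par, "min_voxels", 27),
                    connectivity = arg_or(seg_par, "connectivity", 26),
                    time_index = t)$detections
    })
    detections <- do.call(rbind, dets)
    if (nrow(detections) == 0L) stop("no cells detected in any frame")
    pop <- population_curve(detections)
    write_stamped_csv(detections, file.path(out_dir, "detections.csv"),
                      hash, seed)
    write_stamped_csv(pop, file.path(out_dir, "population.csv"), hash, seed)
    paths["detections"] <- file.path(out_dir, "detections.csv")
    paths["population"] <- file.path(out_dir, "population.csv")
    say("segment: %d detections over %d frames", nrow(detections),
        series$dim[1])
  })

  if ("track" %in% stages) stage("track", {
    tr_par <- config$tracking
    gate <- arg_or(tr_par, "gate_um", Inf)
    if (is.null(gate) || !is.finite(gate)) gate <- Inf
    tracks <- link_tracks(detections, gate_um = gate,
                           policy = arg_or(tr_par, "policy",
                                           "one-to-one-greedy"))
    motility <- motility_summary(tracks, meta$frame_interval)
    write_stamped_csv(as.data.frame(tracks), file.path(out_dir, "tracks.csv"),
                      hash, seed)
    write_stamped_csv(motility, file.path(out_dir, "motility.csv"),
                      hash, seed)
    paths["tracks"] <- file.path(out_dir, "tracks.csv")
    paths["motility"] <- file.path(out_dir, "motility.csv")
    say("track: %d tracks", nrow(motility))
  })

  if ("collagen" %in% stages && "SHG" %in% names(series$channels) &&
      !is.null(tracks)) stage("collagen", {
    cg <- config$collagen
    collagen <- per_cell_alignment(
      tracks, series, channel = "SHG",
      tile_size = arg_or(cg, "tile_size", 200),
      threshold_frac = arg_or(cg, "threshold_frac", 0.2),
      window = arg_or(cg, "window", "hann"),
      min_valid_fraction = arg_or(cg, "min_valid_fraction", 0.5))
    write_stamped_csv(collagen, file.path(out_dir, "collagen.csv"),
                      hash, seed)
    paths["collagen"] <- file.path(out_dir, "collagen.csv")
    if (!is.null(cg$export_dir)) {
      tiles <- lapply(seq_len(nrow(tracks)), function(i) {
        row <- tracks[i, , drop = FALSE]
        vol <- array(series$channels$SHG[row$t, , , ], series$dim[2:4])
        extract_tile(vol, row, arg_or(cg, "tile_size", 200))
      })
      export_tiles_for_ctfire(tiles, cg$export_dir)
      say("collagen: exported %d tiles to %s", length(tiles), cg$export_dir)
    }
    say("collagen: %d cell-centered alignment rows", nrow(collagen))
  })

  if ("flim" %in% stages && !is.null(flim) && !is.null(config$flim))
    stage("flim", {
      fb <- config$flim
      selection <- if (!is.null(fb$areas_json)) {
        read_area_selection(fb$areas_json)
      } else if (!is.null(flim_truth)) {
        n_areas <- arg_or(fb, "n_areas", 5)
        area_size <- arg_or(fb, "area_size", 10)
        sel <- lapply(seq_along(flim_truth$region_masks), function(i)
          sample_random_areas(flim_truth$region_masks[[i]], n_areas,
                              area_size, seed = seed + 10L + i))
        names(sel) <- names(flim_truth$region_masks)
        sel
      } else {
        stop("flim stage needs `areas_json` when regions are not simulated")
      }
      flim_stats <- region_mean_of_means(flim, selection,
                                          intensity_min = fb$intensity_min)
      write_stamped_csv(flim_stats$areas, file.path(out_dir, "flim_areas.csv"),
                        hash, seed)
      write_stamped_csv(flim_stats$regions,
                        file.path(out_dir, "flim_regions.csv"), hash, seed)
      paths["flim_areas"] <- file.path(out_dir, "flim_areas.csv")
      paths["flim_regions"] <- file.path(out_dir, "flim_regions.csv")
      attr(flim_stats, "selection") <- selection
      say("flim: %d region(s), mean-of-means computed",
          nrow(flim_stats$regions))
    })

  # ---- join ----
  table <- NULL
  if (!is.null(tracks)) stage("join", {
    table <- build_multimodal_table(tracks, meta, collagen, flim_stats)
    write_stamped_csv(table, file.path(out_dir, "multimodal_table.csv"),
                      hash, seed)
    paths["multimodal_table"] <- file.path(out_dir, "multimodal_table.csv")
    say("join: multimodal table with %d rows", nrow(table))
  })

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths["run_log"] <- file.path(out_dir, "run_log.txt")
  invisible(list(table = table, tracks = tracks, motility = motility,
                 collagen = collagen, flim = flim_stats, population = pop,
                 detections = detections, paths = paths,
                 config_hash = hash, out_dir = out_dir))
}

# one row per (track_id, t); flags accumulate, never silent NA
build_multimodal_table <- function(tracks, meta, collagen = NULL,
                                   flim_stats = NULL) {
  tab <- as.data.frame(tracks)
  tab$flag <- ""
  add_flag <- function(flags, idx, what) {
    flags[idx] <- ifelse(nzchar(flags[idx]), paste(flags[idx], what,
                                                   sep = ";"), what)
    flags
  }
  tab$velocity_um_min <- NA_real_
  for (id in unique(tab$track_id)) {
    sel <- which(tab$track_id == id)
    sel <- sel[order(tab$t[sel])]
    if (length(sel) >= 2L) {
      v <- instantaneous_velocity(tab[sel, ], meta$frame_interval)
      tab$velocity_um_min[sel[-1]] <- v
    }
    tab$flag <- add_flag(tab$flag, sel[1], "first_point")
  }
  if (!is.null(collagen)) {
    m <- match(paste(tab$track_id, tab$t),
               paste(collagen$track_id, collagen$t))
    tab$eccentricity <- collagen$eccentricity[m]
    tab$fiber_angle_deg <- collagen$fiber_angle_deg[m]
    cflag <- collagen$flag[m]
    bad <- which(!is.na(cflag) & nzchar(cflag))
    tab$flag <- add_flag(tab$flag, bad, paste0("collagen_", cflag[bad]))
  }
  if (!is.null(flim_stats)) {
    sel <- attr(flim_stats, "selection")
    # nearest region: centroid of each region's sampled areas, in pixels
    cent <- t(vapply(sel, function(areas) {
      b <- vapply(areas, function(a)
        c((a$x_min + a$x_max) / 2, (a$y_min + a$y_max) / 2), numeric(2))
      rowMeans(b)
    }, numeric(2)))
    nearest <- vapply(seq_len(nrow(tab)), function(i) {
      d <- sqrt((cent[, 1] - tab$x_px[i])^2 + (cent[, 2] - tab$y_px[i])^2)
      which.min(d)
    }, integer(1))
    rg <- flim_stats$regions
    tab$flim_region <- rg$region[nearest]
    tab$flim_region_mean_ns <- rg$mean_of_means_ns[nearest]
  }
  rownames(tab) <- NULL
  tab
}

#' Read or write an area selection as JSON
#'
#' The JSON maps region names to lists of `{x_min, x_max, y_min, y_max}`
#' boxes (1-based inclusive), the persisted form of the FLIM area
#' selections.
#'
#' @param path JSON file path.
#' @param selection Named list: region -> list of [roi_spec()].
#' @return `read_area_selection` returns the named list of [roi_spec()]
#'   lists; `write_area_selection` invisibly returns `path`.
#' @export
read_area_selection <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(areas)
    lapply(areas, function(a)
      roi_spec(a$x_min, a$x_max, a$y_min, a$y_max)))
}

#' @rdname read_area_selection
#' @export
write_area_selection <- function(selection, path) {
  jsonlite::write_json(lapply(selection, function(areas)
    lapply(areas, unclass)), path, auto_unbox = TRUE)
  invisible(path)
}

#' Correlate two columns of a multimodal table
#'
#' Pearson and Spearman correlation over rows that are unflagged (apart
#' from the bookkeeping `first_point` flag) and finite in both columns.
#'
#' @param table A multimodal table from [run_pipeline()] (or any data
#'   frame; a missing `flag` column is treated as all-clean).
#' @param x,y Column names.
#' @return List with `pearson`, `spearman`, `n`.
#' @export
correlate <- function(table, x, y) {
  for (col in c(x, y))
    if (!col %in% names(table))
      stop(sprintf("column '%s' not in table", col))
  keep <- is.finite(table[[x]]) & is.finite(table[[y]])
  if (!is.null(table$flag)) {
    clean <- vapply(strsplit(table$flag, ";"), function(f)
      all(f %in% c("", "first_point")), logical(1))
    keep <- keep & clean
  }
  xv <- table[[x]][keep]
  yv <- table[[y]][keep]
  if (length(xv) < 3L)
    stop(sprintf("need >= 3 paired finite values for '%s' vs '%s', have %d",
                 x, y, length(xv)))
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop(sprintf("correlation undefined: '%s' or '%s' is constant",
                 x, y))
  list(pearson = stats::cor(xv, yv, method = "pearson"),
       spearman = stats::cor(xv, yv, method = "spearman"),
       n = length(xv))
}
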