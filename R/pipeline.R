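#' @title Full-analysis pipeline and reporting
#' @description
#' A single YAML config drives the full zone analysis: read or generate
#' tracks, derive kinematics, assign zones, classify each zone's motion
#' pattern, summarize speeds, and compute pairwise correlations and
#' nearest-neighbour statistics; optional sections add nuclear-shape and
#' tumor-border analyses. The result is a JSON-serializable report whose
#' every number comes from an exported operation, reproducible
#' byte-identically under an identical config and seed (modulo the
#' timestamp field).
#' @name pipeline
NULL

.report_version <- "1.0"

.cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run the zone analysis pipeline
#'
#' @param config a YAML file path or an equivalent named list. Recognized
#'   fields: `seed`; `frame_interval_min` (default 10);
#'   `include_stationary` (default `FALSE`); `tracks$file` (CSV or
#'   TrackMate XML) or `tracks$generate` (list of generator specs, each a
#'   list with `pattern` and optional [simulate_trajectories()] arguments
#'   plus an `offset = c(x, y)` placing the arena); `zones` (list of
#'   `zone_id`/`x_min`/`x_max`/`y_min`/`y_max`); `classifier`
#'   (`min_n`, `kappa_max`, `use_aicc`); `correlations` (`r_max`,
#'   `bin_width`, `by_sector`, `kernel`); optional `mask`
#'   (`file`, `pixel_size`, `min_area_px`, `ar_threshold`) and `border`
#'   (`file`, `pixel_size`, `epsilon`, `n_steps`, `threshold`).
#' @param out_dir if non-`NULL`, `report.json` is written there.
#' @return an `analysis_report` list (invisibly when writing).
#' @export
run_zone_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    cfg_hash <- unname(tools::md5sum(config))
  } else {
    cfg <- config
    cfg_hash <- .hash_object(config)
  }
  seed <- .cfg_get(cfg, "seed", 1L)
  set.seed(seed)
  dt <- .cfg_get(cfg, "frame_interval_min", 10)
  input_hashes <- character(0)

  # --- tracks -------------------------------------------------------------
  if (!is.null(cfg$tracks$file)) {
    tracks <- read_tracks(cfg$tracks$file, frame_interval = dt)
    input_hashes <- c(tracks = unname(tools::md5sum(cfg$tracks$file)))
  } else if (!is.null(cfg$tracks$generate)) {
    parts <- lapply(cfg$tracks$generate, function(g) {
      off <- .cfg_get(g, "offset", c(0, 0))
      args <- g[setdiff(names(g), c("offset", "zone"))]
      args$dt <- .cfg_get(args, "dt", dt)
      sim <- do.call(simulate_trajectories, args)
      tt <- sim$tracks
      tt$x_um <- tt$x_um + off[[1]]
      tt$y_um <- tt$y_um + off[[2]]
      tag <- .cfg_get(g, "zone", g$pattern)
      tt$track_id <- paste(tag, tt$track_id, sep = ":")
      tt
    })
    tracks <- track_table(do.call(rbind, lapply(parts, as.data.frame)),
                          frame_interval = dt)
  } else stop("config needs tracks$file or tracks$generate")

  kin <- compute_kinematics(tracks)
  rois <- lapply(cfg$zones, function(z)
    zone_roi(z$zone_id, z$x_min, z$x_max, z$y_min, z$y_max))
  kin <- assign_zones(kin, rois)

  ccl <- .cfg_get(cfg, "classifier", list())
  cco <- .cfg_get(cfg, "correlations", list())
  include_stationary <- .cfg_get(cfg, "include_stationary", FALSE)
  speed_sum <- summarize_speeds(kin, include_stationary = include_stationary)

  zones <- lapply(split(seq_len(nrow(kin)), kin$zone), function(i) {
    sub <- kin[i, , drop = FALSE]
    zid <- sub$zone[1]
    thetas <- sub$theta[sub$valid & is.finite(sub$theta)]
    fit <- classify_pattern(thetas,
                            min_n = .cfg_get(ccl, "min_n", 30),
                            kappa_max = .cfg_get(ccl, "kappa_max", 500),
                            use_aicc = .cfg_get(ccl, "use_aicc", FALSE),
                            zone_id = zid)
    if (is.na(fit$label))
      warning("zone ", zid, ": ", fit$note, call. = FALSE)
    snaps <- build_snapshots(sub)
    r_max <- .cfg_get(cco, "r_max", 50)
    corr <- pair_directional_correlation(
      snaps, r_bin_edges = seq(0, r_max, by = .cfg_get(cco, "bin_width", 10)),
      by_sector = .cfg_get(cco, "by_sector", FALSE),
      kernel = .cfg_get(cco, "kernel", "polar"))
    nn <- nearest_neighbor_distances(snaps)
    sp <- speed_sum$summary[speed_sum$summary$group == zid, , drop = FALSE]
    sh <- speed_sum$histograms[[zid]]
    entry <- list(
      zone_id = zid, n_steps = nrow(sub), n_valid = length(thetas),
      pattern = if (is.na(fit$label)) {
        list(label = NULL, note = fit$note)
      } else {
        list(label = fit$label,
             akaike_weights = as.list(fit$akaike_weights),
             aic = as.list(fit$aic), delta_aic = as.list(fit$delta_aic),
             log_likelihood = lapply(fit$fits, function(f) f$log_likelihood),
             mu_flock = fit$fits[[3]]$mu, kappa_flock = fit$fits[[3]]$kappa,
             mu_stream = fit$fits[[2]]$mu, kappa_stream = fit$fits[[2]]$kappa)
      },
      speed = list(n = sp$n, mean = sp$mean, sd = sp$sd,
                   hist_breaks = if (!is.null(sh)) sh$breaks,
                   hist_counts = if (!is.null(sh)) sh$counts),
      angle_histogram = if (length(thetas))
        angle_histogram(thetas, n_bins = 16)[c("breaks", "counts")],
      kde = if (length(thetas)) {
        k <- circular_kde(thetas)
        list(grid = k$grid, density = k$density, bandwidth = k$bandwidth)
      },
      correlation = corr,
      nearest_neighbor = as.list(nn$summary))
    if (!is.null(entry$pattern$log_likelihood))
      names(entry$pattern$log_likelihood) <- c("swarm", "stream", "flock")
    entry
  })

  report <- list(version = .report_version,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 provenance = list(seed = seed, config_hash = cfg_hash,
                                   input_hashes = as.list(input_hashes)),
                 settings = list(frame_interval_min = dt,
                                 include_stationary = include_stationary),
                 zones = zones)

  # --- optional image analyses -------------------------------------------
  if (!is.null(cfg$mask)) {
    mk <- read_labeled_mask(cfg$mask$file, .cfg_get(cfg$mask, "pixel_size", 1))
    desc <- measure_shapes(mk, min_area_px = .cfg_get(cfg$mask, "min_area_px", 5))
    cls <- classify_cell_shape(desc, .cfg_get(cfg$mask, "ar_threshold", 2))
    nem <- nematic_order(desc$feret_deg)
    report$shapes <- list(n = nrow(desc),
                          mean_aspect_ratio = mean(desc$aspect_ratio),
                          fraction_elongated = attr(cls, "fraction_elongated"),
                          nematic_order = nem$S, mean_axis_deg = nem$mean_axis_deg)
  }
  if (!is.null(cfg$border)) {
    bcfg <- cfg$border
    h <- .cfg_get(bcfg, "pixel_size", 1)
    img <- .read_gray_image(bcfg$file)
    pf <- binarize_tumor_image(img, .cfg_get(bcfg, "threshold", "otsu"),
                               h = h, epsilon = .cfg_get(bcfg, "epsilon", 2 * h))
    pf <- allen_cahn_smooth(pf, n_steps = .cfg_get(bcfg, "n_steps", 200))
    crv <- extract_border_curve(pf)
    report$border <- list(length_um = crv$length,
                          endpoint_distance_um = crv$endpoint_distance,
                          sinuosity = crv$sinuosity, closed = crv$closed)
  }

  class(report) <- "analysis_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "report.json"))
    return(invisible(report))
  }
  report
}

.hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, compress = FALSE, version = 2)
  unname(tools::md5sum(tf))
}

.read_gray_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Serialize an analysis report to JSON
#'
#' @param report an `analysis_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# -------------------------------------------------------------------------
# Figures

.open_device <- function(path, width = 6, height = 6) {
  ok <- tryCatch({
    grDevices::png(paste0(path, ".png"), width = width * 100,
                   height = height * 100, res = 100)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) grDevices::pdf(paste0(path, ".pdf"), width = width, height = height)
  invisible(NULL)
}

.rose_plot <- function(breaks, counts, main = "") {
  graphics::plot.new()
  r <- sqrt(counts / max(max(counts), 1))
  graphics::plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  tt <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(cos(tt), sin(tt), col = "grey70")
  for (i in seq_along(counts)) {
    a <- seq(breaks[i], breaks[i + 1], length.out = 12)
    graphics::polygon(c(0, r[i] * cos(a), 0), c(0, r[i] * sin(a), 0),
                      col = "steelblue3", border = "white")
  }
  graphics::title(main = main)
}

#' Render report figures
#'
#' Writes, per zone: a rose plot of headings, a model-comparison panel
#' (circular KDE with the three fitted densities and their Akaike
#' weights), a speed histogram and the pair-correlation curve. PNG when a
#' bitmap device is available, PDF otherwise. An empty report produces no
#' files and a warning.
#'
#' @param report an `analysis_report` from [run_zone_analysis()].
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report") || is.list(report))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(report$zones) == 0) {
    warning("empty report: no figures rendered")
    return(invisible(character(0)))
  }
  written <- character(0)
  for (z in report$zones) {
    zid <- gsub("[^A-Za-z0-9_.-]", "_", z$zone_id)
    if (!is.null(z$angle_histogram)) {
      base <- file.path(out_dir, paste0("rose_", zid))
      .open_device(base)
      .rose_plot(unlist(z$angle_histogram$breaks), unlist(z$angle_histogram$counts),
                 main = paste("Zone", z$zone_id, "headings"))
      grDevices::dev.off()
      written <- c(written, base)
    }
    if (!is.null(z$kde) && !is.null(z$pattern$label)) {
      base <- file.path(out_dir, paste0("models_", zid))
      .open_device(base, width = 7, height = 5)
      g <- unlist(z$kde$grid)
      graphics::plot(g, unlist(z$kde$density), type = "l", lwd = 2,
                     xlab = expression(theta), ylab = "density",
                     main = sprintf("Zone %s: %s", z$zone_id, z$pattern$label))
      graphics::abline(h = 1 / (2 * pi), col = "blue", lty = 2)
      graphics::lines(g, dvonmises(g, z$pattern$mu_flock, z$pattern$kappa_flock),
                      col = "red")
      graphics::lines(g, 0.5 * dvonmises(g, z$pattern$mu_stream,
                                         z$pattern$kappa_stream) +
                        0.5 * dvonmises(g, z$pattern$mu_stream + pi,
                                        z$pattern$kappa_stream),
                      col = "orange")
      aw <- unlist(z$pattern$akaike_weights)
      graphics::legend("topright", bty = "n", lwd = c(2, 1, 1, 1),
                       col = c("black", "blue", "orange", "red"),
                       legend = c("data (KDE)",
                                  sprintf("swarm AW=%.3f", aw["swarm"]),
                                  sprintf("stream AW=%.3f", aw["stream"]),
                                  sprintf("flock AW=%.3f", aw["flock"])))
      grDevices::dev.off()
      written <- c(written, base)
    }
    if (!is.null(z$speed$hist_breaks)) {
      base <- file.path(out_dir, paste0("speed_", zid))
      .open_device(base, width = 6, height = 4)
      br <- unlist(z$speed$hist_breaks); cn <- unlist(z$speed$hist_counts)
      graphics::plot(NULL, xlim = range(br), ylim = c(0, max(cn)),
                     xlab = "speed (um/h)", ylab = "steps",
                     main = sprintf("Zone %s speeds (mean %.2f um/h)",
                                    z$zone_id, z$speed$mean))
      graphics::rect(br[-length(br)], 0, br[-1], cn, col = "grey80")
      grDevices::dev.off()
      written <- c(written, base)
    }
    corr <- z$correlation
    if (!is.null(corr) && !is.data.frame(corr)) {
      num <- function(field) vapply(corr, function(r)
        if (is.null(r[[field]])) NA_real_ else as.numeric(r[[field]]), numeric(1))
      corr <- data.frame(bin_lo_um = num("bin_lo_um"),
                         bin_hi_um = num("bin_hi_um"),
                         C = num("C"), n_pairs = num("n_pairs"))
    }
    if (!is.null(corr) && is.data.frame(corr) && nrow(corr) &&
        any(unlist(corr$n_pairs) > 0)) {
      base <- file.path(out_dir, paste0("correlation_", zid))
      .open_device(base, width = 6, height = 4)
      mid <- (corr$bin_lo_um + corr$bin_hi_um) / 2
      graphics::plot(mid, corr$C, type = "b", ylim = c(-1, 1), pch = 16,
                     xlab = "separation (um)", ylab = "C(r)",
                     main = paste("Zone", z$zone_id, "pair correlation"))
      graphics::abline(h = 0, lty = 3)
      grDevices::dev.off()
      written <- c(written, base)
    }
  }
  invisible(written)
}
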