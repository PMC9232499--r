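#' @title Track tables, kinematics and zone assignment
#' @description
#' Cell tracks are held in a `track_table`: a data.frame with columns
#' `track_id`, `frame`, `t_min`, `x_um`, `y_um` (one row per spot, sorted by
#' time within track) and a `frame_interval` attribute in minutes. All
#' internal computation is in micrometres and minutes; speeds are reported
#' in micrometres per hour.
#' @name trajectory_io
NULL

#' Construct a track table
#'
#' @param df data.frame with columns `track_id`, `t_min`, `x_um`, `y_um` and
#'   optionally `frame`.
#' @param frame_interval frame interval in minutes; if `NULL`, inferred as
#'   the most common positive time difference within tracks.
#' @return a `track_table`.
#' @export
track_table <- function(df, frame_interval = NULL) {
  need <- c("track_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)
  if (nrow(df) > 0 && any(!is.finite(df$x_um) | !is.finite(df$y_um) |
                          !is.finite(df$t_min)))
    stop("track coordinates and times must be finite")
  df <- df[order(df$track_id, df$t_min), , drop = FALSE]
  rownames(df) <- NULL
  if (!"frame" %in% names(df)) {
    df$frame <- stats::ave(df$t_min, df$track_id, FUN = seq_along) - 1
  }
  dup <- stats::ave(df$t_min, df$track_id, FUN = function(t) c(0, diff(t)))
  if (nrow(df) > 0 && any(dup <= 0 & stats::ave(df$t_min, df$track_id,
                                                FUN = seq_along) > 1))
    stop("time must be strictly increasing within each track")
  if (is.null(frame_interval)) {
    dt <- unlist(tapply(df$t_min, df$track_id, diff, simplify = FALSE))
    frame_interval <- if (length(dt)) as.numeric(names(sort(table(dt),
                                                            decreasing = TRUE))[1]) else NA_real_
  }
  if (!is.na(frame_interval) && frame_interval <= 0)
    stop("frame_interval must be positive")
  structure(df[, c("track_id", "frame", "t_min", "x_um", "y_um")],
            frame_interval = frame_interval, class = c("track_table", "data.frame"))
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("track_table: %d tracks, %d spots, frame interval %s min\n",
              length(unique(x$track_id)), nrow(x),
              format(attr(x, "frame_interval"))))
  NextMethod()
}

#' Read cell tracks
#'
#' Reads tracking output either from the plain CSV dialect
#' (`track_id,frame,t_min,x_um,y_um`, header mandatory) or from
#' TrackMate-dialect XML (`Model/AllSpots` spots referenced by
#' `Model/AllTracks/Track/Edge`, positions `POSITION_X`/`POSITION_Y` in
#' micrometres and times from `POSITION_T` or `FRAME`).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tracks-csv"` or `"trackmate-xml"`.
#' @param frame_interval frame interval in minutes; overrides file metadata.
#'   Required for XML files whose spots carry only `FRAME`.
#' @return a [track_table()].
#' @export
read_tracks <- function(path, format = c("auto", "tracks-csv", "trackmate-xml"),
                        frame_interval = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE))
      "trackmate-xml" else "tracks-csv"
  }
  if (format == "tracks-csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("track_id", "frame", "t_min", "x_um", "y_um")
    if (!all(need %in% names(df)))
      stop("malformed tracks CSV ", path, ": missing column(s) ",
           paste(setdiff(need, names(df)), collapse = ", "))
    return(track_table(df, frame_interval))
  }
  .read_trackmate_xml(path, frame_interval)
}

.read_trackmate_xml <- function(path, frame_interval = NULL) {
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Model/AllSpots//Spot")
  if (length(spots) == 0) stop("malformed TrackMate XML ", path, ": no spots")
  sid <- xml2::xml_attr(spots, "ID")
  sx <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  sy <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  st <- as.numeric(xml2::xml_attr(spots, "POSITION_T"))
  sf <- as.numeric(xml2::xml_attr(spots, "FRAME"))
  if (anyNA(sx) || anyNA(sy))
    stop("malformed TrackMate XML ", path, ": spot without POSITION_X/Y")
  if (anyNA(st)) {
    if (anyNA(sf))
      stop("TrackMate XML ", path, ": spots carry neither POSITION_T nor FRAME")
    if (is.null(frame_interval))
      stop("TrackMate XML ", path, ": no time metadata; supply frame_interval")
    st <- sf * frame_interval
  }
  lookup <- data.frame(x = sx, y = sy, t = st,
                       frame = if (anyNA(sf)) NA_real_ else sf,
                       row.names = sid)
  trks <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
  if (length(trks) == 0) stop("malformed TrackMate XML ", path, ": no tracks")
  rows <- lapply(seq_along(trks), function(i) {
    tid <- xml2::xml_attr(trks[[i]], "TRACK_ID")
    if (is.na(tid)) tid <- as.character(i - 1)
    edges <- xml2::xml_find_all(trks[[i]], "./Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0) return(NULL)
    bad <- setdiff(ids, rownames(lookup))
    if (length(bad))
      stop("malformed TrackMate XML ", path, ": edge references unknown spot ",
           bad[1])
    sp <- lookup[ids, , drop = FALSE]
    data.frame(track_id = tid, frame = sp$frame, t_min = sp$t,
               x_um = sp$x, y_um = sp$y, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0)
    stop("malformed TrackMate XML ", path, ": tracks reference no spots")
  if (all(is.na(df$frame))) df$frame <- NULL
  track_table(df, frame_interval)
}

#' Write cell tracks
#'
#' Writes the plain CSV dialect (lossless round-trip with [read_tracks()])
#' or TrackMate-dialect XML. Coordinates are written with a fixed float
#' format so output is byte-stable for identical input.
#'
#' @param table a [track_table()].
#' @param path output file.
#' @param format `"tracks-csv"` or `"trackmate-xml"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(table, path, format = c("tracks-csv", "trackmate-xml")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "track_table"))
  if (format == "tracks-csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("track_id,frame,t_min,x_um,y_um", con)
    if (nrow(table) > 0) {
      writeLines(sprintf("%s,%d,%.6f,%.6f,%.6f", table$track_id,
                         as.integer(table$frame), table$t_min,
                         table$x_um, table$y_um), con)
    }
    return(invisible(path))
  }
  .write_trackmate_xml(table, path)
}

.write_trackmate_xml <- function(table, path) {
  dt <- attr(table, "frame_interval")
  sp_id <- seq_len(nrow(table)) - 1L
  by_frame <- split(seq_len(nrow(table)), table$frame)
  spot_xml <- vapply(names(by_frame), function(fr) {
    i <- by_frame[[fr]]
    paste0(sprintf('  <SpotsInFrame frame="%s">\n', fr),
           paste(sprintf('   <Spot ID="%d" FRAME="%d" POSITION_T="%.6f" POSITION_X="%.6f" POSITION_Y="%.6f"/>',
                         sp_id[i], as.integer(table$frame[i]), table$t_min[i],
                         table$x_um[i], table$y_um[i]), collapse = "\n"),
           "\n  </SpotsInFrame>")
  }, character(1))
  by_track <- split(seq_len(nrow(table)), table$track_id)
  track_xml <- vapply(names(by_track), function(tid) {
    i <- by_track[[tid]][order(table$t_min[by_track[[tid]]])]
    if (length(i) < 2) {
      edges <- sprintf('   <Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d"/>',
                       sp_id[i], sp_id[i])
    } else {
      edges <- sprintf('   <Edge SPOT_SOURCE_ID="%d" SPOT_TARGET_ID="%d"/>',
                       sp_id[i[-length(i)]], sp_id[i[-1]])
    }
    paste0(sprintf('  <Track TRACK_ID="%s">\n', tid),
           paste(edges, collapse = "\n"), "\n  </Track>")
  }, character(1))
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<TrackMate version="7">\n<Model spatialunits="micron" timeunits="min">\n',
                ' <AllSpots>\n', paste(spot_xml, collapse = "\n"), '\n </AllSpots>\n',
                ' <AllTracks>\n', paste(track_xml, collapse = "\n"), '\n </AllTracks>\n',
                sprintf('</Model>\n<Settings frame_interval="%s"/>\n</TrackMate>\n',
                        format(dt)))
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Per-step kinematics
#'
#' For each consecutive sample pair within a track computes the heading
#' `theta = atan2(dy, dx) mod 2*pi` and the speed `(|dr| / dt) * 60` in
#' micrometres per hour, using the actual time difference of each pair.
#' Zero-displacement steps are retained with `valid = FALSE` (their heading
#' is undefined, speed 0).
#'
#' @param table a [track_table()]; every track needs at least 2 samples.
#' @return a `kinematics` data.frame with columns `track_id`, `t_mid`,
#'   `x_mid`, `y_mid`, `theta`, `speed`, `valid`.
#' @export
compute_kinematics <- function(table) {
  stopifnot(inherits(table, "track_table"))
  parts <- lapply(split(seq_len(nrow(table)), table$track_id), function(i) {
    i <- i[order(table$t_min[i])]
    if (length(i) < 2) return(NULL)
    t <- table$t_min[i]; x <- table$x_um[i]; y <- table$y_um[i]
    dt <- diff(t)
    if (any(dt <= 0)) stop("non-increasing time within track ",
                           table$track_id[i[1]])
    dx <- diff(x); dy <- diff(y)
    dr <- sqrt(dx^2 + dy^2)
    valid <- dr > 0
    data.frame(track_id = table$track_id[i[1]],
               t_mid = (t[-length(t)] + t[-1]) / 2,
               x_mid = (x[-length(x)] + x[-1]) / 2,
               y_mid = (y[-length(y)] + y[-1]) / 2,
               theta = ifelse(valid, atan2(dy, dx) %% (2 * pi), NA_real_),
               speed = (dr / dt) * 60,
               valid = valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(track_id = character(0), t_mid = numeric(0),
                                      x_mid = numeric(0), y_mid = numeric(0),
                                      theta = numeric(0), speed = numeric(0),
                                      valid = logical(0))
  rownames(out) <- NULL
  class(out) <- c("kinematics", "data.frame")
  out
}

#' Rectangular analysis zones
#'
#' @param zone_id label.
#' @param x_min,x_max,y_min,y_max bounds in micrometres.
#' @return a `zone_roi`.
#' @export
zone_roi <- function(zone_id, x_min, x_max, y_min, y_max) {
  stopifnot(x_min < x_max, y_min < y_max)
  structure(list(zone_id = as.character(zone_id), x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max), class = "zone_roi")
}

#' Assign kinematics rows to zones
#'
#' A step belongs to a zone if its midpoint lies in
#' `[x_min, x_max) x [y_min, y_max)` (half-open, so boundaries never double
#' count). Zones may overlap: a row inside several zones is replicated once
#' per zone. Rows outside all zones are labeled `"unzoned"`.
#'
#' @param kin a `kinematics` table from [compute_kinematics()].
#' @param rois list of [zone_roi()] objects (possibly empty).
#' @return the kinematics table with a `zone` column (long format).
#' @export
assign_zones <- function(kin, rois = list()) {
  stopifnot(is.data.frame(kin))
  if (inherits(rois, "zone_roi")) rois <- list(rois)
  if (nrow(kin) == 0) {
    kin$zone <- character(0)
    return(kin)
  }
  hits <- matrix(FALSE, nrow(kin), length(rois))
  for (j in seq_along(rois)) {
    r <- rois[[j]]
    hits[, j] <- kin$x_mid >= r$x_min & kin$x_mid < r$x_max &
      kin$y_mid >= r$y_min & kin$y_mid < r$y_max
  }
  out <- lapply(seq_along(rois), function(j) {
    sub <- kin[hits[, j], , drop = FALSE]
    if (nrow(sub)) sub$zone <- rois[[j]]$zone_id
    sub
  })
  none <- if (length(rois)) !apply(hits, 1, any) else rep(TRUE, nrow(kin))
  un <- kin[none, , drop = FALSE]
  if (nrow(un)) un$zone <- "unzoned"
  res <- do.call(rbind, c(out[vapply(out, nrow, 1L) > 0],
                          if (nrow(un)) list(un)))
  if (is.null(res)) {
    res <- kin[0, , drop = FALSE]
    res$zone <- character(0)
  }
  rownames(res) <- NULL
  class(res) <- c("kinematics", "data.frame")
  res
}

#' Per-group speed summaries
#'
#' Mean, standard deviation, count and a histogram of step speeds per group
#' (zone by default). Invalid (zero-displacement) rows are excluded unless
#' `include_stationary = TRUE`. Empty groups are reported with `n = 0` and
#' `NA` mean rather than raising an error.
#'
#' @param kin a `kinematics` table (optionally zone-labeled).
#' @param group_by grouping column name, default `"zone"` (falls back to a
#'   single group `"all"` when the column is absent).
#' @param include_stationary include `valid = FALSE` rows (speed 0).
#' @param breaks histogram breaks passed to [graphics::hist()].
#' @return list with `$summary` data.frame (`group`, `n`, `mean`, `sd`) and
#'   `$histograms`, a named list of histogram objects.
#' @export
summarize_speeds <- function(kin, group_by = "zone", include_stationary = FALSE,
                             breaks = "Sturges") {
  stopifnot(is.data.frame(kin))
  g <- if (group_by %in% names(kin)) as.character(kin[[group_by]])
       else rep("all", nrow(kin))
  keep <- if (include_stationary) rep(TRUE, nrow(kin)) else kin$valid
  groups <- unique(g)
  hists <- list()
  rows <- lapply(groups, function(gr) {
    v <- kin$speed[g == gr & keep]
    if (length(v) == 0) {
      data.frame(group = gr, n = 0L, mean = NA_real_, sd = NA_real_)
    } else {
      hists[[gr]] <<- graphics::hist(v, breaks = breaks, plot = FALSE)
      data.frame(group = gr, n = length(v), mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
  })
  list(summary = do.call(rbind, rows), histograms = hists)
}
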