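#' @title Pairwise spatial and directional correlations
#' @description
#' Local-order statistics over per-frame snapshots of a zone: pair
#' directional correlation versus separation (optionally resolved by the
#' neighbor's sector in the focal cell's heading frame), relative-position
#' maps, and nearest-neighbour distance statistics.
#' @name spatial_correlations
NULL

#' Group zone-labeled kinematics into per-frame snapshots
#'
#' Rows are grouped by `(zone, t_mid)`; each snapshot keeps position,
#' heading and the `valid` flag per cell. Cells with `valid = FALSE` carry
#' a position but are excluded from directional statistics downstream.
#'
#' @param kin a `kinematics` table, optionally with a `zone` column.
#' @return list of snapshot data.frames, each with attributes `zone` and `t`.
#' @export
build_snapshots <- function(kin) {
  stopifnot(is.data.frame(kin))
  if (nrow(kin) == 0) return(list())
  zone <- if ("zone" %in% names(kin)) as.character(kin$zone) else
    rep("all", nrow(kin))
  key <- paste(zone, kin$t_mid, sep = "\r")
  idx <- split(seq_len(nrow(kin)), key)
  snaps <- lapply(idx, function(i) {
    s <- data.frame(track_id = kin$track_id[i], x = kin$x_mid[i],
                    y = kin$y_mid[i], theta = kin$theta[i],
                    valid = kin$valid[i], stringsAsFactors = FALSE)
    attr(s, "zone") <- zone[i[1]]
    attr(s, "t") <- kin$t_mid[i[1]]
    s
  })
  ord <- order(vapply(snaps, function(s) attr(s, "zone"), character(1)),
               vapply(snaps, function(s) attr(s, "t"), numeric(1)))
  unname(snaps[ord])
}

.SECTORS <- c("front", "right", "back", "left")

# Sector of a neighbor's bearing relative to the focal heading:
# front (-45, 45], right (45, 135], back (135, 225], left (225, 315].
.sector_of <- function(bearing_deg) {
  b <- (bearing_deg + 45) %% 360  # front becomes (0, 90]
  idx <- pmin(floor(((b - 1e-12) %% 360) / 90), 3) + 1L
  .SECTORS[idx]
}

#' Pair directional correlation versus distance
#'
#' For every unordered pair of valid cells in a snapshot whose separation
#' falls in a distance bin, accumulates `cos(theta_i - theta_j)` (polar
#' kernel) or `cos(2 (theta_i - theta_j))` (nematic kernel; useful for
#' antiparallel streams, where the polar kernel averages toward zero).
#' Pairs are pooled over snapshots before averaging (pair-weighted) unless
#' `frame_weighted = TRUE`. In sector mode each pair contributes twice,
#' once per focal cell, binned by the neighbor's bearing in the focal
#' heading frame.
#'
#' @param snapshots list from [build_snapshots()].
#' @param r_bin_edges distance bin edges in micrometres (default 0-50 by 10).
#' @param by_sector resolve by front/right/back/left sector.
#' @param kernel `"polar"` or `"nematic"`.
#' @param frame_weighted average per snapshot first, then across snapshots.
#' @return data.frame `bin_lo_um`, `bin_hi_um`, `sector`, `C`, `n_pairs`;
#'   `C` is `NA` where `n_pairs = 0`.
#' @export
pair_directional_correlation <- function(snapshots,
                                         r_bin_edges = seq(0, 50, by = 10),
                                         by_sector = FALSE,
                                         kernel = c("polar", "nematic"),
                                         frame_weighted = FALSE) {
  kernel <- match.arg(kernel)
  nb <- length(r_bin_edges) - 1
  stopifnot(nb >= 1)
  sectors <- if (by_sector) .SECTORS else "all"
  dims <- c(nb, length(sectors))
  sums <- array(0, dims); npairs <- array(0, dims)
  fsums <- array(0, dims); fn <- array(0, dims)
  for (s in snapshots) {
    v <- s[s$valid & is.finite(s$theta), , drop = FALSE]
    m <- nrow(v)
    if (m < 2) next
    ii <- rep(seq_len(m - 1), times = (m - 1):1)
    jj <- sequence((m - 1):1) + ii
    dx <- v$x[jj] - v$x[ii]; dy <- v$y[jj] - v$y[ii]
    r <- sqrt(dx^2 + dy^2)
    bin <- findInterval(r, r_bin_edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    if (!any(ok)) next
    dthe <- v$theta[ii] - v$theta[jj]
    cc <- if (kernel == "polar") cos(dthe) else cos(2 * dthe)
    loc_s <- array(0, dims); loc_n <- array(0, dims)
    if (by_sector) {
      # i focal: bearing of j in i's frame; then j focal
      bi <- (atan2(dy, dx) * 180 / pi - v$theta[ii] * 180 / pi) %% 360
      bj <- (atan2(-dy, -dx) * 180 / pi - v$theta[jj] * 180 / pi) %% 360
      for (bearing in list(bi, bj)) {
        sec <- match(.sector_of(bearing), .SECTORS)
        k <- ok
        tb <- tapply(cc[k], list(factor(bin[k], levels = 1:nb),
                                 factor(sec[k], levels = 1:4)), sum)
        tn <- tapply(rep(1, sum(k)), list(factor(bin[k], levels = 1:nb),
                                          factor(sec[k], levels = 1:4)), sum)
        tb[is.na(tb)] <- 0; tn[is.na(tn)] <- 0
        loc_s <- loc_s + tb; loc_n <- loc_n + tn
      }
    } else {
      tb <- tapply(cc[ok], factor(bin[ok], levels = 1:nb), sum)
      tn <- tapply(rep(1, sum(ok)), factor(bin[ok], levels = 1:nb), sum)
      tb[is.na(tb)] <- 0; tn[is.na(tn)] <- 0
      loc_s[, 1] <- tb; loc_n[, 1] <- tn
    }
    sums <- sums + loc_s; npairs <- npairs + loc_n
    has <- loc_n > 0
    fsums[has] <- fsums[has] + loc_s[has] / loc_n[has]
    fn[has] <- fn[has] + 1
  }
  C <- if (frame_weighted) ifelse(fn > 0, fsums / fn, NA_real_)
       else ifelse(npairs > 0, sums / npairs, NA_real_)
  out <- expand.grid(bin = seq_len(nb), sector = sectors,
                     stringsAsFactors = FALSE)
  data.frame(bin_lo_um = r_bin_edges[out$bin], bin_hi_um = r_bin_edges[out$bin + 1],
             sector = out$sector, C = as.vector(C),
             n_pairs = as.vector(npairs), stringsAsFactors = FALSE)
}

#' Relative neighbor-position map in the focal heading frame
#'
#' For each ordered pair of valid cells the displacement (neighbor minus
#' focal) is rotated by minus the focal heading, so the focal direction of
#' motion maps to +x ("front"). Displacements are histogrammed on a square
#' grid and normalized to a probability map.
#'
#' @param snapshots list from [build_snapshots()].
#' @param r_max half-width of the map in micrometres.
#' @param bin_width bin width in micrometres.
#' @return list with `edges` (shared x/y bin edges), `density` (matrix,
#'   rows = x front-back, cols = y left-right) and `n_pairs`.
#' @export
relative_position_map <- function(snapshots, r_max = 50, bin_width = 5) {
  edges <- seq(-r_max, r_max, by = bin_width)
  nb <- length(edges) - 1
  counts <- matrix(0, nb, nb)
  total <- 0
  for (s in snapshots) {
    v <- s[s$valid & is.finite(s$theta), , drop = FALSE]
    m <- nrow(v)
    if (m < 2) next
    ii <- rep(seq_len(m), each = m)[-seq(1, m * m, by = m + 1)]
    jj <- rep(seq_len(m), times = m)[-seq(1, m * m, by = m + 1)]
    dx <- v$x[jj] - v$x[ii]; dy <- v$y[jj] - v$y[ii]
    th <- v$theta[ii]
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    bx <- findInterval(xr, edges, rightmost.closed = TRUE)
    by <- findInterval(yr, edges, rightmost.closed = TRUE)
    ok <- bx >= 1 & bx <= nb & by >= 1 & by <= nb
    if (!any(ok)) next
    tb <- table(factor(bx[ok], levels = 1:nb), factor(by[ok], levels = 1:nb))
    counts <- counts + unclass(tb)
    total <- total + sum(ok)
  }
  dens <- if (total > 0) counts / total else counts
  list(edges = edges, density = dens, n_pairs = total)
}

#' Nearest-neighbour distances per cell per frame
#'
#' Euclidean distance from each cell to its closest other cell in the same
#' snapshot, pooled over snapshots. Frames with fewer than two cells are
#' skipped. An optional toroidal metric (used when validating against the
#' Poisson-process expectation, which assumes no edges) wraps distances on
#' the given arena.
#'
#' @param snapshots list from [build_snapshots()].
#' @param toroidal wrap distances on a rectangular arena.
#' @param arena `c(width, height)` in micrometres; required when `toroidal`.
#' @return list with `distances` (pooled vector) and `summary`
#'   (`n`, `median`, `q1`, `q3`), plus a histogram object when non-empty.
#' @export
nearest_neighbor_distances <- function(snapshots, toroidal = FALSE,
                                       arena = NULL) {
  if (toroidal && (is.null(arena) || length(arena) != 2))
    stop("toroidal metric needs arena = c(width, height)")
  all_d <- lapply(snapshots, function(s) {
    m <- nrow(s)
    if (m < 2) return(numeric(0))
    dx <- abs(outer(s$x, s$x, "-")); dy <- abs(outer(s$y, s$y, "-"))
    if (toroidal) {
      dx <- pmin(dx, arena[1] - dx)
      dy <- pmin(dy, arena[2] - dy)
    }
    d <- sqrt(dx^2 + dy^2)
    diag(d) <- Inf
    apply(d, 1, min)
  })
  d <- unlist(all_d)
  if (length(d) == 0)
    return(list(distances = numeric(0),
                summary = data.frame(n = 0L, median = NA_real_,
                                     q1 = NA_real_, q3 = NA_real_)))
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(distances = d,
       summary = data.frame(n = length(d), median = q[2], q1 = q[1], q3 = q[3]),
       histogram = graphics::hist(d, breaks = "Sturges", plot = FALSE))
}
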