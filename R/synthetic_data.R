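#' @title Ground-truthed synthetic data generators
#' @description
#' Statistical emulators of the observables the analysis consumes:
#' trajectories per collective-motion pattern, aligned/unaligned ellipse
#' fields (nuclei masks), and tumor borders of known sinuosity. Every
#' generator is deterministic under its `seed` and returns the ground
#' truth needed to score the downstream estimators. Defaults reproduce
#' the study conditions: 10-min frame interval, 293-frame movies, core
#' mean speeds per pattern (swarm 6.27, stream 4.26, flock 5.95 um/h) and
#' a cell density giving nearest-neighbour distances around 30 um.
#' @name synthetic_data
NULL

.PATTERN_SPEEDS <- c(swarm = 6.27, stream = 4.26, flock = 5.95)

# reflect positions into [0, w]
.reflect <- function(p, w) {
  r <- abs(p) %% (2 * w)
  ifelse(r > w, 2 * w - r, r)
}

#' Simulate cell trajectories for a collective-motion pattern
#'
#' Initial positions are uniform in the arena. Per step, each cell draws a
#' heading -- swarm: uniform on `[0, 2*pi)`; flock: von Mises(`mu`,
#' `kappa`); stream: von Mises around `mu` or `mu + pi` with a fixed
#' per-cell lane (the first `ceiling(n/2)` cells take `mu`), so lanes
#' persist over time -- and a speed from a lognormal with mean
#' `speed_mean` and coefficient of variation `speed_cv`. Positions are
#' reflected at the arena walls.
#'
#' @param pattern `"swarm"`, `"stream"` or `"flock"`.
#' @param n_cells number of cells (default 100).
#' @param n_frames number of frames (default 293, a core movie).
#' @param dt frame interval in minutes (default 10).
#' @param speed_mean mean speed in um/h; default is the pattern's core
#'   value (swarm 6.27, stream 4.26, flock 5.95).
#' @param speed_cv coefficient of variation of speeds (default 0.3).
#' @param kappa heading concentration; 0 for swarm, default 4 otherwise.
#' @param mu pattern direction (flock) or axis (stream), radians.
#' @param arena `c(width, height)` in micrometres.
#' @param lane_resample stream only: resample the lane each step instead
#'   of fixing it per cell (null-model variant).
#' @param seed RNG seed (`set.seed`); `NULL` leaves the RNG state alone.
#' @return list with `tracks` (a [track_table()]) and `truth` (pattern,
#'   `mu`, `kappa`, `speed_mean`, per-cell lane directions).
#' @export
simulate_trajectories <- function(pattern = c("swarm", "stream", "flock"),
                                  n_cells = 100, n_frames = 293, dt = 10,
                                  speed_mean = NULL, speed_cv = 0.3,
                                  kappa = NULL, mu = pi / 4,
                                  arena = c(600, 600), lane_resample = FALSE,
                                  seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(n_cells >= 1, n_frames >= 2, dt > 0, all(arena > 0))
  if (is.null(speed_mean)) speed_mean <- unname(.PATTERN_SPEEDS[pattern])
  if (is.null(kappa)) kappa <- if (pattern == "swarm") 0 else 4
  stopifnot(speed_mean > 0, kappa >= 0)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + speed_cv^2))
  meanlog <- log(speed_mean) - sdlog^2 / 2
  x <- stats::runif(n_cells, 0, arena[1])
  y <- stats::runif(n_cells, 0, arena[2])
  lane <- rep(mu, n_cells)
  if (pattern == "stream")
    lane[seq_len(n_cells) > ceiling(n_cells / 2)] <- mu + pi
  X <- matrix(NA_real_, n_frames, n_cells); Y <- X
  X[1, ] <- x; Y[1, ] <- y
  for (f in 2:n_frames) {
    th <- switch(pattern,
      swarm = stats::runif(n_cells, 0, 2 * pi),
      flock = rvonmises(n_cells, mu, kappa),
      stream = {
        d <- if (lane_resample)
          ifelse(stats::runif(n_cells) < 0.5, mu, mu + pi) else lane
        (rvonmises(n_cells, 0, kappa) + d) %% (2 * pi)
      })
    sp <- stats::rlnorm(n_cells, meanlog, sdlog)   # um/h
    step <- sp * dt / 60
    x <- .reflect(x + step * cos(th), arena[1])
    y <- .reflect(y + step * sin(th), arena[2])
    X[f, ] <- x; Y[f, ] <- y
  }
  df <- data.frame(
    track_id = sprintf("cell_%04d", rep(seq_len(n_cells), each = n_frames)),
    frame = rep(seq_len(n_frames) - 1L, times = n_cells),
    t_min = rep((seq_len(n_frames) - 1) * dt, times = n_cells),
    x_um = as.vector(X), y_um = as.vector(Y), stringsAsFactors = FALSE)
  list(tracks = track_table(df, frame_interval = dt),
       truth = list(pattern = pattern, mu = mu, kappa = kappa,
                    speed_mean = speed_mean, speed_cv = speed_cv,
                    lane = lane, arena = arena))
}

#' Simulate a field of labeled, oriented ellipses
#'
#' Non-overlapping ellipses with aspect ratios from a truncated normal
#' (`>= 1`) and orientations from an axial von Mises around `axis_mu`.
#' Placement is rejection sampling; if an ellipse cannot be placed within
#' `max_tries` attempts the generator stops and suggests a lower density.
#'
#' @param n_cells number of ellipses.
#' @param ar_mean,ar_sd aspect-ratio distribution (defaults 2.63, 0.19:
#'   the elongated-nucleus group; use 1.37, 0.12 for the round group).
#' @param axis_mu mean orientation axis in degrees.
#' @param axis_kappa axial concentration; 0 = isotropic.
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param area_px_mean,area_px_sd ellipse pixel-area distribution.
#' @param max_tries placement attempts per ellipse.
#' @param seed RNG seed.
#' @return list with `mask` (a [labeled_mask()], labels 1..n) and `truth`
#'   (per-object data.frame: `label`, `ar`, `orientation_deg`, `area_px`).
#' @export
simulate_ellipse_field <- function(n_cells = 100, ar_mean = 2.63, ar_sd = 0.19,
                                   axis_mu = 0, axis_kappa = 4,
                                   image_size = c(512, 512), pixel_size = 1,
                                   area_px_mean = 150, area_px_sd = 20,
                                   max_tries = 200, seed = NULL) {
  stopifnot(ar_mean >= 1, n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  nr <- image_size[1]; nc <- image_size[2]
  lab <- matrix(0L, nr, nc)
  truth <- vector("list", n_cells)
  for (id in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ar <- max(stats::rnorm(1, ar_mean, ar_sd), 1)
      area <- max(stats::rnorm(1, area_px_mean, area_px_sd), 20)
      b <- sqrt(area / (pi * ar)); a <- ar * b
      ang <- (rvonmises(1, 2 * axis_mu * pi / 180, axis_kappa) / 2) %% pi
      cx <- stats::runif(1, a + 1, nc - a - 1)
      cy <- stats::runif(1, a + 1, nr - a - 1)
      rr <- max(1, floor(cy - a)):min(nr, ceiling(cy + a))
      cc <- max(1, floor(cx - a)):min(nc, ceiling(cx + a))
      px <- rep(cc, each = length(rr)) - 0.5
      py <- rep(rr, times = length(cc)) - 0.5
      dx <- px - cx; dy <- py - cy
      inside <- ((dx * cos(ang) + dy * sin(ang)) / a)^2 +
        ((-dx * sin(ang) + dy * cos(ang)) / b)^2 <= 1
      if (sum(inside) < 5) next
      ridx <- rep(rr, times = length(cc))[inside]
      cidx <- rep(cc, each = length(rr))[inside]
      cells <- cbind(ridx, cidx)
      if (any(lab[cells] != 0)) next
      lab[cells] <- id
      truth[[id]] <- data.frame(label = id, ar = ar,
                                orientation_deg = ang * 180 / pi,
                                area_px = sum(inside))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ellipse ", id, " after ", max_tries,
           " tries; lower the density (fewer/smaller cells or larger image)")
  }
  list(mask = labeled_mask(lab, pixel_size), truth = do.call(rbind, truth))
}

#' Simulate a binary tumor-border image of known sinuosity
#'
#' Tumor occupies the half-plane below the sine curve
#' `y = y0 + amplitude * sin(2*pi*x / wavelength)`. The ground-truth
#' sinuosity is the sine arc length over the endpoint distance, computed
#' by dense numeric quadrature. Optional salt-and-pepper noise flips each
#' pixel independently with probability `noise_flip_prob`.
#'
#' @param amplitude sine amplitude in micrometres (`>= 0`).
#' @param wavelength sine wavelength in micrometres.
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param noise_flip_prob per-pixel flip probability.
#' @param seed RNG seed (used only for noise).
#' @return list with `image` (0/1 matrix), `pixel_size` and `truth`
#'   (`sinuosity`, `amplitude`, `wavelength`).
#' @export
simulate_border_image <- function(amplitude = 20, wavelength = 100,
                                  image_size = c(200, 400), pixel_size = 1,
                                  noise_flip_prob = 0, seed = NULL) {
  stopifnot(amplitude >= 0, wavelength > 0)
  if (!is.null(seed)) set.seed(seed)
  nr <- image_size[1]; nc <- image_size[2]
  xs <- (seq_len(nc) - 0.5) * pixel_size
  ys <- (seq_len(nr) - 0.5) * pixel_size
  y0 <- nr * pixel_size / 2
  border <- y0 + amplitude * sin(2 * pi * xs / wavelength)
  img <- outer(ys, border, FUN = function(y, b) as.numeric(y < b))
  if (noise_flip_prob > 0) {
    flip <- matrix(stats::runif(nr * nc) < noise_flip_prob, nr, nc)
    img[flip] <- 1 - img[flip]
  }
  # ground truth by dense quadrature over the imaged x range
  xq <- seq(xs[1], xs[nc], length.out = 100000)
  yq <- y0 + amplitude * sin(2 * pi * xq / wavelength)
  L <- sum(sqrt(diff(xq)^2 + diff(yq)^2))
  D <- sqrt((xq[length(xq)] - xq[1])^2 + (yq[length(yq)] - yq[1])^2)
  list(image = img, pixel_size = pixel_size,
       truth = list(sinuosity = L / D, amplitude = amplitude,
                    wavelength = wavelength))
}
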