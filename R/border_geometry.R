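#' @title Allen-Cahn border smoothing and sinuosity
#' @description
#' A two-phase tumor/brain image is mapped to a phase field with values
#' -1 (outside) and +1 (inside), relaxed under the Allen-Cahn equation
#' `du/dt = eps^2 * lap(u) + u - u^3` (double-well `W(u) = (1 - u^2)^2/4`,
#' minima at +-1), and the smoothed interface is the zero level set. Its
#' sinuosity is the curve length divided by the distance between the two
#' extreme points.
#' @name border_geometry
NULL

#' Construct a phase field
#'
#' @param u real matrix (rows = y, cols = x), nominally in `[-1, 1]`.
#' @param h grid spacing, micrometres per pixel.
#' @param epsilon interface-width parameter in micrometres (default `2*h`:
#'   wide enough to kill pixel noise, narrow against lobes of interest).
#' @param dt explicit-Euler time step; default is 0.9 of the stability
#'   bound `h^2/(4*epsilon^2)`.
#' @return a `phase_field`.
#' @export
phase_field <- function(u, h = 1, epsilon = 2 * h, dt = NULL) {
  stopifnot(is.matrix(u), h > 0, epsilon > 0)
  if (is.null(dt)) dt <- 0.9 * h^2 / (4 * epsilon^2)
  structure(list(u = u, h = h, epsilon = epsilon, dt = dt),
            class = "phase_field")
}

#' Binarize a tumor image into a +-1 phase field
#'
#' @param image numeric matrix (grayscale; rows = y, cols = x).
#' @param threshold numeric cut (tumor where `image >= threshold`) or
#'   `"otsu"` for automatic threshold selection.
#' @param h,epsilon,dt passed to [phase_field()].
#' @return a `phase_field` with `u` in `{-1, +1}`; a single-phase image
#'   yields attribute `no_interface = TRUE`.
#' @export
binarize_tumor_image <- function(image, threshold = "otsu", h = 1,
                                 epsilon = 2 * h, dt = NULL) {
  stopifnot(is.matrix(image))
  if (identical(threshold, "otsu")) threshold <- .otsu(image)
  stopifnot(is.numeric(threshold))
  u <- matrix(ifelse(image >= threshold, 1, -1), nrow(image), ncol(image))
  pf <- phase_field(u, h = h, epsilon = epsilon, dt = dt)
  if (all(u == 1) || all(u == -1)) attr(pf, "no_interface") <- TRUE
  pf
}

# Otsu threshold on a 256-bin histogram; returns the cut maximizing
# between-class variance, placed between the two classes.
.otsu <- function(image) {
  v <- as.vector(image)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = 257)
  h <- graphics::hist(v, breaks = brk, plot = FALSE)$counts
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-257]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu <- mu1[256]
  sb <- (mu * w1 - mu1)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  brk[which.max(sb) + 1]
}

#' Allen-Cahn relaxation of a phase field
#'
#' Explicit finite differences: forward Euler in time, 5-point Laplacian,
#' zero-flux (Neumann) boundaries. The stability condition
#' `dt <= 0.9 * h^2 / (4 * epsilon^2)` is checked before stepping.
#' Uniform fields at -1, 0 or +1 are preserved exactly.
#'
#' @param field a `phase_field`.
#' @param n_steps number of time steps (default 200).
#' @return the evolved `phase_field`.
#' @export
allen_cahn_smooth <- function(field, n_steps = 200) {
  stopifnot(inherits(field, "phase_field"), n_steps >= 0)
  h <- field$h; eps <- field$epsilon; dt <- field$dt
  if (dt > 0.9 * h^2 / (4 * eps^2) + 1e-12)
    stop(sprintf("unstable time step: dt = %g > 0.9 * h^2/(4 eps^2) = %g",
                 dt, 0.9 * h^2 / (4 * eps^2)))
  u <- field$u
  nr <- nrow(u); nc <- ncol(u)
  if (nr < 2 || nc < 2) stop("phase field must be at least 2 x 2")
  c1 <- eps^2 * dt / h^2
  for (s in seq_len(n_steps)) {
    up <- u[c(1, 1:(nr - 1)), ]; dn <- u[c(2:nr, nr), ]
    lf <- u[, c(1, 1:(nc - 1))]; rt <- u[, c(2:nc, nc)]
    u <- u + c1 * (up + dn + lf + rt - 4 * u) + dt * (u - u^3)
  }
  out <- field
  out$u <- u
  out
}

#' Extract the tumor border curve from a phase field
#'
#' Marching-squares contour of `u` at level 0 with linear interpolation.
#' The longest open contour (one whose ends differ, i.e. it spans the
#' field of view) is returned; exact-length ties go to the first contour
#' in scan order. If only closed contours exist, the longest closed one is
#' returned with `closed = TRUE` and sinuosity undefined.
#'
#' @param field a `phase_field`.
#' @return a `border_curve`: list with `points` (n x 2 matrix, micrometres),
#'   `length`, `endpoint_distance`, `sinuosity` and `closed`.
#' @export
extract_border_curve <- function(field) {
  stopifnot(inherits(field, "phase_field"))
  u <- field$u; h <- field$h
  if (all(u >= 0) || all(u <= 0)) stop("no zero level set: single-phase field")
  xs <- (seq_len(ncol(u)) - 0.5) * h
  ys <- (seq_len(nrow(u)) - 0.5) * h
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(u), levels = 0)
  if (length(cl) == 0) stop("no zero level set found")
  lens <- vapply(cl, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, numeric(1))
  closed <- vapply(cl, function(cc) {
    isTRUE(all.equal(c(cc$x[1], cc$y[1]),
                     c(cc$x[length(cc$x)], cc$y[length(cc$y)])))
  }, logical(1))
  pick_from <- if (any(!closed)) which(!closed) else seq_along(cl)
  best <- pick_from[which.max(lens[pick_from])]
  pts <- cbind(x_um = cl[[best]]$x, y_um = cl[[best]]$y)
  is_closed <- closed[best]
  curve <- structure(list(points = pts, length = lens[best],
                          endpoint_distance = NA_real_, sinuosity = NA_real_,
                          closed = is_closed), class = "border_curve")
  if (!is_closed) {
    d <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
    curve$endpoint_distance <- d
    curve$sinuosity <- if (d > 0) lens[best] / d else NA_real_
  }
  curve
}

#' @export
print.border_curve <- function(x, ...) {
  cat(sprintf("border_curve: %d points, L = %.3f um, %s\n", nrow(x$points),
              x$length,
              if (x$closed) "closed (sinuosity undefined)"
              else sprintf("D = %.3f um, S = %.4f", x$endpoint_distance,
                           x$sinuosity)))
  invisible(x)
}

#' Sinuosity of a polyline
#'
#' `S = L / D`: total segment length over the Euclidean distance between
#' the first and last point. Dimensionless, `>= 1`, invariant under rigid
#' motion and uniform scaling.
#'
#' @param curve a `border_curve` or an n x 2 matrix of points.
#' @return the sinuosity.
#' @export
sinuosity <- function(curve) {
  pts <- if (inherits(curve, "border_curve")) curve$points else as.matrix(curve)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 2)
  L <- sum(sqrt(rowSums(diff(pts)^2)))
  D <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  if (D == 0) stop("sinuosity undefined: endpoints coincide (closed curve)")
  L / D
}

#' Write a border polyline as CSV
#'
#' @param curve a `border_curve`.
#' @param path output CSV (`x_um,y_um`).
#' @export
write_border_curve <- function(curve, path) {
  stopifnot(inherits(curve, "border_curve"))
  utils::write.csv(as.data.frame(curve$points), path, row.names = FALSE)
  invisible(path)
}
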