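#' @title Circular-distribution classification of collective motion
#' @description
#' A zone's per-step headings are compared against three candidate circular
#' densities: uniform (swarm; no preferred direction), von Mises (flock; one
#' preferred direction) and an equal-weight antipodal von Mises mixture
#' (stream; two opposite preferred directions). Each family is fitted by
#' maximum likelihood and the families are compared through Akaike weights.
#' @name motion_classifier
NULL

.check_thetas <- function(thetas, min_n = 1) {
  if (length(thetas) < min_n || any(!is.finite(thetas)))
    stop("heading sample must contain at least ", min_n, " finite angles")
  thetas %% (2 * pi)
}

.dist_model <- function(family, mu, kappa, k_free, loglik, n) {
  structure(list(family = family, mu = mu, kappa = kappa,
                 k_free = k_free, log_likelihood = loglik, n = n),
            class = "distribution_model")
}

#' @export
print.distribution_model <- function(x, ...) {
  cat(sprintf("<%s>  logL = %.4f (N = %d, k = %d)\n",
              x$family, x$log_likelihood, x$n, x$k_free))
  if (!is.null(x$mu))
    cat(sprintf("  mu = %.4f rad, kappa = %.4f\n", x$mu, x$kappa))
  invisible(x)
}

#' Log-likelihood of the uniform (swarm) model
#'
#' The circular uniform density has no free parameters; its log-likelihood is
#' \code{-N * log(2*pi)} regardless of the observed angles.
#'
#' @param thetas headings in radians.
#' @return a `distribution_model` with family `"swarm_uniform"`.
#' @export
loglik_uniform <- function(thetas) {
  thetas <- .check_thetas(thetas, 1)
  n <- length(thetas)
  .dist_model("swarm_uniform", NULL, NULL, 0L, -n * log(2 * pi), n)
}

#' Maximum-likelihood von Mises (flock) fit
#'
#' The MLE of the mean direction is the direction of the mean resultant
#' vector; the concentration solves \code{A(kappa) = Rbar} where
#' \code{A = I1/I0} is the Bessel ratio. `kappa` is clipped to
#' `[0, kappa_max]` for degenerate (fully concentrated) samples.
#'
#' @inheritParams loglik_uniform
#' @param kappa_max upper clip for the fitted concentration.
#' @return a `distribution_model` with family `"flock_unimodal"`.
#' @export
fit_unimodal <- function(thetas, kappa_max = 500) {
  thetas <- .check_thetas(thetas, 2)
  n <- length(thetas)
  C <- mean(cos(thetas)); S <- mean(sin(thetas))
  rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C) %% (2 * pi)
  kappa <- .A1inv(rbar, kappa_max)
  ll <- sum(dvonmises(thetas, mu, kappa, log = TRUE))
  .dist_model("flock_unimodal", mu, kappa, 2L, ll, n)
}

# log density of the equal-weight antipodal von Mises mixture
# 0.5 f(theta; mu, kappa) + 0.5 f(theta; mu + pi, kappa)
#   = cosh(kappa * cos(theta - mu)) / (2 pi I0(kappa)),
# evaluated stably via log cosh(x) = |x| + log1p(exp(-2|x|)) - log 2.
.dbimodal_log <- function(theta, mu, kappa) {
  x <- abs(kappa * cos(theta - mu))
  x + log1p(exp(-2 * x)) - log(2) -
    (log(2 * pi) + kappa + log(besselI(kappa, 0, expon.scaled = TRUE)))
}

.bimodal_negll <- function(par, thetas, kappa_max) {
  kappa <- min(max(par[2], 0), kappa_max)
  -sum(.dbimodal_log(thetas, par[1], kappa))
}

#' Maximum-likelihood antipodal von Mises mixture (stream) fit
#'
#' Fits \code{0.5 vM(mu, kappa) + 0.5 vM(mu + pi, kappa)}: equal weights,
#' antipodal modes, shared concentration, so the model has the same number
#' of free parameters (axis and concentration) as the flock model. The axis
#' is initialized from the doubled-angle mean direction
#' \code{0.5 * arg(sum(exp(2i * theta)))} and `(mu, kappa)` are refined by
#' bounded quasi-Newton maximization from several starts.
#'
#' @inheritParams fit_unimodal
#' @return a `distribution_model` with family `"stream_bimodal"`; `mu` is the
#'   axis, reported in `[0, pi)`.
#' @export
fit_bimodal <- function(thetas, kappa_max = 500) {
  thetas <- .check_thetas(thetas, 2)
  n <- length(thetas)
  c2 <- mean(cos(2 * thetas)); s2 <- mean(sin(2 * thetas))
  mu0 <- (0.5 * atan2(s2, c2)) %% pi
  r2 <- sqrt(c2^2 + s2^2)
  starts <- unique(pmin(pmax(c(.A1inv(r2, kappa_max), 0.5, 4), 1e-3), kappa_max))
  best <- NULL
  for (k0 in starts) {
    opt <- stats::optim(c(mu0, k0), .bimodal_negll, thetas = thetas,
                        kappa_max = kappa_max, method = "L-BFGS-B",
                        lower = c(mu0 - pi, 0), upper = c(mu0 + pi, kappa_max),
                        control = list(factr = 1e4, maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish to tight tolerance from the best start
  best <- stats::optim(best$par, .bimodal_negll, thetas = thetas,
                       kappa_max = kappa_max, method = "L-BFGS-B",
                       lower = c(best$par[1] - 0.5, 0),
                       upper = c(best$par[1] + 0.5, kappa_max),
                       control = list(factr = 1, pgtol = 0, maxit = 1000))
  mu <- best$par[1] %% pi
  kappa <- min(max(best$par[2], 0), kappa_max)
  ll <- sum(.dbimodal_log(thetas, mu, kappa))
  .dist_model("stream_bimodal", mu, kappa, 2L, ll, n)
}

.FAMILY_LABELS <- c(swarm_uniform = "swarm", stream_bimodal = "stream",
                    flock_unimodal = "flock")

#' Akaike weights across the three candidate families
#'
#' Computes \code{AIC = 2k - 2 logL} (optionally the small-sample corrected
#' AICc), the AIC differences relative to the best family, and the Akaike
#' weights \code{exp(-delta/2)} normalized to sum to one. The label is the
#' family with the largest weight; exact ties are broken in the order
#' swarm, stream, flock (parsimony first).
#'
#' @param fits list of the three `distribution_model` fits (any order).
#' @param use_aicc use the small-sample correction `AICc`.
#' @param zone_id optional identifier carried into the result.
#' @return a `pattern_fit` with per-family `aic`, `delta_aic`,
#'   `akaike_weights` (named swarm/stream/flock) and `label`.
#' @export
akaike_weights <- function(fits, use_aicc = FALSE, zone_id = NULL) {
  fam <- vapply(fits, function(f) f$family, character(1))
  if (!setequal(fam, names(.FAMILY_LABELS)))
    stop("akaike_weights() needs exactly one fit per family")
  fits <- fits[match(names(.FAMILY_LABELS), fam)]  # swarm, stream, flock order
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  if (any(!is.finite(ll))) stop("non-finite log-likelihood")
  k <- vapply(fits, function(f) as.numeric(f$k_free), numeric(1))
  n <- fits[[1]]$n
  aic <- 2 * k - 2 * ll
  if (use_aicc) aic <- aic + 2 * k * (k + 1) / pmax(n - k - 1, 1)
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  lab <- unname(.FAMILY_LABELS)
  names(aic) <- names(delta) <- names(w) <- lab
  structure(list(zone_id = zone_id, n = n, fits = fits, aic = aic,
                 delta_aic = delta, akaike_weights = w,
                 label = lab[which.max(w)]),
            class = "pattern_fit")
}

#' @export
print.pattern_fit <- function(x, ...) {
  if (!is.null(x$zone_id)) cat("Zone:", x$zone_id, "\n")
  if (is.na(x$label)) {
    cat(sprintf("insufficient sample (N = %d)\n", x$n))
    return(invisible(x))
  }
  cat(sprintf("N = %d headings; pattern: %s\n", x$n, x$label))
  tab <- data.frame(logL = vapply(x$fits, function(f) f$log_likelihood, 0),
                    AIC = x$aic, dAIC = x$delta_aic, AW = x$akaike_weights)
  print(round(tab, 4))
  invisible(x)
}

#' Classify a heading sample as swarm, stream or flock
#'
#' Runs the three maximum-likelihood fits and compares them with
#' [akaike_weights()]. Samples smaller than `min_n` yield an
#' "insufficient sample" result with an `NA` label rather than an error.
#'
#' @inheritParams fit_unimodal
#' @param min_n minimum sample size for a classification (default 30).
#' @param use_aicc passed to [akaike_weights()].
#' @param zone_id optional identifier carried into the result.
#' @return a `pattern_fit`.
#' @export
classify_pattern <- function(thetas, min_n = 30, kappa_max = 500,
                             use_aicc = FALSE, zone_id = NULL) {
  thetas <- thetas[is.finite(thetas)] %% (2 * pi)
  n <- length(thetas)
  if (n < min_n) {
    return(structure(list(zone_id = zone_id, n = n, fits = NULL, aic = NULL,
                          delta_aic = NULL, akaike_weights = NULL,
                          label = NA_character_,
                          note = sprintf("insufficient sample: N = %d < %d", n, min_n)),
                     class = "pattern_fit"))
  }
  fits <- list(loglik_uniform(thetas),
               fit_bimodal(thetas, kappa_max),
               fit_unimodal(thetas, kappa_max))
  akaike_weights(fits, use_aicc = use_aicc, zone_id = zone_id)
}

#' Circular kernel density estimate
#'
#' Von Mises kernel density on a uniform angular grid:
#' \code{density(theta) = mean_n f_vM(theta; theta_n, bandwidth_kappa)}.
#'
#' @inheritParams loglik_uniform
#' @param bandwidth_kappa kernel concentration (larger = less smoothing).
#' @param n_grid number of grid points on `[0, 2*pi)`.
#' @return list with `grid`, `density` and `bandwidth`.
#' @export
circular_kde <- function(thetas, bandwidth_kappa = 8, n_grid = 360) {
  thetas <- .check_thetas(thetas, 1)
  stopifnot(bandwidth_kappa > 0, n_grid >= 8)
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  lognorm <- log(2 * pi) + bandwidth_kappa +
    log(besselI(bandwidth_kappa, 0, expon.scaled = TRUE))
  dens <- vapply(grid, function(g) {
    mean(exp(bandwidth_kappa * cos(g - thetas) - lognorm))
  }, numeric(1))
  structure(list(grid = grid, density = dens, bandwidth = bandwidth_kappa),
            class = "circular_kde")
}

#' Angle histogram (rose-plot counts)
#'
#' Counts over `n_bins` equal-width bins of `[0, 2*pi)`; angles are reduced
#' modulo `2*pi` so the last bin closes at `2*pi`.
#'
#' @inheritParams loglik_uniform
#' @param n_bins number of bins (`>= 2`).
#' @return list with `breaks` (length `n_bins + 1`), `counts` and `mids`.
#' @export
angle_histogram <- function(thetas, n_bins = 16) {
  thetas <- .check_thetas(thetas, 1)
  stopifnot(n_bins >= 2)
  width <- 2 * pi / n_bins
  idx <- pmin(floor(thetas / width), n_bins - 1) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1)
  list(breaks = breaks, counts = counts, mids = breaks[-1] - width / 2)
}
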