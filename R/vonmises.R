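#' Von Mises density
#'
#' Density of the von Mises distribution with mean direction \code{mu} and
#' concentration \code{kappa}. \code{kappa = 0} gives the circular uniform
#' density \code{1/(2*pi)}. The Bessel normalization is evaluated on the
#' exponential scale so that densities stay finite up to very large
#' concentrations.
#'
#' @param theta angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration, `>= 0`.
#' @param log if `TRUE`, return the log density.
#' @return numeric vector of (log) densities.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 0, log = FALSE) {
  stopifnot(kappa >= 0)
  # log I0(kappa) = kappa + log(besselI(kappa, 0, expon.scaled = TRUE))
  logd <- kappa * cos(theta - mu) - log(2 * pi) -
    (kappa + log(besselI(kappa, 0, expon.scaled = TRUE)))
  if (log) logd else exp(logd)
}

#' Von Mises random deviates
#'
#' Best-Fisher rejection sampler; exact for all `kappa >= 0`. Deterministic
#' under `set.seed()`.
#'
#' @inheritParams dvonmises
#' @param n number of deviates.
#' @return angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(keep)
    if (nk > 0) {
      u3 <- stats::runif(nk)
      th <- sign(u3 - 0.5) * acos(f[keep])
      out[(got + 1L):(got + nk)] <- (th + mu) %% (2 * pi)
      got <- got + nk
    }
  }
  out
}

# Bessel-function ratio A1(kappa) = I1(kappa)/I0(kappa), computed on the
# exponential scale; A1 is the mean resultant length of a von Mises sample.
.A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Invert A1(kappa) = rbar on [0, kappa_max] by root finding; values of rbar
# beyond A1(kappa_max) are clipped to kappa_max.
.A1inv <- function(rbar, kappa_max = 500) {
  if (rbar <= 0) return(0)
  if (rbar >= .A1(kappa_max)) return(kappa_max)
  stats::uniroot(function(k) .A1(k) - rbar, c(0, kappa_max), tol = 1e-12)$root
}
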