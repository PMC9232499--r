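# Shared helpers: independent brute-force oracles and small generators.

# smallest circular difference, period `per`
circ_diff <- function(a, b, per = 2 * pi) {
  d <- abs(a - b) %% per
  pmin(d, per - d)
}

# Independent grid-search maximum of the von Mises log-likelihood.
# Uses the sufficient statistics (sum cos, sum sin) so the full
# 0.001-rad x 0.01-kappa grid over [0, 2pi) x [0, 20] is evaluated directly.
oracle_loglik_unimodal <- function(th) {
  n <- length(th)
  Cs <- sum(cos(th)); Ss <- sum(sin(th))
  eval_grid <- function(kappa_grid, mu_grid) {
    best <- c(-Inf, 0, 0)
    for (k in kappa_grid) {
      lognorm <- log(2 * pi) + k + log(besselI(k, 0, expon.scaled = TRUE))
      ll <- k * (Cs * cos(mu_grid) + Ss * sin(mu_grid)) - n * lognorm
      i <- which.max(ll)
      if (ll[i] > best[1]) best <- c(ll[i], mu_grid[i], k)
    }
    best
  }
  b <- eval_grid(seq(0, 20, by = 0.01), seq(0, 2 * pi, by = 0.001))
  # local refinement below the stated grid resolution
  eval_grid(seq(max(b[3] - 0.02, 0), min(b[3] + 0.02, 20), by = 0.002),
            seq(b[2] - 0.002, b[2] + 0.002, by = 0.0005))[1]
}

# Grid-search maximum of the antipodal von Mises mixture log-likelihood:
# coarse grid over the axis [0, pi) then a local fine grid at 0.001-rad /
# 0.01-kappa resolution around the coarse optimum.
oracle_loglik_bimodal <- function(th) {
  n <- length(th)
  ll_at <- function(mu, k) {
    x <- abs(k * cos(outer(th, mu, "-")))
    colSums(x + log1p(exp(-2 * x)) - log(2)) -
      n * (log(2 * pi) + k + log(besselI(k, 0, expon.scaled = TRUE)))
  }
  mus <- seq(0, pi, by = 0.01)
  best <- c(-Inf, 0, 0)
  for (k in seq(0, 20, by = 0.05)) {
    ll <- ll_at(mus, k)
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], mus[i], k)
  }
  mus <- seq(best[2] - 0.02, best[2] + 0.02, by = 0.0005)
  out <- -Inf
  for (k in seq(max(best[3] - 0.1, 0), min(best[3] + 0.1, 20), by = 0.002)) {
    m <- max(ll_at(mus, k))
    if (m > out) out <- m
  }
  out
}

# antipodally balanced stream sample around axis `axis`
r_stream <- function(n, axis, kappa) {
  lanes <- rep(c(0, pi), length.out = n)
  (rvonmises(n, 0, kappa) + axis + lanes) %% (2 * pi)
}

# rotate a labeled mask about its center by `deg`: inverse mapping with
# per-object bilinear interpolation (threshold 0.5), so object boundaries
# stay smooth enough for perimeter estimates
rotate_mask <- function(labels, deg) {
  th <- deg * pi / 180
  nr <- nrow(labels); nc <- ncol(labels)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  side <- ceiling(sqrt(nr^2 + nc^2))
  oy <- (side + 1) / 2; ox <- (side + 1) / 2
  ridx <- rep(seq_len(side), times = side)
  cidx <- rep(seq_len(side), each = side)
  xs <- (cidx - ox) * cos(-th) - (ridx - oy) * sin(-th) + cx
  ys <- (cidx - ox) * sin(-th) + (ridx - oy) * cos(-th) + cy
  x0 <- pmin(pmax(floor(xs), 1), nc - 1); y0 <- pmin(pmax(floor(ys), 1), nr - 1)
  fx <- pmin(pmax(xs - x0, 0), 1); fy <- pmin(pmax(ys - y0, 0), 1)
  inside <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
  out <- matrix(0L, side, side)
  for (id in sort(unique(labels[labels > 0]))) {
    bin <- matrix(0, nr, nc); bin[labels == id] <- 1
    v <- bin[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      bin[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      bin[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      bin[cbind(y0 + 1, x0 + 1)] * fx * fy
    hit <- inside & v >= 0.5
    out[cbind(ridx[hit], cidx[hit])] <- id
  }
  out
}

# rasterized disk mask
disk_mask <- function(r = 30, pad = 10) {
  n <- 2 * (r + pad)
  cc <- n / 2 + 0.5
  m <- matrix(0L, n, n)
  idx <- which((row(m) - cc)^2 + (col(m) - cc)^2 <= r^2)
  m[idx] <- 1L
  m
}

# snapshot data.frame constructor
snap_df <- function(x, y, theta, valid = TRUE) {
  data.frame(track_id = as.character(seq_along(x)), x = x, y = y,
             theta = theta, valid = valid, stringsAsFactors = FALSE)
}
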