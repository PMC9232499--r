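test_that("uniform log-likelihood has its closed form and ignores the angles", {
  set.seed(1)
  expect_equal(loglik_uniform(runif(10, 0, 2 * pi))$log_likelihood,
               -10 * log(2 * pi))
  expect_equal(loglik_uniform(1.234)$log_likelihood, -log(2 * pi))
  a <- loglik_uniform(runif(25, 0, 2 * pi))$log_likelihood
  b <- loglik_uniform(runif(25, 0, 2 * pi))$log_likelihood
  expect_identical(a, b)
  expect_error(loglik_uniform(numeric(0)), "at least")
})

test_that("unimodal fit handles degenerate samples by construction", {
  # perfectly antipodal -> zero resultant -> kappa 0, uniform likelihood
  f <- fit_unimodal(c(0, pi, 0, pi))
  expect_equal(f$kappa, 0)
  expect_equal(f$log_likelihood, -4 * log(2 * pi))
  # identical headings -> clipped at kappa_max
  g <- fit_unimodal(rep(1.1, 5), kappa_max = 500)
  expect_equal(g$kappa, 500)
  expect_equal(circ_diff(g$mu, 1.1), 0, tolerance = 1e-12)
})

test_that("bimodal fit treats two antipodal points as ideal data", {
  f <- fit_bimodal(c(0, pi))
  expect_equal(f$kappa, 500)             # likelihood increasing in kappa
  expect_lt(circ_diff(f$mu, 0, per = pi), 1e-6)
  # uniform data: kappa near 0, log-likelihood near the uniform value
  set.seed(4)
  th <- runif(400, 0, 2 * pi)
  g <- fit_bimodal(th)
  expect_lt(g$log_likelihood - (-400 * log(2 * pi)), 3)  # small overfit gain
  expect_gte(g$log_likelihood, -400 * log(2 * pi))       # nested model
})

test_that("directional fits recover generating parameters at N = 2000", {
  set.seed(7)
  th <- rvonmises(2000, pi / 4, 4)
  f <- fit_unimodal(th)
  expect_lt(circ_diff(f$mu, pi / 4), 0.05)
  expect_lt(abs(f$kappa - 4) / 4, 0.10)
  expect_lt(abs(f$log_likelihood - oracle_loglik_unimodal(th)), 1e-3)

  set.seed(8)
  thb <- r_stream(2000, pi / 3, 3)
  g <- fit_bimodal(thb)
  expect_lt(circ_diff(g$mu, pi / 3, per = pi), 0.05)
  expect_lt(abs(g$kappa - 3) / 3, 0.10)
  expect_lt(abs(g$log_likelihood - oracle_loglik_bimodal(thb)), 1e-3)
})

test_that("model nesting at kappa = 0 reproduces the uniform likelihood exactly", {
  set.seed(12)
  th <- rvonmises(100, 1, 2)
  lu <- loglik_uniform(th)$log_likelihood
  expect_identical(sum(dvonmises(th, 1, 0, log = TRUE)), lu)
  expect_identical(sum(gliomotion:::.dbimodal_log(th, 1, 0)), lu)
})

test_that("Akaike weights follow the closed form and always normalize", {
  mk <- function(fam, ll, k) structure(
    list(family = fam, mu = 0, kappa = 1, k_free = k, log_likelihood = ll, n = 50),
    class = "distribution_model")
  # AICs (100, 110, 110): weights 1/(1 + 2 e^-5), e^-5/(1 + 2 e^-5)
  fits <- list(mk("swarm_uniform", -50, 0),     # AIC 100
               mk("stream_bimodal", -53, 2),    # AIC 110
               mk("flock_unimodal", -53, 2))    # AIC 110
  pf <- akaike_weights(fits)
  expect_equal(unname(round(pf$akaike_weights, 4)), c(0.9867, 0.0066, 0.0066))
  expect_equal(pf$label, "swarm")
  expect_lt(abs(sum(pf$akaike_weights) - 1), 1e-12)
  expect_equal(min(pf$delta_aic), 0)

  # equal AICs -> thirds, tie broken toward the simpler family
  fits2 <- list(mk("swarm_uniform", -52, 0), mk("stream_bimodal", -50, 2),
                mk("flock_unimodal", -50, 2))
  pf2 <- akaike_weights(fits2)
  expect_equal(unname(pf2$akaike_weights), rep(1 / 3, 3))
  expect_equal(pf2$label, "swarm")

  expect_error(akaike_weights(list(mk("swarm_uniform", NaN, 0),
                                   mk("stream_bimodal", -1, 2),
                                   mk("flock_unimodal", -1, 2))), "non-finite")
})

test_that("seeded samples from each pattern are labeled correctly and confidently", {
  set.seed(21)
  ps <- classify_pattern(r_stream(500, pi / 4, 4))
  expect_equal(ps$label, "stream")
  expect_gt(ps$akaike_weights["stream"], 0.99)
  set.seed(20)
  pw <- classify_pattern(runif(500, 0, 2 * pi))
  expect_equal(pw$label, "swarm")
  set.seed(23)
  pf <- classify_pattern(rvonmises(500, pi, 4))
  expect_equal(pf$label, "flock")
  expect_gt(pf$akaike_weights["flock"], 0.99)
})

test_that("undersized samples return a null label instead of an error", {
  res <- classify_pattern(runif(10, 0, 2 * pi), min_n = 30)
  expect_true(is.na(res$label))
  expect_match(res$note, "insufficient")
})

test_that("classification is rotation-equivariant", {
  set.seed(31)
  th <- r_stream(300, 0.4, 3)
  phi <- 1.234
  a <- classify_pattern(th)
  b <- classify_pattern((th + phi) %% (2 * pi))
  expect_equal(a$akaike_weights, b$akaike_weights, tolerance = 1e-6)
  expect_equal(a$aic, b$aic, tolerance = 1e-6)
  expect_lt(circ_diff(a$fits[[3]]$mu + phi, b$fits[[3]]$mu), 1e-4)
  expect_lt(circ_diff(a$fits[[2]]$mu + phi, b$fits[[2]]$mu, per = pi), 1e-3)
})

test_that("the prescribed AIC classifier separates the directional classes", {
  # Directional classes are essentially perfectly recovered at kappa = 3;
  # truly uniform samples are overfitted by a directional family whenever
  # the Rayleigh-type likelihood gain exceeds the AIC penalty (prob ~ e^-2
  # per alternative), so swarm recall is structurally ~75% and its errors
  # can only be overfit directional labels.
  classes <- c("swarm", "stream", "flock")
  acc <- sapply(classes, function(cls) {
    labs <- sapply(1:40, function(s) {
      set.seed(s)
      th <- switch(cls,
        swarm = runif(200, 0, 2 * pi),
        stream = r_stream(200, pi / 3, 3),
        flock = rvonmises(200, pi / 4, 3))
      classify_pattern(th)$label
    })
    mean(labs == cls)
  })
  expect_gte(acc["stream"], 0.95)
  expect_gte(acc["flock"], 0.95)
  expect_gt(acc["swarm"], 0.5)
})

test_that("circular KDE integrates to one and limits to the uniform density", {
  k <- circular_kde(0, bandwidth_kappa = 8)
  step <- k$grid[2] - k$grid[1]
  expect_lt(abs(sum(k$density) * step - 1), 1e-6)
  expect_equal(k$density, dvonmises(k$grid, 0, 8), tolerance = 1e-12)

  set.seed(5)
  k2 <- circular_kde(runif(50, 0, 2 * pi), bandwidth_kappa = 1e-6)
  expect_lt(max(abs(k2$density - 1 / (2 * pi))), 1e-6)
})

test_that("angle histograms conserve counts and close the last bin", {
  h <- angle_histogram(c(0, pi), n_bins = 4)
  expect_equal(h$counts, c(1, 0, 1, 0))
  set.seed(6)
  th <- runif(137, 0, 2 * pi)
  expect_equal(sum(angle_histogram(th, 7)$counts), 137)
  expect_equal(angle_histogram(2 * pi - 1e-9, 8)$counts[8], 1)
})
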