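test_that("CSV tracks round-trip losslessly and infer the frame interval", {
  df <- data.frame(track_id = "a", frame = 0:2, t_min = c(0, 10, 20),
                   x_um = c(0, 1, 3), y_um = c(0, -2, 1))
  tt <- track_table(df)
  expect_equal(attr(tt, "frame_interval"), 10)
  expect_equal(nrow(tt), 3)

  f <- tempfile(fileext = ".csv")
  write_tracks(tt, f)
  back <- read_tracks(f)
  expect_equal(back$x_um, tt$x_um, tolerance = 1e-6)
  expect_equal(back$y_um, tt$y_um, tolerance = 1e-6)
  expect_equal(back$t_min, tt$t_min, tolerance = 1e-6)

  # empty table -> header-only file
  f2 <- tempfile(fileext = ".csv")
  write_tracks(tt[0, ], f2)
  expect_equal(readLines(f2), "track_id,frame,t_min,x_um,y_um")

  # byte-stable output
  sim <- simulate_trajectories("swarm", n_cells = 20, n_frames = 10, seed = 5)
  fa <- tempfile(); fb <- tempfile()
  write_tracks(sim$tracks, fa); write_tracks(sim$tracks, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("TrackMate XML ingestion handles track-scoped spots and round-trips", {
  sim <- simulate_trajectories("flock", n_cells = 5, n_frames = 6, seed = 2)
  f <- tempfile(fileext = ".xml")
  write_tracks(sim$tracks, f, format = "trackmate-xml")
  back <- read_tracks(f, frame_interval = 10)
  expect_equal(length(unique(back$track_id)), 5)
  ka <- compute_kinematics(sim$tracks); kb <- compute_kinematics(back)
  expect_equal(sort(ka$speed), sort(kb$speed), tolerance = 1e-6)

  # two tracks referencing the same spot id stay independent
  xml <- paste0('<TrackMate><Model><AllSpots><SpotsInFrame frame="0">',
    '<Spot ID="1" POSITION_T="0" POSITION_X="0" POSITION_Y="0"/>',
    '<Spot ID="2" POSITION_T="10" POSITION_X="1" POSITION_Y="0"/>',
    '</SpotsInFrame></AllSpots><AllTracks>',
    '<Track TRACK_ID="0"><Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/></Track>',
    '<Track TRACK_ID="1"><Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/></Track>',
    '</AllTracks></Model></TrackMate>')
  f2 <- tempfile(fileext = ".xml")
  writeLines(xml, f2)
  two <- read_tracks(f2)
  expect_equal(length(unique(two$track_id)), 2)

  # malformed: edge pointing at a missing spot
  bad <- sub('SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/></Track></AllTracks>',
             'SPOT_SOURCE_ID="1" SPOT_TARGET_ID="99"/></Track></AllTracks>', xml)
  f3 <- tempfile(fileext = ".xml")
  writeLines(bad, f3)
  expect_error(read_tracks(f3), "unknown spot")
})

test_that("per-step kinematics match hand arithmetic and flag stationary steps", {
  df <- data.frame(track_id = "t1", t_min = c(0, 10, 20, 30),
                   x_um = c(0, 1, 1, 1), y_um = c(0, 0, -2, -2))
  kin <- compute_kinematics(track_table(df))
  expect_equal(nrow(kin), 3)           # n_samples - 1
  expect_equal(kin$speed[1], 6)        # 1 um / 10 min = 6 um/h
  expect_equal(kin$theta[1], 0)
  expect_equal(kin$speed[2], 12)       # 2 um down
  expect_equal(kin$theta[2], 3 * pi / 2)
  expect_false(kin$valid[3])           # zero displacement
  expect_equal(kin$speed[3], 0)

  bad <- data.frame(track_id = "t", t_min = c(0, 10, 10), x_um = 1:3, y_um = 0)
  expect_error(track_table(bad), "strictly increasing")
})

test_that("kinematics row count, rotation equivariance and rigid invariance hold", {
  sim <- simulate_trajectories("stream", n_cells = 12, n_frames = 15, seed = 9)
  kin <- compute_kinematics(sim$tracks)
  expect_equal(nrow(kin), 12 * 14)

  phi <- 0.7
  rot <- sim$tracks
  x <- rot$x_um * cos(phi) - rot$y_um * sin(phi)
  y <- rot$x_um * sin(phi) + rot$y_um * cos(phi)
  rot$x_um <- x; rot$y_um <- y
  krot <- compute_kinematics(track_table(as.data.frame(rot), 10))
  v <- kin$valid
  expect_lt(max(circ_diff(krot$theta[v], (kin$theta[v] + phi) %% (2 * pi))), 1e-9)
  expect_equal(krot$speed, kin$speed, tolerance = 1e-9)

  # translation + reflection leave speed unchanged
  tr <- sim$tracks
  tr$x_um <- -tr$x_um + 50; tr$y_um <- tr$y_um + 120
  ktr <- compute_kinematics(track_table(as.data.frame(tr), 10))
  expect_equal(ktr$speed, kin$speed, tolerance = 1e-12)
})

test_that("zone assignment is half-open, supports overlap, defaults to unzoned", {
  df <- data.frame(track_id = rep(c("a", "b", "c"), each = 2),
                   t_min = rep(c(0, 10), 3),
                   x_um = c(9.5, 10.5, 4, 6, 90, 92),
                   y_um = c(0, 0, 0, 0, 0, 0))
  kin <- compute_kinematics(track_table(df))
  # midpoints: a -> x = 10 (on the upper bound), b -> x = 5, c -> x = 91
  z1 <- zone_roi("Z1", 0, 10, -5, 5)
  z2 <- zone_roi("Z2", 0, 20, -5, 5)
  lab <- assign_zones(kin, list(z1, z2))
  expect_false(any(lab$zone == "Z1" & lab$track_id == "a"))  # x == x_max
  expect_true(any(lab$zone == "Z2" & lab$track_id == "a"))
  expect_equal(sort(lab$zone[lab$track_id == "b"]), c("Z1", "Z2"))
  expect_equal(lab$zone[lab$track_id == "c"], "unzoned")
  expect_true(all(assign_zones(kin, list())$zone == "unzoned"))
})

test_that("speed summaries average valid steps and report empty groups as NA", {
  df <- data.frame(track_id = "t", t_min = c(0, 10, 20, 30),
                   x_um = c(0, 1, 3, 3), y_um = 0)
  kin <- compute_kinematics(track_table(df))
  kin$zone <- c("A", "A", "B")
  s <- summarize_speeds(kin)
  expect_equal(s$summary$mean[s$summary$group == "A"], 9)  # (6 + 12)/2
  expect_equal(s$summary$n[s$summary$group == "B"], 0)     # only a stationary step
  expect_true(is.na(s$summary$mean[s$summary$group == "B"]))
  s2 <- summarize_speeds(kin, include_stationary = TRUE)
  expect_equal(s2$summary$mean[s2$summary$group == "B"], 0)
})

test_that("generator speeds reach the configured mean at large samples", {
  sim <- simulate_trajectories("swarm", n_cells = 50, n_frames = 201, seed = 11)
  kin <- compute_kinematics(sim$tracks)
  expect_equal(nrow(kin), 10000)
  expect_lt(abs(mean(kin$speed[kin$valid]) - 6.27) / 6.27, 0.05)
})
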