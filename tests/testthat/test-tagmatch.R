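test_that("haversine matches the closed form and an independent oracle", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  # one degree along the equator: 2*pi*R/360
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-10)
  expect_equal(haversine_km(19.5, -156.2, 20.1, -155.8),
               haversine_km(20.1, -155.8, 19.5, -156.2))
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(c(-156.2, 19.5), c(-155.8, 20.1),
                                  r = 6371000) / 1000
  expect_equal(haversine_km(19.5, -156.2, 20.1, -155.8), ref,
               tolerance = 1e-8)
  expect_error(haversine_km(100, 0, 0, 0), "range")
})

straight_track <- function(n = 100, lat0 = 19.7, lon0 = -156.3) {
  t0 <- as.POSIXct("2009-11-03 00:00:00", tz = "UTC")
  data.frame(t_utc = t0 + (0:(n - 1)) * 600,
             lat = lat0 + (0:(n - 1)) * 1e-4, lon = lon0)
}

fix_at <- function(track, i, offset_km, acc = 1.0) {
  data.frame(t_utc = track$t_utc[i],
             lat = track$lat[i],
             lon = track$lon[i] + offset_km /
               (111.195 * cos(track$lat[i] * pi / 180)),
             accuracy_radius_km = acc)
}

test_that("the 6 km / 1.5 km encounter rule admits and rejects correctly", {
  tr <- straight_track()
  fixes <- rbind(fix_at(tr, 30, 5.8, 1.5),   # qualifies
                 fix_at(tr, 50, 7.0, 1.0),   # too far
                 fix_at(tr, 70, 5.0, 3.0))   # accuracy gate
  res <- find_potential_encounters(tr, fixes)
  expect_equal(res$fixes$qualifies, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(res$encounters), 1)
  expect_equal(res$encounters$n_fixes, 1)
  expect_equal(res$fixes$distance_km[1], 5.8, tolerance = 0.01)
})

test_that("fixes outside the track span are skipped with a warning", {
  tr <- straight_track()
  f <- fix_at(tr, 10, 3)
  f$t_utc <- tr$t_utc[1] - 86400
  expect_warning(res <- find_potential_encounters(tr, f), "skipped")
  expect_false(any(res$fixes$qualifies))
})

test_that("relaxing both gates admits every in-span fix", {
  tr <- straight_track()
  fixes <- rbind(fix_at(tr, 10, 50, 10), fix_at(tr, 40, 200, 99),
                 fix_at(tr, 90, 3, 0.5))
  res <- find_potential_encounters(tr, fixes, max_km = Inf,
                                   max_acc_km = Inf)
  expect_true(all(res$fixes$qualifies))
})

test_that("hypothetical dive profile centres surfacings on the fixes", {
  dp <- dive_cycle_params()
  t0 <- 1e5
  prof <- hypothetical_dive_profile(t0, dp)
  expect_equal(range(prof$profile$time),
               c(t0 - dp$surface_duration_s / 2,
                 t0 + dp$surface_duration_s / 2))
  expect_true(all(prof$profile$depth_m == 0))
  expect_equal(nrow(prof$vocal_intervals), 0)
})

test_that("dives between fixes are u-shaped, symmetric when rates match, and vocal at depth", {
  dp <- dive_cycle_params(descent_rate_m_s = 1, ascent_rate_m_s = 1)
  fixes <- c(0, dp$deep_dive_duration_s + dp$surface_duration_s)
  prof <- hypothetical_dive_profile(fixes, dp)
  expect_equal(nrow(prof$dives), 1)
  d <- prof$dives[1, ]
  mid <- (d$start + d$end) / 2
  # symmetric about the dive midpoint
  v <- prof$vocal_intervals[1, ]
  expect_equal(mid - v$start, v$end - mid, tolerance = 1e-9)
  expect_gt(d$max_depth_m, dp$vocal_onset_depth_m)

  shallow <- dive_cycle_params(vocal_onset_depth_m = 5000)
  prof2 <- hypothetical_dive_profile(fixes, shallow)
  expect_equal(nrow(prof2$vocal_intervals), 0)
})

test_that("fixes closer than a dive cycle are rejected", {
  dp <- dive_cycle_params()
  expect_error(hypothetical_dive_profile(c(0, 600), dp), "dive cycle")
})

test_that("interval intersection follows interval algebra", {
  empty <- recording_overlap(data.frame(start = 0, end = 10),
                             data.frame(start = 20, end = 30))
  expect_equal(empty$total_s, 0)
  r <- recording_overlap(data.frame(start = 0, end = 100),
                         data.frame(start = 50, end = 150))
  expect_equal(r$overlap$start, 50)
  expect_equal(r$overlap$end, 100)
  expect_equal(r$total_s, 50)
  # commutativity and the upper bound
  set.seed(14)
  a <- data.frame(start = sort(runif(5, 0, 100)))
  a$end <- a$start + runif(5, 1, 10)
  b <- data.frame(start = sort(runif(4, 0, 100)))
  b$end <- b$start + runif(4, 1, 10)
  ab <- recording_overlap(a, b)
  ba <- recording_overlap(b, a)
  expect_equal(ab$total_s, ba$total_s)
  expect_lte(ab$total_s, min(sum(a$end - a$start), sum(b$end - b$start)))
})

test_that("a whale dive during the glider surface interval has zero overlap", {
  # the glider records 0-3000 s (deep) and is off 3000-7000 s; the whale's
  # first vocal interval overlaps the recording, the second does not
  rec <- data.frame(start = c(0, 7000), end = c(3000, 10000))
  dp <- dive_cycle_params(deep_dive_duration_s = 2000,
                          surface_duration_s = 120,
                          descent_rate_m_s = 1, ascent_rate_m_s = 1,
                          vocal_onset_depth_m = 400)
  fixes <- c(2060, 2060 + 2120, 2060 + 2 * 2120)
  prof <- hypothetical_dive_profile(fixes, dp)
  expect_equal(nrow(prof$vocal_intervals), 2)
  ov <- recording_overlap(prof$vocal_intervals, rec)
  # oracle: manual intersection of the two vocal intervals with [0,3000]
  v <- prof$vocal_intervals
  manual <- sum(pmax(0, pmin(v$end, 3000) - pmax(v$start, 0)))
  expect_equal(ov$total_s, manual)
  # the second dive (within 3000-7000 s) contributes nothing
  expect_true(all(ov$overlap$end <= 3000))
  expect_gt(ov$total_s, 0)
})

test_that("recording intervals collapse runs of recording samples", {
  t0 <- as.POSIXct("2009-11-03 00:00:00", tz = "UTC")
  track <- data.frame(t_utc = t0 + 0:9 * 60,
                      recording = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                    TRUE, TRUE, FALSE, FALSE))
  ri <- recording_intervals(track)
  expect_equal(nrow(ri), 2)
  expect_equal(as.numeric(ri$start - t0, units = "mins"), c(1, 6))
})

test_that("a co-located tag track is matched and a distant one is not", {
  glider <- make_glider_track(n_dives = 3)
  mid <- glider[round(nrow(glider) / 2), ]
  near <- make_tag_track(3, start_utc = glider$t_utc[1] + 3600,
                         start_lat = mid$lat,
                         start_lon = mid$lon + 3 / (111.195 *
                           cos(mid$lat * pi / 180)),
                         speed_km_h = 0, accuracy_km = 0.5, seed = 3)
  res <- find_potential_encounters(glider, near$fixes)
  expect_gte(nrow(res$encounters), 1)
  far <- near
  far$fixes$lon <- far$fixes$lon + 20 / (111.195 * cos(mid$lat * pi / 180))
  res2 <- find_potential_encounters(glider, far$fixes)
  expect_equal(nrow(res2$encounters), 0)
  # and the acoustic side of the loop: a beaked-whale train in the
  # recording is detected
  tr <- make_click_train(PRESETS$blainville, 6, 3, FS, snr_db = 15, seed = 4)
  expect_gte(nrow(detect_clicks(tr$wave, FS)), 5)
})
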