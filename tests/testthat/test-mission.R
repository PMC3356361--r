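test_that("per-class file percentages follow the published arithmetic", {
  flags <- data.frame(file_id = seq_len(11615),
                      beaked_whale = c(rep(TRUE, 109), rep(FALSE, 11506)))
  expect_equal(percent_with_class(flags, "beaked_whale"), 100 * 109 / 11615)
  expect_equal(round(percent_with_class(flags, "beaked_whale")), 1)
  flags$beaked_whale <- FALSE
  expect_equal(percent_with_class(flags, "beaked_whale"), 0)
  flags$beaked_whale <- TRUE
  expect_equal(percent_with_class(flags, "beaked_whale"), 100)
  expect_error(percent_with_class(flags[0, ], "beaked_whale"), "empty")
})

test_that("diel profile buckets by local hour and respects absence", {
  t0 <- as.POSIXct("2009-11-01 00:00:00", tz = "UTC")
  # local hour = UTC - 10; positives only during local night 20:00-03:00
  hrs_utc <- rep(0:23, each = 20)
  flags <- data.frame(t_utc = t0 + hrs_utc * 3600,
                      delphinid = ((hrs_utc - 10) %% 24) %in%
                        c(20:23, 0:3))
  dp <- diel_profile(flags, "delphinid", utc_offset_h = -10)
  expect_equal(dp$percent[dp$hour %in% 9:16], rep(0, 8))
  expect_equal(dp$percent[dp$hour %in% c(20:23, 0:3)], rep(100, 8))
  expect_equal(sum(dp$positive_minutes), sum(flags$delphinid) * 1)
  expect_equal(sum(dp$observation_minutes), nrow(flags) * 1)
})

test_that("diel profile rotates under a global time shift", {
  set.seed(12)
  t0 <- as.POSIXct("2009-11-01 00:00:00", tz = "UTC")
  flags <- data.frame(t_utc = t0 + sample(0:23, 500, replace = TRUE) * 3600,
                      cls = runif(500) < 0.3)
  a <- diel_profile(flags, "cls", utc_offset_h = 0)
  flags2 <- flags
  flags2$t_utc <- flags$t_utc + 5 * 3600
  b <- diel_profile(flags2, "cls", utc_offset_h = 0)
  expect_equal(b$percent, a$percent[match((0:23 - 5) %% 24, a$hour)])
})

test_that("a diel prevalence peak is recovered from mission truth", {
  h <- 0:23
  mult <- 1 + cos(2 * pi * (h - 22) / 24)         # peak at 22:00 local
  sc <- mission_scenario(n_dives = 40, files_per_dive = 20,
                         prevalence = c(delphinid = 0.45),
                         diel_profile = mult, diel_classes = "delphinid")
  m <- make_mission(sc, audio = "none", seed = 77)
  dp <- diel_profile(m$files, "delphinid", utc_offset_h = sc$utc_offset_h)
  pk <- dp$hour[which.max(dp$percent)]
  circ_dist <- min(abs(pk - 22), 24 - abs(pk - 22))
  expect_lte(circ_dist, 1)
})

test_that("uniform prevalence gives a flat diel profile within binomial error", {
  sc <- mission_scenario(n_dives = 40, files_per_dive = 20,
                         prevalence = c(delphinid = 0.4))
  m <- make_mission(sc, audio = "none", seed = 78)
  dp <- diel_profile(m$files, "delphinid", utc_offset_h = sc$utc_offset_h)
  n <- dp$observation_minutes / sc$file_duration_s * 60
  ok <- !is.na(dp$percent) & n > 0
  z <- (dp$percent[ok] / 100 - 0.4) / sqrt(0.4 * 0.6 / n[ok])
  expect_true(all(abs(z) < 4))
})

test_that("one-way ANOVA behaves at the degenerate ends", {
  r <- day_night_anova(c(10, 11, 12, 22, 23, 0), c(1, 2, 3, 1, 2, 3))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  r2 <- day_night_anova(c(10, 11, 12, 22, 23, 0),
                        c(0, 0, 1e-9, 1, 1, 1 + 1e-9))
  expect_lt(r2$p, 0.01)
  r3 <- day_night_anova(c(10, 11, 12, 22, 23, 0), c(1, 1, 1, 2, 2, 2))
  expect_true(is.na(r3$p))      # zero within-group variance sentinel
  expect_identical(r3$F, Inf)
})

test_that("the ANOVA matches t^2 = F and aov to near machine precision", {
  set.seed(41)
  day <- rnorm(12, 5, 2)
  night <- rnorm(15, 9, 2)
  r <- day_night_anova(c(rep(10, 12), rep(22, 15)), c(day, night))
  tt <- t.test(day, night, var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  # three groups against the stock aov implementation
  g <- rep(c("a", "b", "c"), times = c(8, 9, 10))
  v <- rnorm(27, rep(c(1, 2, 4), times = c(8, 9, 10)))
  mine <- gliderpam:::oneway_anova(v, g)
  ref <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("encounters are counted per dive with detections", {
  t0 <- as.POSIXct("2009-11-01 00:00:00", tz = "UTC")
  n <- 850
  flags <- data.frame(file_id = seq_len(n),
                      dive_id = rep(1:85, each = 10),
                      t_utc = t0 + seq_len(n) * 60,
                      bw = FALSE)
  pos_dives <- c(3, 10, 22, 40, 51, 62, 80)
  flags$bw[flags$dive_id %in% pos_dives] <- TRUE
  enc <- count_encounters(flags, "bw")
  expect_equal(nrow(enc), 7)
  expect_equal(nrow(count_encounters(transform(flags, bw = FALSE), "bw")), 0)
  one <- transform(flags, bw = dive_id == 3)
  expect_equal(nrow(count_encounters(one, "bw")), 1)
})

test_that("encounter rate is recording hours per encounter", {
  expect_equal(round(encounter_rate(194, 7), 1), 27.7)
  expect_equal(encounter_rate(10, 10), 1)
  expect_identical(encounter_rate(100, 0), Inf)
})

test_that("detector performance reproduces the published accounting", {
  ft <- make_flag_tables(11615, 85, truth_pos = 1:109,
                         det_pos = c(1:79, 11000:11020))
  perf <- detector_performance(ft$truth, ft$det, "bw")
  expect_equal(round(perf$file_recall_pct), 72)
  expect_equal(perf$n_truth_files, 109)
  expect_equal(perf$n_detected_files, 79)

  perfect <- detector_performance(ft$truth, ft$truth, "bw")
  expect_equal(perfect$file_recall_pct, 100)
  expect_equal(perfect$dive_false_detections, 0)
})

test_that("dive-level false detections are flagged dives without truth", {
  n <- 850
  base <- data.frame(file_id = seq_len(n), dive_id = rep(1:85, each = 10))
  truth <- det <- base
  truth$bw <- base$dive_id %in% c(1, 5, 9, 20, 33, 47, 60)   # 7 true dives
  det$bw <- base$dive_id %in% c(1, 5, 9, 20, 33, 47, 60, 70, 75, 80)
  perf <- detector_performance(truth, det, "bw")
  expect_equal(perf$dive_true_detections, 7)
  expect_equal(perf$dive_false_detections, 3)
  expect_error(detector_performance(truth[-1, ], det, "bw"), "different")
})
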