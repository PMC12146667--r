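# detection QC: post-release trim, shed/dead signature, minimum period

test_that("post-release trimming removes a closed 48-h window", {
  tags <- fixture_tags("T1", release_time = utc("2021-01-01 00:00:00"))
  det <- det_df("T1", "R1", utc("2021-01-01 00:00:00") +
                              c(1, 47.9, 48, 49) * 3600)
  out <- trim_post_release(det, tags)
  expect_equal(nrow(out), 1)
  expect_equal(out$timestamp, utc("2021-01-03 01:00:00"))

  # everything inside the window -> empty (allowed)
  det2 <- det_df("T1", "R1", utc("2021-01-01 00:00:00") + c(1, 40) * 3600)
  expect_equal(nrow(trim_post_release(det2, tags)), 0)
})

test_that("shed/dead flagging catches terminal single-receiver runs only", {
  # year-long continuous pings at one receiver -> flagged, animal removed
  t_shed <- utc("2021-01-01 00:00:00") + seq(0, 400 * 86400, by = 6 * 3600)
  shed <- det_df("SHED", "R1", t_shed)
  out <- flag_shed_or_dead(shed)
  expect_equal(out$flagged, "SHED")
  expect_equal(nrow(out$detections), 0)

  # alternating among 4 receivers over a year -> not flagged
  t_mix <- utc("2021-01-01 00:00:00") + seq(0, 365 * 86400, by = 6 * 3600)
  mix <- det_df("MIX", rep(c("R1", "R2", "R3", "R4"),
                           length.out = length(t_mix)), t_mix)
  expect_length(flag_shed_or_dead(mix)$flagged, 0)

  # 3-day terminal run below the 7-day threshold -> not flagged
  t_short <- c(utc("2021-01-01 00:00:00"),
               utc("2021-02-01 00:00:00") + seq(0, 3 * 86400, by = 3600))
  short <- det_df("SHORT", c("R2", rep("R1", length(t_short) - 1)), t_short)
  expect_length(flag_shed_or_dead(short)$flagged, 0)

  # a 10-day run broken by a 30-h silence -> not flagged
  t_gap <- utc("2021-01-01 00:00:00") +
    c(seq(0, 4 * 86400, by = 3600), 4 * 86400 + 30 * 3600 +
        seq(0, 5 * 86400, by = 3600))
  gap <- det_df("GAP", "R1", t_gap)
  expect_length(flag_shed_or_dead(gap)$flagged, 0)

  # movement to a second site after a long run -> terminal run is short
  t_move <- c(utc("2021-01-01 00:00:00") + seq(0, 20 * 86400, by = 3600),
              utc("2021-02-01 00:00:00"))
  move <- det_df("MOVE", c(rep("R1", length(t_move) - 1), "R2"), t_move)
  expect_length(flag_shed_or_dead(move)$flagged, 0)
})

test_that("detection-period filter excludes <= 14 days and reports flags", {
  # boundary: period of exactly 14 days excluded, 15 days retained
  tags <- fixture_tags(c("P14", "P15"),
                       release_time = utc("2021-03-01 00:00:00"))
  start <- utc("2021-03-03 00:00:00")   # post-48h window end
  det <- rbind(
    det_df("P14", "R1", c(start + 3600, utc("2021-03-16 12:00:00"))),
    det_df("P15", "R1", c(start + 3600, utc("2021-03-17 12:00:00"))))
  out <- apply_min_detection_period(det, tags, tz = "UTC")
  rep14 <- out$report[out$report$tag_id == "P14", ]
  rep15 <- out$report[out$report$tag_id == "P15", ]
  expect_equal(rep14$detection_period_days, 14)
  expect_equal(rep14$flag, "short_period")
  expect_equal(rep15$detection_period_days, 15)
  expect_true(rep15$retained)
  expect_setequal(unique(out$detections$tag_id), "P15")
})

test_that("filter report counts short-period and never-detected animals", {
  # 5 animals retained-length, 2 short-period, 3 never detected
  tags <- fixture_tags(sprintf("T%d", 1:10),
                       release_time = utc("2021-01-01 00:00:00"))
  start <- utc("2021-01-03 00:00:00")
  long_det <- function(id) det_df(id, "R1", start + c(1, 40 * 86400))
  short_det <- function(id) det_df(id, "R1", start + c(1, 5 * 86400))
  det <- rbind(long_det("T1"), long_det("T2"), long_det("T3"),
               long_det("T4"), long_det("T5"),
               short_det("T6"), short_det("T7"))
  tele <- list(detections = det, tags = tags,
               receivers = fixture_receivers(square_island(), "R1",
                                             1500, 0),
               land = square_island(), tz = "UTC")
  qc <- qc_detections(tele)
  tb <- table(qc$report$flag)
  expect_equal(unname(tb["short_period"]), 2)
  expect_equal(unname(tb["never_detected"]), 3)
  expect_equal(sum(qc$report$retained), 5)
  # exactly one primary flag per animal
  expect_true(all(qc$report$flag %in%
                    c("none", "short_period", "never_detected",
                      "shed_or_dead")))
})

test_that("the QC pipeline is order-stable and respects deployments", {
  sim <- simulate_island(tiny_scenario(), seed = 11)
  tele <- as_telemetry(sim)
  qc1 <- qc_detections(tele)
  qc2 <- qc_detections(tele)
  expect_identical(qc1$report, qc2$report)
  expect_identical(qc1$detections, qc2$detections)

  # no retained detection violates its receiver's deployment interval
  i <- match(qc1$detections$receiver_id, qc1$receivers$site)
  expect_true(all(qc1$detections$timestamp >= qc1$receivers$active_from[i]))
  expect_true(all(qc1$detections$timestamp <= qc1$receivers$active_to[i]))
})
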