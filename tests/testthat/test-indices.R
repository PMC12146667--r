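# residency/roaming indices, monthly rule, availability, size split

test_that("detection periods count whole days inclusive of both ends", {
  rel <- utc("2021-02-27 00:00:00")   # post-48h start = 2021-03-01
  one <- detection_period(utc("2021-03-01 12:00:00"), rel, tz = "UTC")
  expect_equal(as.integer(one), 1)
  span <- detection_period(utc(c("2021-03-02 08:00:00",
                                 "2021-03-15 23:00:00")), rel, tz = "UTC")
  expect_equal(as.integer(span), 15)
  # tagging convention starts at the release date
  span2 <- detection_period(utc("2021-03-15 23:00:00"),
                            utc("2021-03-01 10:00:00"),
                            convention = "tagging", tz = "UTC")
  expect_equal(as.integer(span2), 15)
  expect_true(is.na(detection_period(utc(character(0)), rel, tz = "UTC")))
})

test_that("residency index is detected days over period days", {
  expect_equal(residency_index(seq(as.Date("2021-01-01"), by = 1,
                                   length.out = 45), 100), 0.45)
  days <- seq(as.Date("2021-01-01"), as.Date("2021-01-30"), by = 1)
  expect_equal(residency_index(days, 30), 1.0)
  # alternate days over a 30-day period: 15 detected days by enumeration
  alt <- seq(as.Date("2021-01-01"), as.Date("2021-01-30"), by = 2)
  expect_equal(length(alt), 15)
  expect_equal(residency_index(alt, 30), 0.5)
  # repeated detections on one day count once
  expect_equal(residency_index(rep(as.Date("2021-01-01"), 10), 10), 0.1)
})

test_that("roaming index corrects for receiver availability", {
  expect_equal(roaming_index(paste0("S", 1:12), paste0("S", 1:18)),
               12 / 18)
  expect_equal(roaming_index("S1", paste0("S", 1:18)), 1 / 18)
  expect_error(roaming_index("S1", character(0)), "available")

  # 21 receivers, 3 deployed only after the animal's last detection:
  # brute-force interval-overlap oracle gives the denominator
  mask <- square_island()
  n <- 21
  from <- rep(utc("2021-01-01"), n)
  to <- rep(utc("2024-01-01"), n)
  from[19:21] <- utc("2022-06-01")    # deployed after the period below
  rec <- fixture_receivers(mask, paste0("S", 1:n),
                           x = 1500 + seq_len(n), y = 0)
  rec$active_from <- from; rec$active_to <- to
  p_start <- as.Date("2021-02-01"); p_end <- as.Date("2021-12-31")
  oracle <- sum(vapply(seq_len(n), function(i) {
    max(as.Date(from[i]), p_start) <= min(as.Date(to[i]), p_end)
  }, TRUE))
  expect_equal(oracle, 18)
  avail <- available_sites(rec, p_start, p_end, tz = "UTC")
  expect_length(avail, 18)
  # partial overlap counts as available
  rec$active_from[1] <- utc("2021-12-30")
  expect_true("S1" %in% available_sites(rec, p_start, p_end, tz = "UTC"))
})

test_that("monthly records obey the >14-day boundary rule", {
  mask <- square_island()
  rec <- fixture_receivers(mask, c("R1", "R2"), c(1500, -1500), c(0, 0))
  # release so that the post-48h period is 2021-01-20 .. 2021-03-10
  tags <- fixture_tags("T1", release_time = utc("2021-01-18 00:00:00"))
  days <- seq(as.Date("2021-01-20"), as.Date("2021-03-10"), by = 1)
  det <- det_df("T1", "R1", utc(paste(days, "06:00:00")))
  qc <- fixture_qc(det, rec, tags, mask)
  idx <- compute_indices(qc, monthly = TRUE)
  m <- idx[idx$scope == "month", ]
  # January covers 12 days -> dropped; March covers 10 days -> dropped
  expect_equal(m$month, 2)
  expect_equal(m$period_days, 28)
  expect_equal(m$resi, 1.0)    # detected every day of the retained month

  # 20 of 31 covered days in a retained full month -> 20/31
  tags2 <- fixture_tags("T2", release_time = utc("2021-02-26 00:00:00"))
  mdays <- seq(as.Date("2021-03-01"), as.Date("2021-03-31"), by = 1)
  det2 <- det_df("T2", "R1", utc(paste(mdays[1:20], "10:00:00")))
  det2 <- rbind(det2, det_df("T2", "R1", utc("2021-03-31 10:00:00")))
  qc2 <- fixture_qc(det2, rec, tags2, mask)
  m2 <- compute_indices(qc2, monthly = TRUE)
  m2 <- m2[m2$scope == "month", ]
  expect_equal(m2$days_detected, 21)
  expect_equal(m2$resi, 21 / 31)
})

test_that("month-length-weighted monthly residency reproduces overall residency", {
  mask <- square_island()
  rec <- fixture_receivers(mask, "R1", 1500, 0)
  # period exactly spans full months: 2021-02-01 .. 2021-04-30
  tags <- fixture_tags("T1", release_time = utc("2021-01-30 00:00:00"))
  set.seed(3)
  days <- seq(as.Date("2021-02-01"), as.Date("2021-04-30"), by = 1)
  hit <- sort(c(1, sample(2:(length(days) - 1), 40), length(days)))
  det <- det_df("T1", "R1", utc(paste(days[hit], "12:00:00")))
  qc <- fixture_qc(det, rec, tags, mask)
  idx <- compute_indices(qc, monthly = TRUE)
  ov <- idx[idx$scope == "overall", ]
  mo <- idx[idx$scope == "month", ]
  expect_equal(sum(mo$resi * mo$period_days) / sum(mo$period_days),
               ov$resi, tolerance = 1e-12)
  expect_equal(sum(mo$period_days), ov$period_days)
})

test_that("roaming availability is monotone as deployment windows widen", {
  mask <- square_island()
  rec <- fixture_receivers(mask, paste0("S", 1:6),
                           x = 1500 + 1:6 * 10, y = 0)
  p_start <- as.Date("2021-03-01"); p_end <- as.Date("2021-06-01")
  rec$active_from <- utc("2021-07-01")
  rec$active_to <- utc("2021-08-01")
  widths <- c(0, 40, 100, 200, 400)
  n_avail <- vapply(widths, function(w) {
    r <- rec
    r$active_from <- rec$active_from - w * 86400
    length(available_sites(r, p_start, p_end, tz = "UTC"))
  }, 0L)
  expect_true(all(diff(n_avail) >= 0))
})

test_that("size split picks the largest interquartile gap", {
  tl <- c(1.0, 1.1, 1.2, 1.8, 1.9, 2.0)
  ss <- size_split(tl)
  expect_equal(ss$cutoff_m, 1.5)
  expect_equal(ss$labels, c("small", "small", "small", "large", "large",
                            "large"))
  # gap rule variants
  expect_equal(size_split(tl, gap_rule = "lower")$cutoff_m, 1.2)
  expect_equal(size_split(tl, gap_rule = "upper")$cutoff_m, 1.8)

  # evenly spaced: tie among equal gaps resolved toward the median
  ss2 <- size_split(1:8)
  expect_equal(ss2$cutoff_m, 4.5)

  expect_error(size_split(rep(2, 6)), "no gap")
  expect_error(size_split(c(1, 2, 3)), "length")
})
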