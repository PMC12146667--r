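# synthetic island generator: tracks, detection model, artefacts

test_that("presence and anchoring follow the archetype programme", {
  sc <- tiny_scenario()
  # presence identically zero -> no positions for that archetype
  sc$archetypes$migrant$monthly_presence <- rep(0, 12)
  tr <- simulate_tracks(sc, seed = 1)
  mig <- tr$tags$tag_id[tr$tags$archetype == "migrant"]
  expect_false(any(tr$positions$tag_id %in% mig))

  # single site, zero scatter -> every position at that site
  sc2 <- tiny_scenario(n_animals = c(offshore_seasonal = 2))
  sc2$archetypes$offshore_seasonal$site_weights <- c(PhillipDeep = 1)
  sc2$archetypes$offshore_seasonal$scatter_sd <- 0
  tr2 <- simulate_tracks(sc2, seed = 2)
  site <- sc2$receivers[sc2$receivers$site == "PhillipDeep", ]
  expect_true(all(tr2$positions$x == site$x))
  expect_true(all(tr2$positions$y == site$y))
})

test_that("the migrant archetype is almost absent June-October", {
  sc <- island_scenario(n_animals = c(migrant = 50))
  tr <- simulate_tracks(sc, seed = 3)
  td <- tr$truth_daily
  winter <- td$month %in% 6:10
  expect_lt(mean(td$present[winter]), 0.05)
  expect_gt(mean(td$present[td$month %in% c(12, 1, 2)]), 0.5)
})

test_that("detection rate at 250 m is half the transmission rate", {
  sc <- island_scenario()
  hs <- sc$receivers[sc$receivers$site == "Headstone", ]
  # stationary tag 250 m seaward of the hotspot receiver, 100 h
  n_steps <- 50
  pos <- data.frame(
    tag_id = "A69-0001",
    step_start = utc("2021-06-01 00:00:00") + (0:(n_steps - 1)) * 7200,
    x = hs$x - 250, y = hs$y, anchor = "Headstone")
  det <- simulate_detections(pos, sc, seed = 4)
  rate <- sum(det$receiver_id == "Headstone") / (n_steps * 2)
  # closed form: 0.5 * 3600 / mean(U(80, 140)) = 16.36 per hour
  expect_lt(abs(rate - 0.5 * 3600 / 110), 1.5)

  # point-blank: detection probability ~ 1/(1+e^-5) per transmission
  expect_equal(detection_probability(0), 1 / (1 + exp(-5)),
               tolerance = 1e-12)
  expect_equal(detection_probability(250), 0.5)

  # 5 km from every receiver: probability < 1e-4, zero detections
  far <- data.frame(tag_id = "A69-0001",
                    step_start = pos$step_start,
                    x = 40000, y = 0, anchor = "Headstone")
  expect_lt(detection_probability(5000), 1e-4)
  expect_equal(nrow(simulate_detections(far, sc, seed = 5)), 0)
})

test_that("artefact injection removes or replaces records as configured", {
  sc <- tiny_scenario(n_animals = c(pier_resident_a = 3))
  sc$archetypes$pier_resident_a$never_detected_prob <- 1
  sim <- simulate_island(sc, seed = 6)
  expect_equal(nrow(sim$detections), 0)
  expect_equal(nrow(sim$tags), 3)
  expect_true(all(sim$truth$artifacts$type == "never_detected"))

  # zero probabilities leave the detection set untouched
  sc0 <- tiny_scenario(n_animals = c(pier_resident_a = 2))
  sc0$archetypes$pier_resident_a$never_detected_prob <- 0
  sc0$archetypes$pier_resident_a$shed_tag_prob <- 0
  tr <- simulate_tracks(sc0, seed = 7)
  det <- simulate_detections(tr, sc0, seed = 8)
  inj <- inject_artifacts(det, tr, sc0, seed = 9)
  expect_identical(inj$detections, det)
  expect_equal(nrow(inj$artifacts), 0)
})

test_that("injected shed tags are flagged by the QC filter", {
  hits <- vapply(1:10, function(s) {
    sc <- tiny_scenario(n_animals = c(pier_resident_a = 1),
                        study_end = "2021-09-01")
    sc$archetypes$pier_resident_a$never_detected_prob <- 0
    sc$archetypes$pier_resident_a$shed_tag_prob <- 1
    sim <- simulate_island(sc, seed = 100 + s)
    tele <- as_telemetry(sim)
    det <- trim_post_release(tele$detections, tele$tags)
    length(flag_shed_or_dead(det)$flagged) == 1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("a daily presence probability p comes back as mean ResI near p", {
  sc <- island_scenario(n_animals = c(pier_resident_a = 20),
                        study_start = "2021-03-01",
                        study_end = "2022-03-01")
  p <- 0.6
  sc$archetypes$pier_resident_a$monthly_presence <- rep(p, 12)
  sc$archetypes$pier_resident_a$never_detected_prob <- 0
  sc$archetypes$pier_resident_a$shed_tag_prob <- 0
  sim <- simulate_island(sc, seed = 12)
  qc <- qc_detections(as_telemetry(sim))
  idx <- compute_indices(qc, monthly = FALSE)
  expect_lt(abs(mean(idx$resi) - p), 0.05)
})

test_that("simulated datasets round-trip through the standard files", {
  sc <- tiny_scenario(n_animals = c(offshore_seasonal = 2),
                      study_end = "2021-06-01")
  sim <- simulate_island(sc, seed = 13)
  dir <- withr::local_tempdir()
  write_scenario_files(sim, dir)
  tele <- read_telemetry(file.path(dir, "detections.csv"),
                         file.path(dir, "receivers.csv"),
                         file.path(dir, "tags.csv"),
                         file.path(dir, "land.geojson"))
  expect_equal(nrow(tele$detections), nrow(sim$detections))
  expect_equal(nrow(tele$tags), 2)
  expect_equal(tele$n_dropped_deployment, 0)
})
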