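# Fixture builders shared across the suite.  Everything is generated in
# code; no data files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A 2 x 2 km square island centred on the projection origin.
square_island <- function(half = 1000, lon0 = 167.95, lat0 = -29.03) {
  prj <- local_projection(lon0, lat0)
  xy <- rbind(c(-half, -half), c(half, -half), c(half, half),
              c(-half, half), c(-half, -half))
  ll <- prj$unproject(xy[, 1], xy[, 2])
  land_mask(list(ll), projection = prj)
}

# Receiver table in the square island's projected frame.
fixture_receivers <- function(mask, sites, x, y,
                              from = "2020-01-01", to = "2025-01-01") {
  ll <- mask$projection$unproject(x, y)
  n <- length(sites)
  data.frame(site = sites, lon = ll[, 1], lat = ll[, 2], x = x, y = y,
             depth_m = 20,
             active_from = rep_len(utc(from), n),
             active_to = rep_len(utc(to), n),
             stringsAsFactors = FALSE)
}

fixture_tags <- function(tag_id, species = "dusky", sex = "F",
                         total_length_m = 2, release_site = "R1",
                         release_time = utc("2021-01-01 00:00:00")) {
  data.frame(tag_id = tag_id, species = species, sex = sex,
             total_length_m = total_length_m, release_site = release_site,
             release_time = rep_len(release_time, length(tag_id)),
             stringsAsFactors = FALSE)
}

# Assemble a qc_result-shaped list directly from frames (bypasses file
# I/O; used where a test wants full control of the inputs).
fixture_qc <- function(det, receivers, tags, mask = square_island(),
                       tz = "UTC", convention = "post48") {
  det <- det[order(det$tag_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  structure(list(detections = det, report = NULL, receivers = receivers,
                 tags = tags, land = mask, tz = tz,
                 convention = convention,
                 params = list(window_h = 48)),
            class = "qc_result")
}

# Small scenario for fast end-to-end runs.
tiny_scenario <- function(n_animals = c(migrant = 3, pier_resident_a = 3,
                                        pier_resident_b = 3,
                                        offshore_seasonal = 2),
                          study_start = "2021-03-01",
                          study_end = "2021-11-01") {
  island_scenario(n_animals = n_animals, study_start = study_start,
                  study_end = study_end)
}

# detections data frame shorthand
det_df <- function(tag_id, receiver_id, timestamp) {
  data.frame(tag_id = tag_id, receiver_id = receiver_id,
             timestamp = timestamp, stringsAsFactors = FALSE)
}
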