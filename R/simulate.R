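#' Archetype specification for the synthetic island scenario
#'
#' An archetype bundles the behavioural parameters of one simulated
#' species: monthly presence probabilities, site-attachment weights,
#' local movement scatter, anchor-switching rate, transmitter interval,
#' body-size distribution and the rates of tag artefacts.
#'
#' @param name archetype label.
#' @param species species label written to the tag metadata.
#' @param monthly_presence 12 probabilities (Jan..Dec) that a given day is
#'   spent inside the array.
#' @param site_weights named nonnegative weights over receiver sites used
#'   to draw the daily anchor site, or a named list of such vectors keyed
#'   by release site (site-faithful archetypes).
#' @param scatter_sd isotropic Gaussian scatter of 2-h positions around
#'   the anchor, metres.
#' @param daily_transition probability of redrawing the anchor site on a
#'   new day.
#' @param tx_interval transmitter interval bounds (s); transmissions have
#'   i.i.d. uniform gaps on this range.
#' @param tl_mean,tl_sd,tl_range total-length distribution (m), truncated
#'   normal.
#' @param p_female probability an individual is female.
#' @param never_detected_prob,shed_tag_prob artefact rates.
#' @param release_sites site(s) where individuals are released (recycled
#'   over individuals).
#' @return object of class \code{"archetype_spec"} (a list).
#' @export
archetype_spec <- function(name, species, monthly_presence, site_weights,
                           scatter_sd, daily_transition,
                           tx_interval = c(80, 140),
                           tl_mean, tl_sd, tl_range,
                           p_female = 0.7,
                           never_detected_prob = 0, shed_tag_prob = 0,
                           release_sites) {
  stopifnot(length(monthly_presence) == 12,
            all(monthly_presence >= 0 & monthly_presence <= 1),
            scatter_sd >= 0, daily_transition >= 0, daily_transition <= 1,
            tx_interval[1] > 0, tx_interval[2] > tx_interval[1])
  if (!is.list(site_weights)) {
    stopifnot(all(site_weights >= 0), any(site_weights > 0))
  }
  structure(list(name = name, species = species,
                 monthly_presence = monthly_presence,
                 site_weights = site_weights, scatter_sd = scatter_sd,
                 daily_transition = daily_transition,
                 tx_interval = tx_interval, tl_mean = tl_mean,
                 tl_sd = tl_sd, tl_range = tl_range, p_female = p_female,
                 never_detected_prob = never_detected_prob,
                 shed_tag_prob = shed_tag_prob,
                 release_sites = release_sites),
            class = "archetype_spec")
}

#' Default synthetic island scenario
#'
#' An elliptical island of roughly 8 x 5 km (a coastline of ~25 km) ringed
#' by 21 receiver sites: a tight three-receiver cluster on the west coast
#' (a hotspot), two pier pairs on the north-east and south coasts, a
#' general coastal ring, a deep offshore group ~7 km south, and four
#' late-deployed sites that only become active two years into the window.
#' Four archetypes mirror the behavioural contrasts of a sympatric shark
#' community: a seasonal migrant generalist with a west-coast hotspot
#' preference (absent June-October), two site-faithful pier residents
#' present year-round, and an offshore site-attached species with reduced
#' winter presence.
#'
#' @param n_animals named integer vector of individuals per archetype.
#' @param study_start,study_end study window (Dates or strings).
#' @param centre_lon,centre_lat island centre, WGS84 degrees.
#' @param semi_axes ellipse semi-axes (m).
#' @param d50 distance of 50\% detection efficiency (m).
#' @param range_slope logistic slope of the detection-range model (m).
#' @param tz analysis timezone.
#' @param archetypes optionally a list of \code{\link{archetype_spec}}s
#'   replacing the defaults.
#' @return object of class \code{"island_scenario"}.
#' @export
island_scenario <- function(n_animals = c(migrant = 10, pier_resident_a = 8,
                                          pier_resident_b = 8,
                                          offshore_seasonal = 6),
                            study_start = "2021-03-01",
                            study_end = "2024-03-01",
                            centre_lon = 167.95, centre_lat = -29.03,
                            semi_axes = c(4000, 2500),
                            d50 = 250, range_slope = 50,
                            tz = ISLANDRANGE_TZ,
                            archetypes = NULL) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  stopifnot(study_start < study_end)
  prj <- local_projection(centre_lon, centre_lat)

  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ring_xy <- cbind(semi_axes[1] * cos(th), semi_axes[2] * sin(th))
  ring_ll <- prj$unproject(ring_xy[, 1], ring_xy[, 2])
  land <- land_mask(list(rbind(ring_ll, ring_ll[1, ])), projection = prj)

  shore <- function(deg, off = 400) {
    a <- deg * pi / 180
    c((semi_axes[1] + off) * cos(a), (semi_axes[2] + off) * sin(a))
  }
  # canonical late-deployment date; for short windows fall back to
  # two-thirds through the study so the availability contrast survives
  late_from <- as.Date("2023-02-01")
  if (late_from <= study_start || late_from >= study_end) {
    late_from <- study_start +
      floor(2 / 3 * as.numeric(study_end - study_start))
  }
  early_from <- study_start - 30
  site_row <- function(site, xy, late = FALSE) {
    data.frame(site = site, x = xy[1], y = xy[2], late = late,
               stringsAsFactors = FALSE)
  }
  rec <- rbind(
    site_row("Headstone", shore(180)),
    site_row("Chute", shore(180) + c(0, 150)),
    site_row("Jonny", shore(180) - c(0, 150)),
    site_row("Cascade", shore(55)),
    site_row("Simons", shore(40)),
    site_row("Kingston", shore(265)),
    site_row("Surf", shore(250)),
    site_row("Nepean", shore(232)),
    site_row("North", shore(90)),
    site_row("Anson", shore(112)),
    site_row("Rocky", shore(145)),
    site_row("Southwest", shore(210)),
    site_row("Cemetery", shore(287)),
    site_row("Southeast", shore(320)),
    site_row("East", shore(0)),
    site_row("Fishbowl", shore(70), late = TRUE),
    site_row("Cabbage", shore(335), late = TRUE),
    site_row("PhillipDeep", c(1500, -7000)),
    site_row("PhillipReef", c(2500, -7400)),
    site_row("Phillip1", c(2000, -8000), late = TRUE),
    site_row("Phillip2", c(1000, -8200), late = TRUE))
  ll <- prj$unproject(rec$x, rec$y)
  receivers <- data.frame(
    site = rec$site, lon = ll[, 1], lat = ll[, 2], x = rec$x, y = rec$y,
    depth_m = ifelse(grepl("^Phillip", rec$site), 50,
                     ifelse(rec$site %in% c("Kingston", "Cascade"), 5, 20)),
    active_from = as.POSIXct(paste(ifelse(rec$late, format(late_from),
                                          format(early_from)), "00:00:00"),
                             tz = "UTC"),
    active_to = as.POSIXct(paste(format(study_end), "23:59:59"),
                           tz = "UTC"),
    stringsAsFactors = FALSE)

  if (is.null(archetypes)) {
    ring1 <- c(North = 1, Anson = 1, Rocky = 1, Southwest = 1,
               Cemetery = 1, Southeast = 1, East = 1)
    archetypes <- list(
      migrant = archetype_spec(
        "migrant", species = "tiger",
        monthly_presence = c(0.85, 0.85, 0.8, 0.7, 0.3, 0.02, 0.02, 0.02,
                             0.02, 0.02, 0.6, 0.85),
        site_weights = c(Headstone = 3, ring1,
                         Cascade = 1, Simons = 1, Kingston = 1, Surf = 1,
                         Nepean = 1, PhillipDeep = 0.3, PhillipReef = 0.3),
        scatter_sd = 150, daily_transition = 0.5,
        tx_interval = c(80, 140), tl_mean = 3.83, tl_sd = 0.45,
        tl_range = c(2.3, 4.4), p_female = 0.85,
        never_detected_prob = 2 / 47, shed_tag_prob = 0,
        release_sites = "Headstone"),
      pier_resident_a = archetype_spec(
        "pier_resident_a", species = "dusky",
        monthly_presence = rep(0.55, 12),
        site_weights = list(
          Cascade = c(Cascade = 5, Simons = 3, North = 1, East = 0.5,
                      0.12 * ring1, Headstone = 0.12),
          Kingston = c(Kingston = 5, Surf = 3, Nepean = 1.5,
                       Cemetery = 0.5, 0.12 * ring1, Headstone = 0.12)),
        scatter_sd = 80, daily_transition = 0.15,
        tx_interval = c(80, 140), tl_mean = 2.28, tl_sd = 0.28,
        tl_range = c(1.6, 2.8), p_female = 0.65,
        never_detected_prob = 7 / 34, shed_tag_prob = 1 / 34,
        release_sites = c("Cascade", "Kingston")),
      pier_resident_b = archetype_spec(
        "pier_resident_b", species = "galapagos",
        monthly_presence = rep(0.5, 12),
        site_weights = list(
          Cascade = c(Cascade = 5, Simons = 2.5, North = 0.8, East = 0.4,
                      0.08 * ring1, Headstone = 0.08),
          Kingston = c(Kingston = 5, Surf = 2.5, Nepean = 1.8,
                       Southeast = 0.4, 0.08 * ring1, Headstone = 0.08)),
        scatter_sd = 80, daily_transition = 0.12,
        tx_interval = c(80, 140), tl_mean = 1.64, tl_sd = 0.18,
        tl_range = c(1.3, 2.0), p_female = 0.72,
        never_detected_prob = 9 / 32, shed_tag_prob = 0,
        release_sites = c("Cascade", "Kingston")),
      offshore_seasonal = archetype_spec(
        "offshore_seasonal", species = "sandbar",
        monthly_presence = c(0.7, 0.7, 0.6, 0.5, 0.3, 0.15, 0.1, 0.1,
                             0.15, 0.2, 0.5, 0.7),
        site_weights = c(PhillipDeep = 3, PhillipReef = 2, Phillip1 = 1,
                         Phillip2 = 1),
        scatter_sd = 100, daily_transition = 0.05,
        tx_interval = c(90, 150), tl_mean = 1.38, tl_sd = 0.08,
        tl_range = c(1.2, 1.5), p_female = 0.67,
        never_detected_prob = 10 / 20, shed_tag_prob = 0,
        release_sites = "PhillipDeep"))
  }
  stopifnot(all(names(n_animals) %in% names(archetypes)))

  structure(list(n_animals = n_animals, study_start = study_start,
                 study_end = study_end, land = land,
                 receivers = receivers, archetypes = archetypes,
                 d50 = d50, range_slope = range_slope, tz = tz),
            class = "island_scenario")
}

#' @export
print.island_scenario <- function(x, ...) {
  cat(sprintf("<island_scenario> %s to %s, %d receivers, %d archetypes, %d animals\n",
              x$study_start, x$study_end, nrow(x$receivers),
              length(x$archetypes), sum(x$n_animals)))
  invisible(x)
}

#' Simulate true movement tracks for a scenario
#'
#' Presence is drawn per day from the archetype's month-specific
#' probability; on present days the animal is attached to an anchor site
#' (redrawn with the daily transition probability, from the archetype's
#' site weights) and its twelve 2-h step positions scatter isotropically
#' around the anchor.  Ground truth (daily presence and anchor history)
#' is recorded for closed-loop checks of every downstream stage.
#'
#' @param scenario an \code{\link{island_scenario}}.
#' @param seed integer seed for all randomness (animal biology, presence,
#'   anchors, scatter).
#' @return list with \code{tags} (simulated tag metadata),
#'   \code{positions} (tag_id, step_start, x, y, anchor),
#'   \code{truth_daily} (tag_id, date, month, present, anchor).
#' @export
simulate_tracks <- function(scenario, seed = 1) {
  set.seed(seed)
  sc <- scenario
  tz <- sc$tz
  rec_xy <- sc$receivers[, c("x", "y")]
  rownames(rec_xy) <- sc$receivers$site

  tags <- list(); positions <- list(); truth <- list()
  idx <- 0
  for (an in names(sc$n_animals)) {
    a <- sc$archetypes[[an]]
    n <- sc$n_animals[[an]]
    for (i in seq_len(n)) {
      idx <- idx + 1
      tag_id <- sprintf("A69-%04d", idx)
      rel_site <- a$release_sites[1 + (i - 1) %% length(a$release_sites)]
      # releases in the first ~4 months, capped for short windows
      rel_span <- min(120, max(1, floor(
        as.numeric(sc$study_end - sc$study_start) / 3)))
      rel_date <- sc$study_start + floor(stats::runif(1, 0, rel_span))
      rel_time <- as.POSIXct(paste(format(rel_date), "02:00:00"),
                             tz = tz)
      attr(rel_time, "tzone") <- "UTC"
      tl <- stats::rnorm(1, a$tl_mean, a$tl_sd)
      tl <- min(a$tl_range[2], max(a$tl_range[1], tl))
      sex <- if (stats::runif(1) < a$p_female) "F" else "M"
      tags[[idx]] <- data.frame(
        tag_id = tag_id, species = a$species, archetype = a$name,
        sex = sex, total_length_m = round(tl, 2),
        release_site = rel_site, release_time = rel_time,
        stringsAsFactors = FALSE)

      w <- if (is.list(a$site_weights)) a$site_weights[[rel_site]]
           else a$site_weights
      w_sites <- names(w); w_prob <- w / sum(w)

      days <- seq(rel_date + 1, sc$study_end, by = "day")
      mo <- as.integer(format(days, "%m"))
      present <- stats::runif(length(days)) < a$monthly_presence[mo]
      anchor <- character(length(days))
      cur <- sample(w_sites, 1, prob = w_prob)
      for (k in seq_along(days)) {
        if (k > 1 && stats::runif(1) < a$daily_transition) {
          cur <- sample(w_sites, 1, prob = w_prob)
        }
        anchor[k] <- cur
      }
      truth[[idx]] <- data.frame(
        tag_id = tag_id, date = days, month = mo, present = present,
        anchor = anchor, stringsAsFactors = FALSE)

      pd <- which(present)
      if (length(pd)) {
        ns <- length(pd) * 12L
        day0 <- as.POSIXct(paste(format(days[pd]), "00:00:00"), tz = tz)
        step_start <- rep(day0, each = 12L) +
          rep(seq(0, 22, by = 2) * 3600, times = length(pd))
        attr(step_start, "tzone") <- "UTC"
        ax <- rec_xy[anchor[pd], 1]; ay <- rec_xy[anchor[pd], 2]
        positions[[idx]] <- data.frame(
          tag_id = tag_id,
          step_start = step_start,
          x = rep(ax, each = 12L) + stats::rnorm(ns, 0, a$scatter_sd),
          y = rep(ay, each = 12L) + stats::rnorm(ns, 0, a$scatter_sd),
          anchor = rep(anchor[pd], each = 12L),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(tags = do.call(rbind, tags),
       positions = do.call(rbind, positions),
       truth_daily = do.call(rbind, truth))
}

#' Logistic detection-range model
#'
#' Probability that a single transmission at distance \code{d} metres is
#' decoded: \eqn{p(d) = 1 / (1 + \exp((d - d50) / s))}, i.e. 50\%
#' efficiency at \code{d50} with logistic slope \code{s}.
#'
#' @param d distance(s), metres.
#' @param d50 50\% efficiency distance, metres.
#' @param slope logistic slope, metres.
#' @export
detection_probability <- function(d, d50 = 250, slope = 50) {
  1 / (1 + exp((d - d50) / slope))
}

#' Simulate probabilistic detections from true tracks
#'
#' Within each 2-h step the transmitter emits with i.i.d. uniform
#' inter-transmission gaps; every transmission is decoded independently
#' by each active receiver with the distance-dependent probability of
#' \code{\link{detection_probability}}.  Simultaneous detections at
#' several receivers are allowed.
#'
#' @param tracks result of \code{\link{simulate_tracks}} (or a positions
#'   data frame).
#' @param scenario the \code{\link{island_scenario}}.
#' @param seed integer seed.
#' @return detection data frame (\code{tag_id, receiver_id, timestamp}),
#'   sorted by tag then time.
#' @export
simulate_detections <- function(tracks, scenario, seed = 1) {
  set.seed(seed)
  pos <- if (is.data.frame(tracks)) tracks else tracks$positions
  tags <- if (is.data.frame(tracks)) NULL else tracks$tags
  sc <- scenario
  rec <- sc$receivers
  step_len <- 7200
  out <- list()
  for (id in unique(pos$tag_id)) {
    p1 <- pos[pos$tag_id == id, , drop = FALSE]
    arch <- if (!is.null(tags)) {
      sc$archetypes[[tags$archetype[match(id, tags$tag_id)]]]
    } else {
      sc$archetypes[[1]]
    }
    lo <- arch$tx_interval[1]; hi <- arch$tx_interval[2]
    K <- ceiling(step_len / lo)
    # cumulative transmission times per step: gap matrix times the
    # upper-triangular ones matrix is a row-wise cumulative sum
    U <- upper.tri(matrix(0, K, K), diag = TRUE) * 1

    ns <- nrow(p1)
    gaps <- matrix(stats::runif(ns * K, lo, hi), ns, K)
    tx <- gaps %*% U
    valid <- tx < step_len

    active <- outer(p1$step_start, rec$active_from, ">=") &
              outer(p1$step_start + step_len, rec$active_to, "<=")
    for (j in seq_len(nrow(rec))) {
      dj <- sqrt((p1$x - rec$x[j])^2 + (p1$y - rec$y[j])^2)
      pj <- detection_probability(dj, sc$d50, sc$range_slope)
      pj[!active[, j]] <- 0
      rows <- which(pj > 1e-5)
      if (!length(rows)) next
      nr <- length(rows)
      hit <- matrix(stats::runif(nr * K), nr, K) < pj[rows]
      hit <- hit & valid[rows, , drop = FALSE]
      if (!any(hit)) next
      w <- which(hit, arr.ind = TRUE)
      out[[length(out) + 1]] <- data.frame(
        tag_id = id, receiver_id = rec$site[j],
        timestamp = p1$step_start[rows[w[, 1]]] + tx[rows, , drop = FALSE][w],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(tag_id = character(0), receiver_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC")))
  }
  det <- do.call(rbind, out)
  det$timestamp <- as.POSIXct(round(det$timestamp), tz = "UTC")
  det <- det[order(det$tag_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Inject tag artefacts into simulated detections
#'
#' For each animal, with the archetype's probabilities: a
#' \code{never_detected} animal has all detections removed (it stays in
#' the tag metadata); a \code{shed_tag} animal has its record replaced,
#' from a random date onward, by continuous detections at a single
#' receiver until the study end (one ping per 30 min) -- the signature
#' the shed-tag/dead-animal QC filter is designed to catch.
#'
#' @param det simulated detection data frame.
#' @param tracks the \code{\link{simulate_tracks}} result (for tag and
#'   archetype lookup).
#' @param scenario the scenario.
#' @param seed integer seed.
#' @return list with \code{detections} and \code{artifacts} (tag_id,
#'   type, from_date).
#' @export
inject_artifacts <- function(det, tracks, scenario, seed = 1) {
  set.seed(seed)
  sc <- scenario
  tags <- tracks$tags
  art <- list()
  for (i in seq_len(nrow(tags))) {
    a <- sc$archetypes[[tags$archetype[i]]]
    id <- tags$tag_id[i]
    u <- stats::runif(2)
    if (u[1] < a$never_detected_prob) {
      det <- det[det$tag_id != id, , drop = FALSE]
      art[[length(art) + 1]] <- data.frame(
        tag_id = id, type = "never_detected", from_date = as.Date(NA))
    } else if (u[2] < a$shed_tag_prob) {
      rel <- as.Date(tags$release_time[i])
      lo <- rel + 60
      hi <- sc$study_end - 30
      if (lo >= hi) next
      shed_date <- lo + floor(stats::runif(1, 0, as.numeric(hi - lo)))
      shed_t0 <- as.POSIXct(paste(format(shed_date), "00:00:00"),
                            tz = "UTC")
      # receiver that heard the animal most (active for the whole tail)
      cand <- det$receiver_id[det$tag_id == id]
      early <- sc$receivers$site[
        sc$receivers$active_from <= sc$receivers$active_from[1]]
      site <- if (length(cand)) names(sort(table(cand),
                                           decreasing = TRUE))[1]
              else early[1]
      keep <- det$tag_id != id | det$timestamp < shed_t0
      det <- det[keep, , drop = FALSE]
      pings <- seq(shed_t0,
                   as.POSIXct(paste(format(sc$study_end), "23:00:00"),
                              tz = "UTC"), by = 1800)
      det <- rbind(det, data.frame(tag_id = id, receiver_id = site,
                                   timestamp = pings,
                                   stringsAsFactors = FALSE))
      art[[length(art) + 1]] <- data.frame(
        tag_id = id, type = "shed_tag", from_date = shed_date)
    }
  }
  det <- det[order(det$tag_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  list(detections = det,
       artifacts = if (length(art)) do.call(rbind, art) else
         data.frame(tag_id = character(0), type = character(0),
                    from_date = as.Date(character(0))))
}

#' Simulate a complete synthetic island dataset
#'
#' Runs \code{\link{simulate_tracks}}, \code{\link{simulate_detections}}
#' and \code{\link{inject_artifacts}} under a single seed and assembles
#' the four standard inputs (detections, receivers, tags, land) plus the
#' ground truth.
#'
#' @param scenario an \code{\link{island_scenario}} (default scenario if
#'   missing).
#' @param seed integer seed.
#' @return object of class \code{"island_sim"}: \code{detections},
#'   \code{receivers}, \code{tags}, \code{land}, \code{tz},
#'   \code{scenario}, \code{truth} (list: \code{daily}, \code{artifacts}).
#' @export
simulate_island <- function(scenario = island_scenario(), seed = 1) {
  tracks <- simulate_tracks(scenario, seed = seed)
  det <- simulate_detections(tracks, scenario, seed = seed + 1)
  inj <- inject_artifacts(det, tracks, scenario, seed = seed + 2)
  structure(list(detections = inj$detections,
                 receivers = scenario$receivers,
                 tags = tracks$tags, land = scenario$land,
                 tz = scenario$tz, scenario = scenario,
                 truth = list(daily = tracks$truth_daily,
                              artifacts = inj$artifacts,
                              positions = tracks$positions)),
            class = "island_sim")
}

#' @export
print.island_sim <- function(x, ...) {
  cat(sprintf("<island_sim> %d detections, %d tags, %d receivers\n",
              nrow(x$detections), nrow(x$tags), nrow(x$receivers)))
  invisible(x)
}

#' Convert a simulated dataset to analysis-ready telemetry data
#'
#' Routes the simulated tables through the same validation and projection
#' as file input (\code{\link{read_telemetry}}).
#'
#' @param sim an \code{\link{simulate_island}} object.
#' @return a \code{telemetry_data} object.
#' @export
as_telemetry <- function(sim) {
  stopifnot(inherits(sim, "island_sim"))
  det <- data.frame(transmitter_id = sim$detections$tag_id,
                    station_name = sim$detections$receiver_id,
                    detection_datetime = sim$detections$timestamp)
  rec <- data.frame(station_name = sim$receivers$site,
                    longitude = sim$receivers$lon,
                    latitude = sim$receivers$lat,
                    depth_m = sim$receivers$depth_m,
                    deployment_date = sim$receivers$active_from,
                    recovery_date = sim$receivers$active_to)
  tg <- data.frame(transmitter_id = sim$tags$tag_id,
                   species = sim$tags$species,
                   sex = sim$tags$sex,
                   total_length_m = sim$tags$total_length_m,
                   release_site = sim$tags$release_site,
                   release_datetime = sim$tags$release_time)
  read_telemetry(det, rec, tg, sim$land, tz = sim$tz)
}

#' Write the four standard input files for a simulated dataset
#'
#' @param sim an \code{\link{simulate_island}} object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scenario_files <- function(sim, dir) {
  stopifnot(inherits(sim, "island_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iso <- function(t) format(t, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(
    data.frame(transmitter_id = sim$detections$tag_id,
               station_name = sim$detections$receiver_id,
               detection_datetime = iso(sim$detections$timestamp)),
    file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(station_name = sim$receivers$site,
               longitude = sim$receivers$lon,
               latitude = sim$receivers$lat,
               depth_m = sim$receivers$depth_m,
               deployment_date = iso(sim$receivers$active_from),
               recovery_date = iso(sim$receivers$active_to)),
    file.path(dir, "receivers.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(transmitter_id = sim$tags$tag_id,
               species = sim$tags$species, sex = sim$tags$sex,
               total_length_m = sim$tags$total_length_m,
               release_site = sim$tags$release_site,
               release_datetime = iso(sim$tags$release_time)),
    file.path(dir, "tags.csv"), row.names = FALSE)
  write_land_geojson(sim$land, file.path(dir, "land.geojson"))
  invisible(dir)
}
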