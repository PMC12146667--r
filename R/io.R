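#' Read and validate the telemetry inputs
#'
#' Reads the three tabular inputs and the land polygon, projects every
#' position into a local equidistant frame centred on the land
#' centroid, and drops detections logged outside their receiver's
#' deployment interval (counted, not silently discarded).
#'
#' Expected columns:
#' \itemize{
#'   \item detections CSV: \code{transmitter_id, station_name,
#'     detection_datetime} (ISO-8601, UTC)
#'   \item receivers CSV: \code{station_name, longitude, latitude, depth_m,
#'     deployment_date, recovery_date}
#'   \item tags CSV: \code{transmitter_id, species, sex, total_length_m,
#'     release_site, release_datetime}
#'   \item land: GeoJSON Polygon/MultiPolygon (WGS84)
#' }
#'
#' @param detections,receivers,tags paths to CSV files (or data frames with
#'   the same columns).
#' @param land path to a GeoJSON file, or a \code{\link{land_mask}}.
#' @param tz analysis timezone used for calendar-day computations.
#' @return object of class \code{"telemetry_data"}: \code{$detections}
#'   (tag_id, receiver_id, timestamp; sorted by tag then time),
#'   \code{$receivers} (site, lon, lat, x, y, depth_m, active_from,
#'   active_to), \code{$tags}, \code{$land}, \code{$tz},
#'   \code{$n_dropped_deployment}.
#' @export
read_telemetry <- function(detections, receivers, tags, land,
                           tz = ISLANDRANGE_TZ) {
  det <- read_table_arg(detections,
                        c("transmitter_id", "station_name",
                          "detection_datetime"), "detections")
  rec <- read_table_arg(receivers,
                        c("station_name", "longitude", "latitude",
                          "depth_m", "deployment_date", "recovery_date"),
                        "receivers")
  tag <- read_table_arg(tags,
                        c("transmitter_id", "species", "sex",
                          "total_length_m", "release_site",
                          "release_datetime"), "tags")

  mask <- if (inherits(land, "land_mask")) land else read_land_geojson(land)

  xy <- mask$projection$project(rec$longitude, rec$latitude)
  receivers_df <- data.frame(
    site = as.character(rec$station_name),
    lon = rec$longitude, lat = rec$latitude,
    x = xy[, 1], y = xy[, 2],
    depth_m = rec$depth_m,
    active_from = parse_utc(rec$deployment_date, "deployment_date"),
    active_to = parse_utc(rec$recovery_date, "recovery_date"),
    stringsAsFactors = FALSE)
  bad <- receivers_df$active_from >= receivers_df$active_to
  if (any(bad)) {
    stop("receiver deployment interval inverted for site(s): ",
         paste(receivers_df$site[bad], collapse = ", "), call. = FALSE)
  }

  tags_df <- data.frame(
    tag_id = as.character(tag$transmitter_id),
    species = as.character(tag$species),
    sex = as.character(tag$sex),
    total_length_m = as.numeric(tag$total_length_m),
    release_site = as.character(tag$release_site),
    release_time = parse_utc(tag$release_datetime, "release_datetime"),
    stringsAsFactors = FALSE)
  if (any(!is.na(tags_df$total_length_m) & tags_df$total_length_m <= 0)) {
    stop("non-positive total_length_m in tag metadata", call. = FALSE)
  }

  det_df <- data.frame(
    tag_id = as.character(det$transmitter_id),
    receiver_id = as.character(det$station_name),
    timestamp = parse_utc(det$detection_datetime, "detection_datetime"),
    stringsAsFactors = FALSE)

  unknown_rec <- setdiff(unique(det_df$receiver_id), receivers_df$site)
  if (length(unknown_rec)) {
    stop("detections reference unknown receiver_id(s): ",
         paste(unknown_rec, collapse = ", "), call. = FALSE)
  }
  unknown_tag <- setdiff(unique(det_df$tag_id), tags_df$tag_id)
  if (length(unknown_tag)) {
    stop("detections reference unknown tag_id(s): ",
         paste(unknown_tag, collapse = ", "), call. = FALSE)
  }

  # drop detections outside the receiver's active deployment interval
  i <- match(det_df$receiver_id, receivers_df$site)
  ok <- det_df$timestamp >= receivers_df$active_from[i] &
        det_df$timestamp <= receivers_df$active_to[i]
  n_dropped <- sum(!ok)
  det_df <- det_df[ok, , drop = FALSE]
  det_df <- det_df[order(det_df$tag_id, det_df$timestamp), , drop = FALSE]
  rownames(det_df) <- NULL

  structure(list(detections = det_df, receivers = receivers_df,
                 tags = tags_df, land = mask, tz = tz,
                 n_dropped_deployment = n_dropped),
            class = "telemetry_data")
}

read_table_arg <- function(x, required, what) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop(what, " file not found: ", x, call. = FALSE)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " input is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a GeoJSON land polygon as a land mask
#'
#' Accepts Polygon, MultiPolygon, Feature and FeatureCollection geometries
#' in WGS84.  Only outer rings are kept.
#'
#' @param path GeoJSON file path.
#' @inheritParams land_mask
#' @return a \code{\link{land_mask}}.
#' @export
read_land_geojson <- function(path, projection = NULL) {
  if (!file.exists(path)) {
    stop("land polygon file not found: ", path, call. = FALSE)
  }
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- geojson_outer_rings(gj)
  if (!length(rings)) stop("no Polygon/MultiPolygon found in ", path,
                           call. = FALSE)
  land_mask(rings, projection = projection)
}

geojson_outer_rings <- function(g) {
  type <- g$type %||% ""
  switch(type,
    FeatureCollection = do.call(c, lapply(g$features, geojson_outer_rings)),
    Feature = geojson_outer_rings(g$geometry),
    Polygon = list(ring_to_matrix(g$coordinates[[1]])),
    MultiPolygon = lapply(g$coordinates,
                          function(poly) ring_to_matrix(poly[[1]])),
    list())
}

ring_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  colnames(m) <- c("lon", "lat")
  m
}

#' Write a land mask back to GeoJSON
#' @param mask a \code{\link{land_mask}}.
#' @param path output file.
#' @export
write_land_geojson <- function(mask, path) {
  polys <- lapply(mask$rings_ll, function(r) {
    list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
  })
  gj <- list(type = "MultiPolygon", coordinates = polys)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' @export
print.telemetry_data <- function(x, ...) {
  cat("<telemetry_data>\n")
  cat(sprintf("  detections: %d rows, %d tags, %d receivers (tz %s)\n",
              nrow(x$detections), length(unique(x$detections$tag_id)),
              nrow(x$receivers), x$tz))
  cat(sprintf("  tags: %d animals, %d species\n", nrow(x$tags),
              length(unique(x$tags$species))))
  if (x$n_dropped_deployment > 0) {
    cat(sprintf("  dropped outside deployment intervals: %d\n",
                x$n_dropped_deployment))
  }
  invisible(x)
}
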