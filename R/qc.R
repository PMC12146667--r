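#' Remove the post-release acclimation window
#'
#' Detections in the first \code{window_h} hours after each animal's
#' release are discarded so that behaviour induced by capture and tagging
#' does not enter the analysis.  The removal window is closed: a detection
#' at exactly \code{release + window_h} is removed.
#'
#' @param det detection data frame (\code{tag_id, receiver_id, timestamp}).
#' @param tags tag metadata data frame with \code{tag_id, release_time}.
#' @param window_h window length in hours (default 48).
#' @return the detection data frame with the window removed.
#' @export
trim_post_release <- function(det, tags, window_h = 48) {
  if (anyNA(tags$release_time)) {
    stop("every tag needs a release_time", call. = FALSE)
  }
  rel <- tags$release_time[match(det$tag_id, tags$tag_id)]
  if (anyNA(rel)) {
    stop("detections present for tags without metadata: ",
         paste(unique(det$tag_id[is.na(rel)]), collapse = ", "),
         call. = FALSE)
  }
  keep <- det$timestamp > rel + window_h * 3600
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag shed-tag / dead-animal signatures
#'
#' A transmitter that is shed (or whose carrier dies) near a receiver
#' produces an unbroken terminal run of detections at a single site.  An
#' animal is flagged when its final run of detections (i) occurs at exactly
#' one receiver, (ii) spans at least \code{min_days} days, (iii) contains
#' no silence longer than \code{max_gap_h} hours, and (iv) continues to the
#' animal's last detection.  Flagged animals are removed entirely: once the
#' signature is present the tag's whole record is untrustworthy.
#'
#' @param det trimmed detection data frame.
#' @param min_days minimum span of the terminal single-receiver run (days).
#' @param max_gap_h maximum internal silence within the run (hours).
#' @return list with \code{detections} (flagged animals removed) and
#'   \code{flagged} (character vector of tag ids).
#' @export
flag_shed_or_dead <- function(det, min_days = 7, max_gap_h = 24) {
  flagged <- character(0)
  if (nrow(det)) {
    for (id in unique(det$tag_id)) {
      d <- det[det$tag_id == id, , drop = FALSE]
      o <- order(d$timestamp)
      t <- d$timestamp[o]; r <- d$receiver_id[o]
      n <- length(t)
      i <- n
      while (i > 1 && r[i - 1] == r[n] &&
             as.numeric(difftime(t[i], t[i - 1], units = "hours")) <=
               max_gap_h) {
        i <- i - 1
      }
      span_d <- as.numeric(difftime(t[n], t[i], units = "days"))
      if (span_d >= min_days) flagged <- c(flagged, id)
    }
  }
  out <- det[!det$tag_id %in% flagged, , drop = FALSE]
  rownames(out) <- NULL
  list(detections = out, flagged = flagged)
}

#' Apply the minimum detection-period filter and build the filter report
#'
#' Animals whose detection period is \code{min_days} days or shorter are
#' excluded (they likely left the monitored area and would bias residency
#' statistics); animals never detected are reported separately.  The
#' detection period is counted in whole local calendar days, inclusive of
#' both endpoints, from either the end of the post-release window
#' (\code{convention = "post48"}) or the release date
#' (\code{convention = "tagging"}) to the last detection.
#'
#' @param det detection data frame after trimming (and shed-tag removal).
#' @param tags tag metadata.
#' @param min_days retention threshold: animals with period
#'   \code{<= min_days} are dropped (strictly more than \code{min_days}
#'   days retained).
#' @param convention period-start convention, \code{"post48"} or
#'   \code{"tagging"}.
#' @param window_h post-release window used by the \code{"post48"}
#'   convention, hours.
#' @param tz analysis timezone for day counting.
#' @param shed_flagged tag ids already removed as shed/dead (for the
#'   report).
#' @param n_raw,n_after_trim optional named integer vectors of per-animal
#'   detection counts before/after trimming (for the report).
#' @return list with \code{detections} (retained) and \code{report}
#'   (class \code{"filter_report"} data frame: one row per animal with
#'   counts, period and primary exclusion flag).
#' @export
apply_min_detection_period <- function(det, tags, min_days = 14,
                                       convention = c("post48", "tagging"),
                                       window_h = 48, tz = ISLANDRANGE_TZ,
                                       shed_flagged = character(0),
                                       n_raw = NULL, n_after_trim = NULL) {
  convention <- match.arg(convention)
  ids <- tags$tag_id
  cnt <- function(v, tab) {
    out <- rep(0L, length(ids)); names(out) <- ids
    if (!is.null(tab)) out[names(tab)] <- as.integer(tab)
    out
  }
  tab_now <- table(det$tag_id)
  n_now <- cnt(ids, tab_now)
  n_raw <- if (is.null(n_raw)) n_now else cnt(ids, n_raw)
  n_after_trim <- if (is.null(n_after_trim)) n_now else cnt(ids, n_after_trim)

  period <- rep(NA_integer_, length(ids)); names(period) <- ids
  for (id in ids[n_now > 0]) {
    t <- det$timestamp[det$tag_id == id]
    period[id] <- detection_period(
      t, tags$release_time[tags$tag_id == id][1],
      convention = convention, window_h = window_h, tz = tz)
  }

  flag <- rep("none", length(ids)); names(flag) <- ids
  flag[ids %in% shed_flagged] <- "shed_or_dead"
  never <- flag == "none" & n_raw == 0L
  flag[never] <- "never_detected"
  short <- flag == "none" & (n_now == 0L |
                             (!is.na(period) & period <= min_days))
  flag[short] <- "short_period"

  keep_ids <- ids[flag == "none"]
  out <- det[det$tag_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL

  report <- data.frame(
    tag_id = ids,
    species = tags$species,
    n_raw = unname(n_raw),
    n_after_trim = unname(n_after_trim),
    n_final = ifelse(flag == "none", unname(n_now), 0L),
    detection_period_days = unname(period),
    flag = unname(flag),
    retained = unname(flag == "none"),
    stringsAsFactors = FALSE)
  class(report) <- c("filter_report", "data.frame")
  attr(report, "convention") <- convention
  list(detections = out, report = report)
}

#' Run the full detection quality-control pipeline
#'
#' Sequentially applies post-release trimming, shed-tag/dead-animal
#' removal, and the minimum detection-period filter, producing
#' analysis-ready detections and a per-animal filter report.
#'
#' @param tele a \code{\link{read_telemetry}} object (or a list with
#'   \code{detections}, \code{receivers}, \code{tags}, \code{land},
#'   \code{tz}).
#' @param window_h post-release trim window, hours.
#' @param shed_min_days,shed_max_gap_h shed/dead run thresholds.
#' @param min_period_days minimum detection period (strictly greater
#'   retained).
#' @param convention detection-period start convention (see
#'   \code{\link{apply_min_detection_period}}).
#' @return object of class \code{"qc_result"}: \code{detections},
#'   \code{report}, \code{receivers}, \code{tags}, \code{land}, \code{tz},
#'   \code{convention}, \code{params}.
#' @export
qc_detections <- function(tele, window_h = 48, shed_min_days = 7,
                          shed_max_gap_h = 24, min_period_days = 14,
                          convention = c("post48", "tagging")) {
  convention <- match.arg(convention)
  det0 <- tele$detections
  n_raw <- table(det0$tag_id)
  det1 <- trim_post_release(det0, tele$tags, window_h = window_h)
  n_trim <- table(det1$tag_id)
  sh <- flag_shed_or_dead(det1, min_days = shed_min_days,
                          max_gap_h = shed_max_gap_h)
  mp <- apply_min_detection_period(
    sh$detections, tele$tags, min_days = min_period_days,
    convention = convention, window_h = window_h, tz = tele$tz,
    shed_flagged = sh$flagged, n_raw = n_raw, n_after_trim = n_trim)

  structure(list(detections = mp$detections, report = mp$report,
                 receivers = tele$receivers, tags = tele$tags,
                 land = tele$land, tz = tele$tz, convention = convention,
                 params = list(window_h = window_h,
                               shed_min_days = shed_min_days,
                               shed_max_gap_h = shed_max_gap_h,
                               min_period_days = min_period_days)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("<qc_result>\n")
  cat(sprintf("  retained: %d of %d animals, %d detections\n",
              sum(r$retained), nrow(r), nrow(x$detections)))
  tb <- table(r$flag[r$flag != "none"])
  if (length(tb)) {
    cat("  excluded:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  cat(sprintf("  detection-period convention: %s\n", x$convention))
  invisible(x)
}

#' @export
summary.qc_result <- function(object, ...) {
  r <- object$report[object$report$retained, , drop = FALSE]
  out <- do.call(rbind, lapply(split(r, r$species), function(g) {
    data.frame(species = g$species[1], n = nrow(g),
               period_mean = mean(g$detection_period_days),
               period_min = min(g$detection_period_days),
               period_max = max(g$detection_period_days))
  }))
  rownames(out) <- NULL
  out
}
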