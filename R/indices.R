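#' Detection period of one animal
#'
#' Whole local calendar days, inclusive of both endpoint dates, from the
#' period start to the date of the last detection.  The start is either
#' the local date at which the post-release window ends
#' (\code{"post48"}, the default) or the release date (\code{"tagging"}).
#'
#' @param timestamps POSIXct detections of one animal (UTC).
#' @param release_time POSIXct release time (UTC).
#' @param convention \code{"post48"} or \code{"tagging"}.
#' @param window_h post-release window, hours (used by \code{"post48"}).
#' @param tz analysis timezone.
#' @return integer day count with attributes \code{start_date} and
#'   \code{end_date}; \code{NA_integer_} when there are no detections
#'   (undefined, distinct from 0).
#' @export
detection_period <- function(timestamps, release_time,
                             convention = c("post48", "tagging"),
                             window_h = 48, tz = ISLANDRANGE_TZ) {
  convention <- match.arg(convention)
  if (length(timestamps) == 0) return(NA_integer_)
  start <- if (convention == "post48") {
    local_date(release_time + window_h * 3600, tz)
  } else {
    local_date(release_time, tz)
  }
  end <- max(local_date(timestamps, tz))
  if (end < start) start <- end   # guard: detection dated before window end
  structure(ndays_inclusive(start, end), start_date = start,
            end_date = end)
}

#' Residency index
#'
#' Number of days with at least one detection anywhere in the array,
#' divided by the number of days in the detection period.
#'
#' @param dates_detected vector of distinct (or not) detection dates.
#' @param period_days detection period length in days.
#' @return numeric in \code{[0, 1]}; \code{NA} if the period is undefined.
#' @export
residency_index <- function(dates_detected, period_days) {
  if (is.na(period_days)) return(NA_real_)
  stopifnot(period_days >= 1)
  length(unique(dates_detected)) / period_days
}

#' Roaming index
#'
#' Number of unique receiver sites with detections divided by the number
#' of receiver sites available to the animal, where "available" means the
#' site's deployment interval overlaps the animal's detection period (any
#' temporal overlap counts).
#'
#' @param sites_detected character vector of sites with detections.
#' @param available character vector of available sites (see
#'   \code{\link{available_sites}}).
#' @return numeric in \code{[0, 1]}.
#' @export
roaming_index <- function(sites_detected, available) {
  if (length(available) == 0) {
    stop("no receiver sites available in the period: array/config mismatch",
         call. = FALSE)
  }
  length(unique(sites_detected)) / length(unique(available))
}

#' Receiver sites available during an interval
#'
#' @param receivers receiver data frame (\code{site, active_from,
#'   active_to}).
#' @param start_date,end_date local dates bounding the interval
#'   (inclusive).
#' @param tz analysis timezone (deployment timestamps are converted to
#'   local dates before the overlap test).
#' @return character vector of site names whose deployment overlaps the
#'   interval.
#' @export
available_sites <- function(receivers, start_date, end_date,
                            tz = ISLANDRANGE_TZ) {
  from <- local_date(receivers$active_from, tz)
  to <- local_date(receivers$active_to, tz)
  receivers$site[from <= end_date & to >= start_date]
}

#' Overall and monthly residency/roaming indices
#'
#' Produces one \code{scope = "overall"} row per retained animal and, when
#' \code{monthly = TRUE}, one row per retained calendar month.  A month at
#' the start or end of an animal's detection period is kept only if the
#' period covers strictly more than \code{month_min_days} days of it;
#' within a retained month the residency denominator is the number of days
#' of that month inside the period, and roaming availability is assessed
#' against that month's in-period window.
#'
#' @param qc a \code{\link{qc_detections}} result (or any list with
#'   \code{detections}, \code{receivers}, \code{tags}, \code{tz},
#'   \code{convention}, \code{params}).
#' @param monthly also compute per-month records?
#' @param month_min_days boundary-month retention threshold (days,
#'   strict).
#' @return data frame of class \code{"index_table"}: \code{tag_id,
#'   species, scope, year, month, period_days, days_detected, resi,
#'   sites_detected, sites_available, roi}.
#' @export
compute_indices <- function(qc, monthly = TRUE, month_min_days = 14) {
  det <- qc$detections
  tz <- qc$tz
  conv <- qc$convention %||% "post48"
  window_h <- (qc$params %||% list())$window_h %||% 48
  rows <- list()
  for (id in unique(det$tag_id)) {
    d <- det[det$tag_id == id, , drop = FALSE]
    sp <- qc$tags$species[match(id, qc$tags$tag_id)]
    rel <- qc$tags$release_time[match(id, qc$tags$tag_id)]
    per <- detection_period(d$timestamp, rel, convention = conv,
                            window_h = window_h, tz = tz)
    start <- attr(per, "start_date"); end <- attr(per, "end_date")
    dates <- local_date(d$timestamp, tz)
    avail <- available_sites(qc$receivers, start, end, tz)
    rows[[length(rows) + 1]] <- data.frame(
      tag_id = id, species = sp, scope = "overall",
      year = NA_integer_, month = NA_integer_,
      period_days = as.integer(per),
      days_detected = length(unique(dates)),
      resi = residency_index(dates, per),
      sites_detected = length(unique(d$receiver_id)),
      sites_available = length(unique(avail)),
      roi = roaming_index(d$receiver_id, avail),
      stringsAsFactors = FALSE)

    if (!monthly) next
    # walk calendar months covered by the period
    m0 <- as.Date(format(start, "%Y-%m-01"))
    mseq <- seq(m0, end, by = "month")
    for (mstart in as.list(mseq)) {
      mend <- seq(mstart, by = "month", length.out = 2)[2] - 1
      w_start <- max(mstart, start)
      w_end <- min(mend, end)
      covered <- ndays_inclusive(w_start, w_end)
      if (covered <= month_min_days) next
      in_m <- dates >= w_start & dates <= w_end
      avail_m <- available_sites(qc$receivers, w_start, w_end, tz)
      rows[[length(rows) + 1]] <- data.frame(
        tag_id = id, species = sp, scope = "month",
        year = as.integer(format(mstart, "%Y")),
        month = as.integer(format(mstart, "%m")),
        period_days = covered,
        days_detected = length(unique(dates[in_m])),
        resi = residency_index(dates[in_m], covered),
        sites_detected = length(unique(d$receiver_id[in_m])),
        sites_available = length(unique(avail_m)),
        roi = roaming_index(d$receiver_id[in_m], avail_m),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_table", "data.frame")
  out
}

#' Mechanistic size-category split
#'
#' Splits a species' individuals into small/large classes at the largest
#' gap between consecutive sorted total lengths whose two endpoints both
#' lie within the interquartile range (linear-interpolation quantiles).
#' The cut-off is by default the midpoint of that gap; ties among
#' equally large gaps are broken toward the gap whose midpoint is closest
#' to the median.
#'
#' @param tl numeric vector of total lengths (m); at least 4 individuals.
#' @param gap_rule where in the winning gap to place the cut-off:
#'   \code{"midpoint"} (default), \code{"lower"} or \code{"upper"} edge.
#' @param probs quantile bounds for eligible gap endpoints.
#' @return object of class \code{"size_split"}: \code{cutoff_m},
#'   \code{labels} (\code{"small"}/\code{"large"} per input), \code{gap}
#'   (the winning gap endpoints).
#' @export
size_split <- function(tl, gap_rule = c("midpoint", "lower", "upper"),
                       probs = c(0.25, 0.75)) {
  gap_rule <- match.arg(gap_rule)
  stopifnot(length(tl) >= 4, all(is.finite(tl)))
  q <- stats::quantile(tl, probs, type = 7, names = FALSE)
  s <- sort(tl)
  lo <- s[-length(s)]; hi <- s[-1]
  ok <- lo >= q[1] & hi <= q[2] & hi > lo
  if (!any(ok)) {
    stop("no gap: no pair of consecutive distinct lengths lies within the ",
         "interquartile range", call. = FALSE)
  }
  width <- hi - lo
  width[!ok] <- -Inf
  best <- which(width == max(width))
  if (length(best) > 1) {
    med <- stats::median(tl)
    mid <- (lo[best] + hi[best]) / 2
    best <- best[which.min(abs(mid - med))]
  }
  cutoff <- switch(gap_rule,
                   midpoint = (lo[best] + hi[best]) / 2,
                   lower = lo[best],
                   upper = hi[best])
  structure(list(cutoff_m = cutoff,
                 labels = ifelse(tl < cutoff, "small", "large"),
                 gap = c(lo[best], hi[best]),
                 gap_rule = gap_rule),
            class = "size_split")
}

#' @export
print.size_split <- function(x, ...) {
  cat(sprintf(
    "<size_split> cutoff %.3f m (%s of gap %.3f-%.3f); %d small, %d large\n",
    x$cutoff_m, x$gap_rule, x$gap[1], x$gap[2],
    sum(x$labels == "small"), sum(x$labels == "large")))
  invisible(x)
}
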