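#' Jitter detections around their receiver position
#'
#' Each detection is assigned its receiver's projected position displaced
#' by a random distance (uniform on \code{[0, rmax]} metres) at a random
#' bearing (uniform on \code{[0, 2*pi)}), so that centres of activity are
#' not artificially pinned to receiver coordinates.  Uses the current RNG
#' state; call \code{set.seed()} beforehand for reproducibility.
#'
#' @param det detection data frame (\code{tag_id, receiver_id,
#'   timestamp}).
#' @param receivers receiver data frame with projected \code{x, y}.
#' @param rmax maximum displacement, metres.
#' @return \code{det} with \code{x, y} columns appended.
#' @export
jitter_detections <- function(det, receivers, rmax = 25) {
  i <- match(det$receiver_id, receivers$site)
  if (anyNA(i)) {
    stop("detections at unknown receiver(s): ",
         paste(unique(det$receiver_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(det)
  r <- stats::runif(n, 0, rmax)
  a <- stats::runif(n, 0, 2 * pi)
  det$x <- receivers$x[i] + r * cos(a)
  det$y <- receivers$y[i] + r * sin(a)
  det
}

#' Centre-of-activity (COA) tracks
#'
#' Collapses positioned detections into mean positions over consecutive
#' time bins (default 2 h, anchored at local midnight).  The COA of a bin
#' is the arithmetic mean of the jittered detection positions, which
#' equals the detection-count-weighted mean of receiver positions up to
#' jitter.  Bins without detections produce no record.
#'
#' Where several receivers are moored within a few hundred metres of each
#' other, keeping all of them would bias COAs toward that cluster; pass
#' the redundant ones in \code{exclude_sites} to drop their detections
#' first.
#'
#' @param det positioned detections (\code{tag_id, receiver_id, timestamp,
#'   x, y}).
#' @param bin_h bin width in hours (must divide 24).
#' @param tz timezone anchoring the bin grid.
#' @param exclude_sites receiver sites whose detections are discarded
#'   before binning.
#' @return data frame of class \code{"coa_track"}: \code{tag_id,
#'   bin_start} (POSIXct), \code{x, y, n_detections}.
#' @export
compute_coas <- function(det, bin_h = 2, tz = ISLANDRANGE_TZ,
                         exclude_sites = character(0)) {
  stopifnot(24 %% bin_h == 0)
  if (length(exclude_sites)) {
    det <- det[!det$receiver_id %in% exclude_sites, , drop = FALSE]
  }
  if (!nrow(det)) {
    out <- data.frame(tag_id = character(0),
                      bin_start = as.POSIXct(character(0), tz = "UTC"),
                      x = numeric(0), y = numeric(0),
                      n_detections = integer(0))
    class(out) <- c("coa_track", "data.frame")
    return(out)
  }
  w <- bin_h * 3600
  ts <- as.numeric(det$timestamp)
  off <- tz_gmtoff(det$timestamp, tz)
  if (is.null(off)) off <- 0
  bin0 <- floor((ts + off) / w) * w - off   # UTC seconds of bin start
  tagf <- factor(det$tag_id)
  b0min <- min(bin0)
  ib <- round((bin0 - b0min) / w)
  nb <- max(ib) + 1
  key <- (as.integer(tagf) - 1) * nb + ib
  s <- rowsum(cbind(x = det$x, y = det$y, n = 1), group = key,
              reorder = TRUE)
  kk <- as.numeric(rownames(s))
  out <- data.frame(
    tag_id = levels(tagf)[kk %/% nb + 1],
    bin_start = as.POSIXct(b0min + (kk %% nb) * w,
                           origin = "1970-01-01", tz = tz),
    x = s[, "x"] / s[, "n"],
    y = s[, "y"] / s[, "n"],
    n_detections = as.integer(s[, "n"]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("coa_track", "data.frame")
  out
}

#' Reassign on-land COAs to the nearest shore point
#'
#' Averaging detection positions across receivers can place a COA inland;
#' such positions are moved to the nearest point on the land-polygon
#' boundary.  Water positions (and positions exactly on the boundary) are
#' untouched.
#'
#' @param coas a \code{\link{compute_coas}} track.
#' @param mask a \code{\link{land_mask}}.
#' @return the track with on-land positions snapped.
#' @export
snap_to_shore <- function(coas, mask) {
  if (!nrow(coas)) return(coas)
  inland <- on_land(coas$x, coas$y, mask)
  if (any(inland)) {
    sn <- nearest_shore_point(coas$x[inland], coas$y[inland], mask)
    coas$x[inland] <- sn[, 1]
    coas$y[inland] <- sn[, 2]
  }
  coas
}
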