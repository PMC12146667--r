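# Small shared helpers. A calendar "day" throughout the package means a
# civil date in the analysis timezone (tz is carried on the telemetry
# object); detections are stored in UTC and converted at the point where
# days are counted.

#' Default analysis timezone
#'
#' Calendar days are counted in a local timezone; the default is UTC+11
#' (Olson id \code{"Etc/GMT-11"} -- the Etc sign convention is inverted).
#' @export
ISLANDRANGE_TZ <- "Etc/GMT-11"

# seconds east of UTC per element (handles DST); NULL if the platform
# does not expose gmtoff
tz_gmtoff <- function(t, tz) {
  off <- as.POSIXlt(t, tz = tz)$gmtoff
  if (is.null(off) || anyNA(off)) NULL else off
}

local_date <- function(t, tz) {
  off <- tz_gmtoff(t, tz)
  if (is.null(off)) {
    as.Date(format(t, tz = tz, format = "%Y-%m-%d"))
  } else {
    as.Date(floor((as.numeric(t) + off) / 86400), origin = "1970-01-01")
  }
}

# integer index of the local hour containing each timestamp
local_hour_index <- function(t, tz) {
  off <- tz_gmtoff(t, tz)
  if (is.null(off)) off <- 0
  floor((as.numeric(t) + off) / 3600)
}

parse_utc <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  xs <- as.character(x)
  try1 <- function(v) {
    tryCatch(as.POSIXct(v, tz = "UTC", tryFormats = fmts),
             error = function(e) as.POSIXct(rep(NA_character_,
                                                length(v)), tz = "UTC"))
  }
  t <- try1(xs)
  bad <- which(is.na(t) & !is.na(xs) & nzchar(xs))
  if (length(bad)) {
    # re-parse elementwise so one bad row does not hide the good ones
    t[bad] <- do.call(c, lapply(xs[bad], try1))
    bad <- which(is.na(t) & !is.na(xs) & nzchar(xs))
  }
  if (length(bad)) {
    stop(sprintf("unparseable %s at row(s): %s (first offending value: '%s')",
                 what, paste(utils::head(bad, 5), collapse = ", "),
                 xs[bad[1]]), call. = FALSE)
  }
  t
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inclusive day count between two dates
ndays_inclusive <- function(d1, d2) as.integer(d2 - d1) + 1L
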