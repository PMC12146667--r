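#' Kernel utilisation distribution on a land-masked grid
#'
#' Fixed-bandwidth bivariate Gaussian kernel density estimate of a set of
#' centre-of-activity positions, evaluated on a regular metric grid,
#' optionally masked by a land polygon, with level areas (smallest set of
#' cells holding a given fraction of the mass) for each requested
#' probability level.
#'
#' The kernel is isotropic with standard deviation \code{h} on each axis
#' and no cross term.  After zeroing land cells the surface is
#' renormalised over water (\code{mask_mode = "renormalise"}, default); with
#' \code{mask_mode = "clip"} the level sets are ranked on the unmasked
#' surface and land cells are merely excluded from the area counts.
#'
#' @param coas a COA track (data frame with \code{x, y}) or any 2-column
#'   matrix of positions in metres.
#' @param h kernel bandwidth, metres.
#' @param cell grid cell size, metres.
#' @param mask optional \code{\link{land_mask}}.
#' @param levels percentage levels for utilisation-distribution areas.
#' @param pad grid padding beyond the position bounding box, metres
#'   (default \code{4 * h}).
#' @param xlim,ylim optional explicit grid limits (metres); supply the
#'   same limits to every group whose surfaces will be compared with
#'   \code{\link{ud_overlap}}.
#' @param mask_mode \code{"renormalise"} or \code{"clip"}.
#' @return object of class \code{"ud_grid"}: grid axes \code{x, y} (cell
#'   centres), density matrix \code{z} (length(x) by length(y), integrates
#'   to 1 over water), \code{water} logical matrix, \code{level_sets}
#'   (named list of logical matrices), \code{areas_km2} (named numeric),
#'   \code{h}, \code{cell}, \code{n_coa}.
#' @export
kde_ud <- function(coas, h = 300, cell = 50, mask = NULL,
                   levels = c(50, 95), pad = 4 * h,
                   xlim = NULL, ylim = NULL,
                   mask_mode = c("renormalise", "clip")) {
  mask_mode <- match.arg(mask_mode)
  if (is.data.frame(coas)) {
    pts <- cbind(coas$x, coas$y)
  } else {
    pts <- as.matrix(coas)[, 1:2, drop = FALSE]
  }
  if (nrow(pts) == 0) stop("no COA positions to estimate from",
                           call. = FALSE)
  stopifnot(h > 0, cell > 0, all(levels > 0 & levels < 100))

  # grid of cell centres snapped to multiples of `cell` so that grids
  # built from the same limits align exactly
  if (is.null(xlim)) xlim <- range(pts[, 1]) + c(-pad, pad)
  if (is.null(ylim)) ylim <- range(pts[, 2]) + c(-pad, pad)
  xs <- seq(floor(xlim[1] / cell) * cell + cell / 2,
            ceiling(xlim[2] / cell) * cell, by = cell)
  ys <- seq(floor(ylim[1] / cell) * cell + cell / 2,
            ceiling(ylim[2] / cell) * cell, by = cell)

  z <- gaussian_grid_density(pts, xs, ys, h)
  z <- z / (sum(z) * cell^2)

  water <- matrix(TRUE, length(xs), length(ys))
  if (!is.null(mask)) {
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    water <- matrix(!on_land(gx, gy, mask), length(xs), length(ys))
  }

  rank_z <- z                      # surface used to rank cells
  if (!is.null(mask) && mask_mode == "renormalise") {
    z[!water] <- 0
    tot <- sum(z) * cell^2
    if (tot <= 0) stop("all density mass fell on land", call. = FALSE)
    z <- z / tot
    rank_z <- z
  }

  # level sets: cells sorted by density descending (ties by cell index),
  # smallest prefix whose mass reaches the level
  ord <- order(rank_z, decreasing = TRUE)
  mass <- rank_z[ord] * cell^2
  cum <- cumsum(mass) / sum(mass)
  level_sets <- list()
  areas <- numeric(length(levels))
  for (i in seq_along(levels)) {
    k <- which(cum >= levels[i] / 100)[1]
    sel <- matrix(FALSE, length(xs), length(ys))
    sel[ord[seq_len(k)]] <- TRUE
    if (mask_mode == "clip") sel <- sel & water
    level_sets[[i]] <- sel
    areas[i] <- sum(sel) * cell^2 / 1e6
  }
  names(level_sets) <- names(areas) <- paste0("ud", levels)

  structure(list(x = xs, y = ys, z = z, water = water,
                 level_sets = level_sets, areas_km2 = areas,
                 levels = levels, h = h, cell = cell,
                 n_coa = nrow(pts), mask_mode = mask_mode),
            class = "ud_grid")
}

# Sum of isotropic Gaussian kernels evaluated at grid cell centres.
# Exact (separable, chunked over points) for moderate n; for large n the
# points are binned to the grid first and the count matrix is smoothed by
# separable Gaussian matrix products (binning error << h for cell << h).
gaussian_grid_density <- function(pts, xs, ys, h, exact_max = 4000) {
  nx <- length(xs); ny <- length(ys)
  n <- nrow(pts)
  if (n <= exact_max) {
    z <- matrix(0, nx, ny)
    chunk <- 2000L
    for (s in seq(1, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      wx <- stats::dnorm(outer(xs, pts[s:e, 1], "-"), sd = h)
      wy <- stats::dnorm(outer(ys, pts[s:e, 2], "-"), sd = h)
      z <- z + wx %*% t(wy)
    }
    z
  } else {
    ix <- pmin(nx, pmax(1L, round((pts[, 1] - xs[1]) / (xs[2] - xs[1])) + 1L))
    iy <- pmin(ny, pmax(1L, round((pts[, 2] - ys[1]) / (ys[2] - ys[1])) + 1L))
    cnt <- matrix(0, nx, ny)
    tab <- table(factor(ix, levels = seq_len(nx)),
                 factor(iy, levels = seq_len(ny)))
    cnt[] <- as.numeric(tab)
    kx <- stats::dnorm(outer(xs, xs, "-"), sd = h)
    ky <- stats::dnorm(outer(ys, ys, "-"), sd = h)
    kx %*% cnt %*% ky
  }
}

#' Utilisation-distribution level area
#' @param ud a \code{\link{kde_ud}} object.
#' @param level percentage level present in the fit.
#' @return area in km^2.
#' @export
ud_area <- function(ud, level) {
  stopifnot(inherits(ud, "ud_grid"))
  key <- paste0("ud", level)
  if (!key %in% names(ud$areas_km2)) {
    stop("level ", level, " not estimated; available: ",
         paste(ud$levels, collapse = ", "), call. = FALSE)
  }
  unname(ud$areas_km2[key])
}

#' Overlap between two utilisation distributions
#'
#' Area of the intersection of the two groups' level sets divided by the
#' arithmetic mean of the two level areas.  Equal surfaces give 1,
#' disjoint surfaces 0; the ratio cannot exceed 1 because the
#' intersection is contained in both sets.
#'
#' @param a,b \code{\link{kde_ud}} objects on identical grids.
#' @param level percentage level.
#' @return overlap value in \code{[0, 1]}.
#' @export
ud_overlap <- function(a, b, level = 50) {
  stopifnot(inherits(a, "ud_grid"), inherits(b, "ud_grid"))
  if (length(a$x) != length(b$x) || length(a$y) != length(b$y) ||
      any(a$x != b$x) || any(a$y != b$y) || a$cell != b$cell) {
    stop("utilisation grids do not share origin/cell/extent; rebuild with ",
         "common xlim/ylim", call. = FALSE)
  }
  key <- paste0("ud", level)
  inter <- sum(a$level_sets[[key]] & b$level_sets[[key]]) * a$cell^2 / 1e6
  denom <- mean(c(ud_area(a, level), ud_area(b, level)))
  inter / denom
}

#' Pairwise overlap matrix for a set of utilisation distributions
#' @param uds named list of \code{\link{kde_ud}} objects on one grid.
#' @param level percentage level.
#' @return symmetric matrix of overlap values with unit diagonal.
#' @export
ud_overlap_matrix <- function(uds, level = 50) {
  n <- length(uds)
  m <- matrix(1, n, n, dimnames = list(names(uds), names(uds)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- ud_overlap(uds[[i]], uds[[j]], level)
    }
  }
  m
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("<ud_grid> %d x %d cells of %g m, h = %g m, %d COAs\n",
              length(x$x), length(x$y), x$cell, x$h, x$n_coa))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %g%% UD area: %.3f km^2\n", x$levels[i],
                x$areas_km2[i]))
  }
  invisible(x)
}

#' @param x a \code{\link{kde_ud}} object.
#' @param mask optional land mask whose outline is drawn.
#' @param ... passed to \code{image}.
#' @rdname kde_ud
#' @export
plot.ud_grid <- function(x, mask = NULL, ...) {
  graphics::image(x$x, x$y, x$z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(32, "YlGnBu", rev = TRUE),
                  ...)
  for (key in names(x$level_sets)) {
    thr <- min(x$z[x$level_sets[[key]] & x$z > 0])
    graphics::contour(x$x, x$y, x$z, levels = thr, add = TRUE,
                      drawlabels = FALSE)
  }
  if (!is.null(mask)) {
    for (r in mask$rings_xy) graphics::lines(r, col = "grey30")
  }
  invisible(x)
}

#' Write a utilisation grid as an ESRI ASCII raster
#'
#' Plain-text \code{.asc} raster of the density surface, suitable for GIS
#' import (the projected frame is local; the six-line header carries the
#' cell size and lower-left corner).
#'
#' @param ud a \code{\link{kde_ud}} object.
#' @param path output file.
#' @export
write_ud_asc <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", length(ud$x)),
    sprintf("nrows %d", length(ud$y)),
    sprintf("xllcorner %.3f", ud$x[1] - ud$cell / 2),
    sprintf("yllcorner %.3f", ud$y[1] - ud$cell / 2),
    sprintf("cellsize %g", ud$cell),
    "NODATA_value -9999"), con)
  # rows from north to south
  for (j in rev(seq_along(ud$y))) {
    writeLines(paste(formatC(ud$z[, j], format = "e", digits = 6),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Write 50/95\% contour outlines of a utilisation grid as GeoJSON
#'
#' Contour polylines are traced at the density threshold of each level
#' set and written as MultiLineString features in the mask's geographic
#' coordinates (WGS84).
#'
#' @param ud a \code{\link{kde_ud}} object.
#' @param mask the \code{\link{land_mask}} providing the projection.
#' @param path output file.
#' @export
write_ud_contours_geojson <- function(ud, mask, path) {
  feats <- list()
  for (i in seq_along(ud$levels)) {
    key <- paste0("ud", ud$levels[i])
    zin <- ud$z[ud$level_sets[[key]] & ud$z > 0]
    if (!length(zin)) next
    cl <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = min(zin))
    lines <- lapply(cl, function(l) {
      ll <- mask$projection$unproject(l$x, l$y)
      lapply(seq_len(nrow(ll)), function(k) c(ll[k, 1], ll[k, 2]))
    })
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(level = ud$levels[i]),
      geometry = list(type = "MultiLineString", coordinates = lines))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
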