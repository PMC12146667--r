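#' Cyclic seasonal mixed-model smoother for monthly indices
#'
#' Fits monthly residency or roaming indices with a species-specific
#' cyclic cubic regression spline on month (period 12, \code{k = 12}
#' basis) plus animal and year random intercepts:
#' \deqn{y = \beta_{species} + s_{species}(month) + b_{animal} + b_{year}
#'   + \epsilon}
#' Smoothing parameters and random-effect variances are estimated by REML
#' (the random intercepts enter as random-effect smooths, the standard
#' penalized-regression representation of a mixed model).  The cyclic
#' constraint makes the fitted curve and its derivatives continuous
#' across the December-to-January wrap.
#'
#' The indices live on \code{[0, 1]}; the default fits them on the
#' identity scale with Gaussian errors, \code{transform = "logit"}
#' applies an empirical logit first.
#'
#' @param idx monthly index table from \code{\link{compute_indices}}
#'   (rows with \code{scope == "month"}), or any data frame with columns
#'   \code{tag_id, species, year, month} and the response.
#' @param response \code{"resi"} or \code{"roi"}.
#' @param k cyclic basis dimension.
#' @param transform response transform.
#' @return object of class \code{"seasonal_fit"}: the \code{mgcv} model,
#'   per-species smooth table (edf, F, p), fitted curves with 95\% CI on a
#'   fine month grid, and the data used.
#' @export
fit_seasonal_smoother <- function(idx, response = c("resi", "roi"),
                                  k = 12,
                                  transform = c("identity", "logit")) {
  response <- match.arg(response)
  transform <- match.arg(transform)
  d <- as.data.frame(idx)
  if ("scope" %in% names(d)) d <- d[d$scope == "month", , drop = FALSE]
  need <- c("tag_id", "species", "year", "month", response)
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("index table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- d[stats::complete.cases(d[, need]), need]
  d$y <- d[[response]]
  if (transform == "logit") {
    eps <- 1 / (2 * max(30, nrow(d)))
    d$y <- stats::qlogis(pmin(1 - eps, pmax(eps, d$y)))
  }
  d$species <- factor(d$species)
  d$tag_id <- factor(d$tag_id)
  d$year <- factor(d$year)
  d$month <- as.numeric(d$month)

  multi_species <- nlevels(d$species) > 1
  re_animal <- nlevels(d$tag_id) > 1
  re_year <- nlevels(d$year) > 1
  if (!re_animal) {
    warning("only one animal: dropping random intercepts", call. = FALSE)
  }

  # degenerate input: an exactly constant response gives a zero-variance
  # working model; return the flat fit directly
  if (stats::sd(d$y) == 0) {
    return(flat_seasonal_fit(d, response, transform))
  }

  terms <- character(0)
  if (multi_species) {
    terms <- c("species", sprintf("s(month, bs = 'cc', k = %d, by = species)",
                                  k))
  } else {
    terms <- sprintf("s(month, bs = 'cc', k = %d)", k)
  }
  if (re_animal) terms <- c(terms, "s(tag_id, bs = 're')")
  if (re_animal && re_year) terms <- c(terms, "s(year, bs = 're')")
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))

  model <- mgcv::gam(fml, data = d, method = "REML",
                     knots = list(month = c(0.5, 12.5)))

  st <- summary(model)$s.table
  is_month <- grepl("^s\\(month", rownames(st))
  smooth_table <- data.frame(
    species = if (multi_species) {
      sub("^s\\(month\\):species", "", rownames(st)[is_month])
    } else levels(d$species),
    edf = st[is_month, "edf"],
    F = st[is_month, grep("^(F|Chi)", colnames(st))[1]],
    p_value = st[is_month, "p-value"],
    row.names = NULL, stringsAsFactors = FALSE)

  curves <- seasonal_curves(model, d, multi_species, transform)

  structure(list(model = model, response = response,
                 transform = transform, smooth_table = smooth_table,
                 curves = curves, data = d,
                 random_effects = c(animal = re_animal,
                                    year = re_animal && re_year)),
            class = "seasonal_fit")
}

seasonal_curves <- function(model, d, multi_species, transform,
                            months = seq(0.5, 12.5, by = 0.1)) {
  sp_levels <- levels(d$species)
  nd <- expand.grid(month = months, species = factor(sp_levels,
                                                     levels = sp_levels))
  nd$tag_id <- factor(levels(d$tag_id)[1], levels = levels(d$tag_id))
  nd$year <- factor(levels(d$year)[1], levels = levels(d$year))
  excl <- intersect(c("s(tag_id)", "s(year)"),
                    vapply(model$smooth, function(s) s$label, ""))
  pr <- stats::predict(model, newdata = nd, se.fit = TRUE,
                       exclude = excl, newdata.guaranteed = TRUE)
  out <- data.frame(species = as.character(nd$species), month = nd$month,
                    fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
                    stringsAsFactors = FALSE)
  out$lo <- out$fit - 1.96 * out$se
  out$hi <- out$fit + 1.96 * out$se
  if (transform == "logit") {
    out[c("fit", "lo", "hi")] <- lapply(out[c("fit", "lo", "hi")],
                                        stats::plogis)
  }
  out
}

flat_seasonal_fit <- function(d, response, transform) {
  mu <- mean(d$y)
  months <- seq(0.5, 12.5, by = 0.1)
  sp <- levels(d$species)
  curves <- data.frame(
    species = rep(sp, each = length(months)),
    month = rep(months, length(sp)),
    fit = if (transform == "logit") stats::plogis(mu) else mu,
    se = 0, stringsAsFactors = FALSE)
  curves$lo <- curves$hi <- curves$fit
  structure(list(model = NULL, response = response, transform = transform,
                 smooth_table = data.frame(species = sp, edf = 0, F = 0,
                                           p_value = 1,
                                           stringsAsFactors = FALSE),
                 curves = curves, data = d,
                 random_effects = c(animal = FALSE, year = FALSE)),
            class = "seasonal_fit")
}

#' Significance of the seasonal smooth terms
#'
#' Per-species test of the month smooth against a flat (constant) function.
#' \code{method = "wald"} reports the model's approximate Wald-type test of
#' the penalized smooth.  \code{method = "perm"} runs a permutation test:
#' month labels are shuffled within animal, the model is refitted with the
#' smoothing parameters fixed at their observed-fit values, and the
#' residual-sum-of-squares reduction attributable to the smooth is compared
#' with its permutation distribution (each species tested on its own
#' records); the attainable floor is \code{1 / (n_perm + 1)}.
#'
#' @param fit a \code{\link{fit_seasonal_smoother}} object.
#' @param method \code{"wald"} or \code{"perm"}.
#' @param n_perm number of permutations for \code{method = "perm"}.
#' @return data frame with one row per species: \code{species, p_value}
#'   (plus \code{edf, F} for Wald).
#' @export
smooth_significance <- function(fit, method = c("wald", "perm"),
                                n_perm = 999) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "seasonal_fit"))
  if (method == "wald" || is.null(fit$model)) {
    return(fit$smooth_table)
  }
  d <- fit$data
  out <- lapply(levels(d$species), function(sp) {
    ds <- droplevels(d[d$species == sp, , drop = FALSE])
    data.frame(species = sp,
               p_value = perm_smooth_p(ds, n_perm = n_perm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Permutation p-value for one species' cyclic smooth.  RSS-drop statistic
# with smoothing parameters (and random-effect structure) frozen at the
# observed REML fit.
perm_smooth_p <- function(ds, n_perm = 999, k = 12) {
  if (stats::sd(ds$y) == 0) return(1)
  re_animal <- nlevels(ds$tag_id) > 1
  re_year <- re_animal && nlevels(ds$year) > 1
  terms_full <- sprintf("s(month, bs = 'cc', k = %d)",
                        min(k, length(unique(ds$month))))
  terms_re <- character(0)
  if (re_animal) terms_re <- c(terms_re, "s(tag_id, bs = 're')")
  if (re_year) terms_re <- c(terms_re, "s(year, bs = 're')")
  fml_full <- stats::as.formula(
    paste("y ~", paste(c(terms_full, terms_re), collapse = " + ")))
  fml_null <- if (length(terms_re)) {
    stats::as.formula(paste("y ~", paste(terms_re, collapse = " + ")))
  } else {
    y ~ 1
  }
  m0 <- mgcv::gam(fml_full, data = ds, method = "REML",
                  knots = list(month = c(0.5, 12.5)))
  sp_full <- m0$sp
  n_smooth_sp <- length(sp_full) - length(terms_re)
  sp_null <- if (length(terms_re)) {
    utils::tail(sp_full, length(sp_full) - n_smooth_sp)
  } else NULL

  rss <- function(fml, data, sp) {
    m <- mgcv::gam(fml, data = data, sp = sp,
                   knots = list(month = c(0.5, 12.5)))
    sum(stats::residuals(m)^2)
  }
  stat_obs <- rss(fml_null, ds, sp_null) - rss(fml_full, ds, sp_full)

  ids <- split(seq_len(nrow(ds)), ds$tag_id)
  stat_perm <- numeric(n_perm)
  dp <- ds
  for (b in seq_len(n_perm)) {
    for (ii in ids) dp$month[ii] <- ds$month[sample(ii)]
    stat_perm[b] <- rss(fml_null, dp, sp_null) - rss(fml_full, dp, sp_full)
  }
  (1 + sum(stat_perm >= stat_obs)) / (1 + n_perm)
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf("<seasonal_fit> response = %s (%s scale), %d records, %s\n",
              x$response, x$transform, nrow(x$data),
              paste0(nlevels(x$data$species), " species")))
  st <- x$smooth_table
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  s(month) %-12s edf = %5.2f  p = %.4g\n",
                st$species[i], st$edf[i], st$p_value[i]))
  }
  invisible(x)
}

#' @param x a \code{seasonal_fit}.
#' @param ... passed to \code{matplot}.
#' @rdname fit_seasonal_smoother
#' @export
plot.seasonal_fit <- function(x, ...) {
  cv <- x$curves
  sp <- unique(cv$species)
  w <- matrix(cv$fit, ncol = length(sp))
  graphics::matplot(unique(cv$month), w, type = "l", lty = 1,
                    xlab = "month", ylab = x$response, ...)
  graphics::legend("topright", legend = sp, lty = 1,
                   col = seq_along(sp), bty = "n")
  invisible(x)
}
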