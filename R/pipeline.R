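#' Default pipeline configuration
#'
#' Returns the full list of tunable pipeline parameters; any subset can
#' be overridden through the \code{config} argument of
#' \code{\link{run_island_pipeline}}.
#'
#' @return named list of defaults.
#' @export
island_config <- function() {
  list(
    tz = ISLANDRANGE_TZ,
    window_h = 48,
    shed_min_days = 7, shed_max_gap_h = 24,
    min_period_days = 14,
    convention = "post48",
    month_min_days = 14,
    coa_bin_h = 2,
    jitter_rmax = 25,
    coa_exclude_sites = c("Chute", "Jonny"),
    h = 300, cell = 50, ud_levels = c(50, 95),
    mask_mode = "renormalise",
    usematrix_exclude_sites = c("Cabbage", "Fishbowl", "Phillip1",
                                "Phillip2", "Chute", "Jonny"),
    usematrix_unit = "individual_month",
    permanova_terms = c("species", "month", "release_site", "sex",
                        "size_class"),
    n_perm = 999,
    seasonal_k = 12,
    seed = 1)
}

#' Run the full island space-use pipeline
#'
#' Orchestrates QC, residency/roaming indices, centre-of-activity tracks,
#' kernel utilisation distributions with species-pair overlap, cyclic
#' seasonal smoothers, and the site-preference PERMANOVA; writes every
#' stage's table to \code{out_dir} together with a serialised copy of the
#' configuration and a markdown report.  Every numeric table in the
#' report is re-derivable from the stage CSVs.
#'
#' @param input either a \code{telemetry_data} object, an
#'   \code{island_sim} object, or a named list of file paths
#'   (\code{detections, receivers, tags, land}).
#' @param out_dir output directory; on any stage failure, partially
#'   written outputs are removed before the error propagates.
#' @param config named list overriding \code{\link{island_config}}
#'   entries.
#' @return object of class \code{"island_report"} (invisible list of all
#'   stage results).
#' @export
run_island_pipeline <- function(input, out_dir, config = list()) {
  cfg <- utils::modifyList(island_config(), config)
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  res <- tryCatch(
    run_pipeline_stages(input, out_dir, cfg, logmsg),
    error = function(e) {
      if (created) unlink(out_dir, recursive = TRUE)
      stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
    })
  invisible(res)
}

run_pipeline_stages <- function(input, out_dir, cfg, logmsg) {
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  tele <- if (inherits(input, "telemetry_data")) {
    input
  } else if (inherits(input, "island_sim")) {
    as_telemetry(input)
  } else {
    for (f in c("detections", "receivers", "tags", "land")) {
      if (is.null(input[[f]])) {
        stop("input is missing the '", f, "' entry", call. = FALSE)
      }
    }
    read_telemetry(input$detections, input$receivers, input$tags,
                   input$land, tz = cfg$tz)
  }
  logmsg("inputs: %d detections, %d tags, %d receivers",
         nrow(tele$detections), nrow(tele$tags), nrow(tele$receivers))

  # --- QC ---------------------------------------------------------------
  qc <- qc_detections(tele, window_h = cfg$window_h,
                      shed_min_days = cfg$shed_min_days,
                      shed_max_gap_h = cfg$shed_max_gap_h,
                      min_period_days = cfg$min_period_days,
                      convention = cfg$convention)
  utils::write.csv(qc$report, file.path(out_dir, "filter_report.csv"),
                   row.names = FALSE)
  logmsg("qc: retained %d of %d animals", sum(qc$report$retained),
         nrow(qc$report))
  if (!nrow(qc$detections)) stop("no detections survive QC")

  # --- indices ----------------------------------------------------------
  idx <- compute_indices(qc, monthly = TRUE,
                         month_min_days = cfg$month_min_days)
  utils::write.csv(idx, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)
  logmsg("indices: %d overall + %d monthly records",
         sum(idx$scope == "overall"), sum(idx$scope == "month"))

  # --- activity space ---------------------------------------------------
  set.seed(cfg$seed)
  pdet <- jitter_detections(qc$detections, qc$receivers,
                            rmax = cfg$jitter_rmax)
  coas <- compute_coas(pdet, bin_h = cfg$coa_bin_h, tz = qc$tz,
                       exclude_sites = cfg$coa_exclude_sites)
  coas <- snap_to_shore(coas, qc$land)

  sp_of <- qc$tags$species[match(coas$tag_id, qc$tags$tag_id)]
  rs_of <- qc$tags$release_site[match(coas$tag_id, qc$tags$tag_id)]
  groups <- split(seq_len(nrow(coas)), sp_of)
  # per-species x release-site surfaces where a species has >1 release site
  for (sp in unique(sp_of)) {
    rs <- unique(rs_of[sp_of == sp])
    if (length(rs) > 1) {
      for (r in rs) {
        groups[[paste(sp, r, sep = "@")]] <-
          which(sp_of == sp & rs_of == r)
      }
    }
  }
  xl <- range(coas$x) + c(-4, 4) * cfg$h
  yl <- range(coas$y) + c(-4, 4) * cfg$h
  uds <- lapply(groups, function(ii) {
    kde_ud(coas[ii, , drop = FALSE], h = cfg$h, cell = cfg$cell,
           mask = qc$land, levels = cfg$ud_levels, xlim = xl, ylim = yl,
           mask_mode = cfg$mask_mode)
  })
  ud_summary <- data.frame(
    group = names(uds),
    n_coa = vapply(uds, function(u) u$n_coa, 0),
    do.call(rbind, lapply(uds, function(u) as.data.frame(
      as.list(u$areas_km2)))),
    row.names = NULL)
  names(ud_summary)[-(1:2)] <- paste0("area",
                                      cfg$ud_levels, "_km2")
  utils::write.csv(ud_summary, file.path(out_dir, "ud_summary.csv"),
                   row.names = FALSE)
  overlaps <- lapply(cfg$ud_levels, function(lv) ud_overlap_matrix(uds, lv))
  names(overlaps) <- paste0("ud", cfg$ud_levels)
  for (lv in cfg$ud_levels) {
    utils::write.csv(overlaps[[paste0("ud", lv)]],
                     file.path(out_dir, sprintf("overlap%d.csv", lv)))
  }
  for (g in names(uds)) {
    safe <- gsub("[^A-Za-z0-9_@-]", "_", g)
    write_ud_asc(uds[[g]], file.path(out_dir,
                                     sprintf("ud_%s.asc", safe)))
    write_ud_contours_geojson(uds[[g]], qc$land,
                              file.path(out_dir,
                                        sprintf("ud_%s.geojson", safe)))
  }
  logmsg("activity space: %d surfaces on a %d x %d grid", length(uds),
         length(uds[[1]]$x), length(uds[[1]]$y))

  # --- seasonal smoother ------------------------------------------------
  seasonal <- list()
  for (resp in c("resi", "roi")) {
    fit <- tryCatch(
      fit_seasonal_smoother(idx, response = resp, k = cfg$seasonal_k),
      error = function(e) {
        logmsg("seasonal (%s) skipped: %s", resp, conditionMessage(e))
        NULL
      })
    seasonal[[resp]] <- fit
  }
  curves <- do.call(rbind, lapply(names(seasonal), function(r) {
    if (is.null(seasonal[[r]])) return(NULL)
    cbind(response = r, seasonal[[r]]$curves)
  }))
  tests <- do.call(rbind, lapply(names(seasonal), function(r) {
    if (is.null(seasonal[[r]])) return(NULL)
    cbind(response = r, seasonal[[r]]$smooth_table)
  }))
  if (!is.null(curves)) {
    utils::write.csv(curves, file.path(out_dir, "seasonal_fit.csv"),
                     row.names = FALSE)
  }
  if (!is.null(tests)) {
    utils::write.csv(tests, file.path(out_dir, "seasonal_tests.csv"),
                     row.names = FALSE)
    logmsg("seasonal: fitted %s", paste(names(seasonal), collapse = ", "))
  }

  # --- site preference --------------------------------------------------
  size_cls <- unlist(lapply(split(qc$tags, qc$tags$species), function(g) {
    g <- g[g$tag_id %in% qc$detections$tag_id, , drop = FALSE]
    if (nrow(g) < 4) return(stats::setNames(character(0), character(0)))
    ss <- tryCatch(size_split(g$total_length_m), error = function(e) NULL)
    if (is.null(ss)) return(stats::setNames(character(0), character(0)))
    stats::setNames(ss$labels, g$tag_id)
  }), use.names = TRUE)
  names(size_cls) <- sub("^[^.]*\\.", "", names(size_cls))

  um <- build_use_matrix(qc, exclude_sites = cfg$usematrix_exclude_sites,
                         unit = cfg$usematrix_unit,
                         size_class = size_cls)
  utils::write.csv(cbind(um$meta, as.data.frame(um$mat)),
                   file.path(out_dir, "use_matrix.csv"),
                   row.names = FALSE)
  # keep only terms that are complete, have >1 level, and add model rank
  # (a term aliased with earlier terms -- e.g. sex constant within
  # species -- is dropped rather than aborting the run)
  meta_f <- um$meta
  terms <- character(0)
  rank_prev <- 1L
  for (tm in cfg$permanova_terms) {
    vars <- strsplit(tm, ":")[[1]]
    ok <- all(vapply(vars, function(v) {
      x <- meta_f[[v]]
      !is.null(x) && !anyNA(x) && length(unique(x)) > 1
    }, TRUE))
    if (ok) {
      X <- stats::model.matrix(stats::reformulate(c(terms, tm)),
                               data = meta_f)
      r <- qr(X)$rank
      ok <- r > rank_prev && nrow(meta_f) - r > 0
      if (ok) rank_prev <- r
    }
    if (ok) terms <- c(terms, tm)
    else logmsg("permanova: dropping unusable/aliased term: %s", tm)
  }
  perm <- NULL
  if (length(terms)) {
    set.seed(cfg$seed + 1)
    perm <- permanova(bray_curtis(um), um$meta, terms,
                      n_perm = cfg$n_perm)
    utils::write.csv(as.data.frame(perm),
                     file.path(out_dir, "permanova.csv"),
                     row.names = FALSE)
    logmsg("permanova: %d terms, %d permutations", length(terms),
           cfg$n_perm)
  }

  report <- build_report(qc, idx, ud_summary, overlaps, tests, perm, cfg)
  writeLines(report, file.path(out_dir, "report.md"))
  logmsg("report written to %s", file.path(out_dir, "report.md"))

  invisible(structure(
    list(qc = qc, indices = idx, coas = coas, uds = uds,
         ud_summary = ud_summary, overlaps = overlaps,
         seasonal = seasonal, use_matrix = um, permanova = perm,
         config = cfg, out_dir = out_dir),
    class = "island_report"))
}

mean_se <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return("--")
  if (length(x) == 1) return(sprintf("%.2f", mean(x)))
  sprintf("%.2f ± %.2f", mean(x), stats::sd(x) / sqrt(length(x)))
}

build_report <- function(qc, idx, ud_summary, overlaps, tests, perm,
                         cfg) {
  out <- c("# Island space-use report", "")
  rep_tab <- qc$report

  out <- c(out, "## Tagging and filtering summary", "",
           paste("| species | tagged | analyzed | excluded short |",
                 "never detected | shed/dead | TL (m) |"),
           "|---|---|---|---|---|---|---|")
  for (sp in sort(unique(rep_tab$species))) {
    g <- rep_tab[rep_tab$species == sp, ]
    tl <- qc$tags$total_length_m[qc$tags$species == sp &
                                 qc$tags$tag_id %in% g$tag_id[g$retained]]
    out <- c(out, sprintf("| %s | %d | %d | %d | %d | %d | %s |",
                          sp, nrow(g), sum(g$retained),
                          sum(g$flag == "short_period"),
                          sum(g$flag == "never_detected"),
                          sum(g$flag == "shed_or_dead"), mean_se(tl)))
  }

  ov <- idx[idx$scope == "overall", ]
  out <- c(out, "", "## Detection and index summary", "",
           paste("| species | days detected | detection period (d) |",
                 "residency | roaming |"),
           "|---|---|---|---|---|")
  for (sp in sort(unique(ov$species))) {
    g <- ov[ov$species == sp, ]
    out <- c(out, sprintf(
      "| %s | %s (%d-%d) | %s (%d-%d) | %s (%.2f-%.2f) | %s (%.2f-%.2f) |",
      sp, mean_se(g$days_detected), min(g$days_detected),
      max(g$days_detected), mean_se(g$period_days), min(g$period_days),
      max(g$period_days), mean_se(g$resi), min(g$resi), max(g$resi),
      mean_se(g$roi), min(g$roi), max(g$roi)))
  }

  out <- c(out, "", "## Activity space (kernel UD areas)", "",
           "| group | n COA | area50 km2 | area95 km2 |",
           "|---|---|---|---|")
  for (i in seq_len(nrow(ud_summary))) {
    out <- c(out, sprintf("| %s | %d | %.2f | %.2f |",
                          ud_summary$group[i], ud_summary$n_coa[i],
                          ud_summary[i, 3], ud_summary[i, 4]))
  }
  for (lv in names(overlaps)) {
    m <- overlaps[[lv]]
    out <- c(out, "", sprintf("### Overlap (%s)", lv), "",
             paste0("| | ", paste(colnames(m), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(m) + 1), collapse = "|"),
                    "|"))
    for (i in seq_len(nrow(m))) {
      out <- c(out, paste0("| ", rownames(m)[i], " | ",
                           paste(sprintf("%.2f", m[i, ]),
                                 collapse = " | "), " |"))
    }
  }

  if (!is.null(tests)) {
    out <- c(out, "", "## Seasonal smooth significance", "",
             "| response | species | edf | p |", "|---|---|---|---|")
    for (i in seq_len(nrow(tests))) {
      out <- c(out, sprintf("| %s | %s | %.2f | %.4g |",
                            tests$response[i], tests$species[i],
                            tests$edf[i], tests$p_value[i]))
    }
  }

  if (!is.null(perm)) {
    out <- c(out, "", "## Site-preference PERMANOVA", "",
             "| term | df | SS | R2 | F | p |", "|---|---|---|---|---|---|")
    pt <- as.data.frame(perm)
    for (i in seq_len(nrow(pt))) {
      out <- c(out, sprintf("| %s | %d | %.4f | %.3f | %s | %s |",
                            pt$term[i], pt$df[i], pt$SS[i], pt$R2[i],
                            ifelse(is.na(pt$F[i]), "",
                                   sprintf("%.3f", pt$F[i])),
                            ifelse(is.na(pt$p_perm[i]), "",
                                   sprintf("%.3f", pt$p_perm[i]))))
    }
  }
  out
}

#' @export
print.island_report <- function(x, ...) {
  cat(sprintf("<island_report> outputs in %s\n", x$out_dir))
  cat(sprintf("  %d animals analyzed, %d UD surfaces, %s PERMANOVA terms\n",
              sum(x$qc$report$retained), length(x$uds),
              if (is.null(x$permanova)) "no"
              else length(attr(x$permanova, "terms"))))
  invisible(x)
}
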