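#' Individual site-use proportion matrix
#'
#' Collapses filtered detections to hourly presence per (analysis unit,
#' site) and normalises each unit's counts to proportions.  The analysis
#' unit is either the individual-month (default; month then enters the
#' PERMANOVA as a factor) or the individual.  Multiple detections of a
#' unit at one site within the same local hour count once.
#'
#' @param qc a \code{\link{qc_detections}} result (or list with
#'   \code{detections}, \code{tags}, \code{tz}).
#' @param exclude_sites receiver sites dropped before building the matrix
#'   (e.g. sites not deployed for the whole study, or redundant sites).
#' @param unit \code{"individual_month"} or \code{"individual"}.
#' @param size_class optional named character vector (tag_id ->
#'   \code{"small"}/\code{"large"}) attached to the row metadata.
#' @return object of class \code{"use_matrix"}: \code{mat} (rows = units,
#'   columns = sites, rows sum to 1) and \code{meta} (tag_id, species,
#'   release_site, sex, size_class, year, month).
#' @export
build_use_matrix <- function(qc, exclude_sites = character(0),
                             unit = c("individual_month", "individual"),
                             size_class = NULL) {
  unit <- match.arg(unit)
  det <- qc$detections
  det <- det[!det$receiver_id %in% exclude_sites, , drop = FALSE]
  sites <- sort(setdiff(unique(det$receiver_id), exclude_sites))
  if (!length(sites)) stop("all receiver sites excluded", call. = FALSE)

  hour <- local_hour_index(det$timestamp, qc$tz)
  unit_key <- if (unit == "individual_month") {
    dloc <- local_date(det$timestamp, qc$tz)
    ud <- unique(dloc)
    ym <- format(ud, "%Y-%m")[match(dloc, ud)]
    paste(det$tag_id, ym, sep = "|")
  } else {
    det$tag_id
  }
  # one presence per (unit, site, hour), deduplicated on a numeric key
  unitf <- factor(unit_key)
  sitef <- factor(det$receiver_id, levels = sites)
  h0 <- min(hour); nh <- max(hour) - h0 + 1
  pres_key <- ((as.integer(unitf) - 1) * length(sites) +
                 (as.integer(sitef) - 1)) * nh + (hour - h0)
  keep <- !duplicated(pres_key)

  tab <- table(unitf[keep], sitef[keep])
  mat <- matrix(as.numeric(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), sites))
  rs <- rowSums(mat)
  mat <- mat[rs > 0, , drop = FALSE] / rs[rs > 0]

  ids <- sub("\\|.*$", "", rownames(mat))
  tg <- qc$tags[match(ids, qc$tags$tag_id), , drop = FALSE]
  meta <- data.frame(
    tag_id = ids,
    species = tg$species,
    release_site = tg$release_site,
    sex = tg$sex,
    size_class = if (is.null(size_class)) NA_character_
                 else unname(size_class[ids]),
    stringsAsFactors = FALSE)
  if (unit == "individual_month") {
    ym_row <- sub("^.*\\|", "", rownames(mat))
    meta$year <- as.integer(substr(ym_row, 1, 4))
    meta$month <- as.integer(substr(ym_row, 6, 7))
  } else {
    meta$year <- NA_integer_; meta$month <- NA_integer_
  }
  structure(list(mat = mat, meta = meta, unit = unit,
                 exclude_sites = exclude_sites),
            class = "use_matrix")
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{d(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)} between
#' nonnegative composition rows.
#'
#' @param mat numeric matrix (rows = units) or a \code{use_matrix}.
#' @return object of class \code{"dist"}.
#' @export
bray_curtis <- function(mat) {
  if (inherits(mat, "use_matrix")) mat <- mat$mat
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("negative entries are not allowed", call. = FALSE)
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    stop("zero row(s): Bray-Curtis is undefined for empty compositions",
         call. = FALSE)
  }
  num <- stats::dist(mat, method = "manhattan")
  n <- nrow(mat)
  i <- unlist(lapply(seq_len(n - 1), function(k) seq(k + 1, n)))
  j <- rep(seq_len(n - 1), times = (n - 1):1)
  den <- rs[i] + rs[j]
  out <- as.numeric(num) / den
  attributes(out) <- attributes(num)
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a dissimilarity matrix among factors by sequential (Type-I)
#' sums of squares on the Gower-centred inner-product matrix, with
#' pseudo-F statistics tested against free permutations of the unit
#' labels: \eqn{p = (1 + \#\{F^{perm} \ge F^{obs}\}) / (1 + n_{perm})}.
#'
#' Repeated rows per animal (the individual-month unit) violate strict
#' exchangeability; pass \code{strata} to restrict permutations to within
#' groups (e.g. within animal) when that caveat matters.
#'
#' @param d a \code{"dist"} object (e.g. \code{\link{bray_curtis}}).
#' @param data data frame of factors, rows aligned with \code{d}.
#' @param terms character vector of model terms in the order their SS are
#'   stripped out; interactions as \code{"a:b"}.
#' @param n_perm number of permutations.
#' @param strata optional factor restricting permutations to within its
#'   levels.
#' @return object of class \code{"permanova"}: a data frame with one row
#'   per term plus Residual and Total (\code{df, SS, R2, F, p_perm}).
#' @examples
#' set.seed(1)
#' m <- matrix(runif(60), 12)
#' m <- m / rowSums(m)
#' meta <- data.frame(g = rep(c("a", "b"), each = 6))
#' permanova(bray_curtis(m), meta, "g", n_perm = 99)
#' @export
permanova <- function(d, data, terms, n_perm = 999, strata = NULL) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  data <- as.data.frame(data)
  if (nrow(data) != n) stop("metadata rows do not align with the distance ",
                            "matrix", call. = FALSE)
  for (v in unique(unlist(strsplit(terms, ":")))) {
    if (!v %in% names(data)) stop("unknown term variable: ", v,
                                  call. = FALSE)
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2) {
      stop("term '", v, "' has fewer than 2 levels", call. = FALSE)
    }
  }

  D2 <- as.matrix(d)^2
  Jc <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * Jc %*% D2 %*% Jc
  ss_total <- sum(diag(G))

  # cumulative hat matrices for the sequential decomposition
  hats <- vector("list", length(terms))
  ranks <- integer(length(terms))
  for (k in seq_along(terms)) {
    X <- stats::model.matrix(
      stats::reformulate(terms[seq_len(k)]), data = data)
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
    ranks[k] <- qrX$rank
  }
  df_term <- diff(c(1L, ranks))
  if (any(df_term <= 0)) {
    stop("aliased term(s): ",
         paste(terms[df_term <= 0], collapse = ", "), call. = FALSE)
  }
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) stop("more model df than observations", call. = FALSE)

  H0 <- matrix(1 / n, n, n)   # intercept-only hat
  decomp <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), 0)
    ss <- diff(c(sum(H0 * Gm), tr))
    ss_res <- sum(diag(Gm)) - tr[length(tr)]
    f <- (ss / df_term) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- decomp(G)

  exceed <- numeric(length(terms))
  if (n_perm > 0) {
    perm_index <- make_perm_fun(n, strata)
    for (b in seq_len(n_perm)) {
      p <- perm_index()
      fp <- decomp(G[p, p])$f
      exceed <- exceed + (fp >= obs$f - 1e-12)
    }
  }
  p_perm <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_term, df_res, n - 1L),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p_perm = c(p_perm, NA, NA),
    stringsAsFactors = FALSE)
  structure(tab, class = c("permanova", "data.frame"),
            n_perm = n_perm, terms = terms)
}

make_perm_fun <- function(n, strata) {
  if (is.null(strata)) {
    function() sample.int(n)
  } else {
    strata <- as.factor(strata)
    stopifnot(length(strata) == n)
    groups <- split(seq_len(n), strata)
    function() {
      p <- seq_len(n)
      for (g in groups) p[g] <- g[sample.int(length(g))]
      p
    }
  }
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations)\n",
              attr(x, "n_perm")))
  df <- as.data.frame(x)
  df$SS <- round(df$SS, 4); df$R2 <- round(df$R2, 4)
  df$F <- round(df$F, 3)
  print(df, row.names = FALSE, na.print = "")
  invisible(x)
}

#' @export
print.use_matrix <- function(x, ...) {
  cat(sprintf("<use_matrix> %d %s rows x %d sites\n", nrow(x$mat),
              x$unit, ncol(x$mat)))
  invisible(x)
}
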