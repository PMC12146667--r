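# Bray-Curtis distances, use matrices, and the permutation ANOVA

test_that("Bray-Curtis reproduces worked values and matches vegan", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 1)
  expect_equal(unname(as.matrix(bray_curtis(rbind(c(2, 1),
                                                  c(1, 1))))[1, 2]), 0.2)
  expect_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "zero row")
  expect_error(bray_curtis(rbind(c(1, -1), c(0, 1))), "negative")

  skip_if_not_installed("vegan")
  set.seed(1)
  x <- matrix(rexp(60), 10)
  expect_equal(as.numeric(bray_curtis(x)),
               as.numeric(vegan::vegdist(x, "bray")), tolerance = 1e-12)
})

test_that("use matrices are hourly-presence proportions per unit", {
  mask <- square_island()
  rec <- fixture_receivers(mask, c("Kingston", "Surf", "Far"),
                           c(1500, -1500, 0), c(0, 0, -1500))
  tags <- fixture_tags("T1")
  # 30 distinct hours at Kingston, 10 at Surf; plus a duplicate within
  # one hour that must count once
  t0 <- utc("2021-02-01 00:00:00")
  det <- rbind(
    det_df("T1", "Kingston", t0 + (0:29) * 3600),
    det_df("T1", "Surf", t0 + (48:57) * 3600),
    det_df("T1", "Kingston", t0 + 30 * 60))   # same hour as first ping
  qc <- fixture_qc(det, rec, tags, mask)
  um <- build_use_matrix(qc, unit = "individual")
  expect_equal(sum(um$mat), 1)
  expect_equal(unname(um$mat[1, "Kingston"]), 0.75)
  expect_equal(unname(um$mat[1, "Surf"]), 0.25)
  expect_false("Far" %in% colnames(um$mat)[um$mat[1, ] > 0])

  # excluded sites never appear as columns
  um2 <- build_use_matrix(qc, exclude_sites = "Surf",
                          unit = "individual")
  expect_false("Surf" %in% colnames(um2$mat))
  expect_error(build_use_matrix(qc, exclude_sites = c("Kingston", "Surf",
                                                      "Far")), "excluded")

  # individual-month units split rows by calendar month
  det3 <- rbind(det, det_df("T1", "Kingston",
                            utc("2021-03-05 00:00:00") + (0:5) * 3600))
  qc3 <- fixture_qc(det3, rec, tags, mask)
  um3 <- build_use_matrix(qc3, unit = "individual_month")
  expect_equal(nrow(um3$mat), 2)
  expect_equal(unname(rowSums(um3$mat)), c(1, 1))
  expect_equal(sort(um3$meta$month), c(2, 3))
})

test_that("univariate Euclidean pseudo-F equals the classical ANOVA F", {
  set.seed(2)
  y <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3))
  g <- factor(rep(c("a", "b", "c"), each = 8))
  pm <- permanova(dist(y), data.frame(g = g), "g", n_perm = 0)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(pm$F[1], f_aov, tolerance = 1e-9)
  expect_equal(pm$df[1:2], c(2L, 21L))
  expect_equal(sum(pm$R2[1:2]), 1, tolerance = 1e-9)
})

test_that("Monte-Carlo p matches exhaustive enumeration at n = 6", {
  skip_if_not_installed("vegan")
  set.seed(3)
  mat <- matrix(runif(18), 6)
  mat <- mat / rowSums(mat)
  meta <- data.frame(g = factor(c("a", "a", "a", "b", "b", "b")))
  d <- bray_curtis(mat)

  # independent oracle: observed-F rank among all 720 label permutations,
  # each F computed by vegan::adonis2 with no internal permutations
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_p <- perms(1:6)
  f_of <- function(p) {
    df <- data.frame(g = meta$g[p])
    as.data.frame(vegan::adonis2(d ~ g, data = df,
                                 permutations = 0))$F[1]
  }
  f_all <- vapply(all_p, f_of, 0)
  f_obs <- f_of(1:6)
  p_exact <- mean(f_all >= f_obs - 1e-12)

  set.seed(4)
  pm <- permanova(d, meta, "g", n_perm = 999)
  expect_equal(pm$F[1], f_obs, tolerance = 1e-9)
  expect_lt(abs(pm$p_perm[1] - p_exact), 0.02)
})

test_that("null data give uniform p: rejection rate 0.05 +/- 0.03", {
  set.seed(5)
  rej <- mean(replicate(200, {
    mat <- matrix(runif(20 * 5), 20)
    mat <- mat / rowSums(mat)
    meta <- data.frame(g = factor(rep(c("a", "b"), each = 10)))
    permanova(bray_curtis(mat), meta, "g", n_perm = 199)$p_perm[1] <= 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("disjoint groups reach the permutation floor", {
  mat <- rbind(matrix(rep(c(1, 0, 0, 0), each = 10), 10),
               matrix(rep(c(0, 0, 1, 0), each = 10), 10))
  mat <- mat + matrix(runif(80, 0, 0.01), 20)
  mat <- mat / rowSums(mat)
  meta <- data.frame(g = factor(rep(c("a", "b"), each = 10)))
  set.seed(6)
  pm <- permanova(bray_curtis(mat), meta, "g", n_perm = 999)
  expect_equal(pm$p_perm[1], 1 / 1000)
})

test_that("sequential SS agree with vegan::adonis2 on random fixtures", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (rep_i in 1:20) {
    n <- sample(16:30, 1)
    mat <- matrix(rexp(n * 6), n)
    mat <- mat / rowSums(mat)
    meta <- data.frame(
      g = factor(sample(c("a", "b", "c"), n, replace = TRUE)),
      h = factor(sample(c("x", "y"), n, replace = TRUE)))
    if (nlevels(droplevels(meta$g)) < 3) next
    d <- bray_curtis(mat)
    pm <- permanova(d, meta, c("g", "h"), n_perm = 199)
    va <- as.data.frame(vegan::adonis2(d ~ g + h, data = meta,
                                       permutations = 199, by = "terms"))
    expect_equal(pm$F[1:2], va$F[1:2], tolerance = 1e-8)
    expect_equal(pm$SS[1:2], va$SumOfSqs[1:2], tolerance = 1e-8)
    expect_equal(pm$R2[1:4], va$R2, tolerance = 1e-8)
  }
})

test_that("permutation p is seed-reproducible and respects strata", {
  set.seed(8)
  mat <- matrix(runif(24 * 4), 24); mat <- mat / rowSums(mat)
  meta <- data.frame(g = factor(rep(c("a", "b"), each = 12)),
                     animal = factor(rep(1:6, each = 4)))
  d <- bray_curtis(mat)
  set.seed(9); p1 <- permanova(d, meta, "g", n_perm = 199)$p_perm[1]
  set.seed(9); p2 <- permanova(d, meta, "g", n_perm = 199)$p_perm[1]
  expect_identical(p1, p2)
  set.seed(9)
  ps <- permanova(d, meta, "g", n_perm = 199,
                  strata = meta$animal)$p_perm[1]
  expect_true(ps >= 1 / 200 && ps <= 1)

  expect_error(permanova(d, meta, "nope", n_perm = 9), "unknown term")
  meta$one <- factor("z")
  expect_error(permanova(d, meta, "one", n_perm = 9), "levels")
})
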