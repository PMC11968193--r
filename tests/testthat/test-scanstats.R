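test_that("Hudson site components match hand-computed values", {
  # fixed difference
  f1 <- fst_site(1, 20, 0, 20)
  expect_equal(f1$num, 1); expect_equal(f1$den, 1); expect_equal(f1$fst, 1)
  # p1 = 0.9, p2 = 0.1, n = 20 alleles each
  f2 <- fst_site(0.9, 20, 0.1, 20)
  expect_equal(f2$num, 0.64 - 2 * (0.09 / 19))
  expect_equal(f2$den, 0.82)
  expect_equal(f2$fst, (0.64 - 2 * 0.09 / 19) / 0.82, tolerance = 1e-6)
  expect_equal(f2$fst, 0.76894, tolerance = 1e-4)
  # identical intermediate frequencies: negative numerator allowed
  f3 <- fst_site(0.5, 10, 0.5, 10)
  expect_equal(f3$num, -2 * 0.25 / 9)
  expect_equal(f3$num, -0.05556, tolerance = 1e-3)
  # undefined cases: both fixed same allele, or too few alleles
  f4 <- fst_site(0, 20, 0, 20)
  expect_true(is.na(f4$fst))
  f5 <- fst_site(0.5, 1, 0.5, 20)
  expect_true(is.na(f5$num))
})

test_that("window bookkeeping follows the 50 kb / 25 kb sliding design", {
  s <- tibble::tibble(chrom = "chr1", pos = 30001L, num = 0.5, den = 1)
  w <- fst_windows(s)
  expect_identical(w$start, c(0L, 25000L))
  expect_identical(w$end, c(50000L, 75000L))
  expect_equal(w$fst, c(0.5, 0.5))

  # ratio of sums, not mean of ratios
  s2 <- tibble::tibble(chrom = "chr1", pos = c(1000L, 2000L),
                       num = c(1, 0), den = c(1, 1))
  w2 <- fst_windows(s2)
  expect_equal(w2$fst[1], 0.5)

  # a window whose sites are all undefined is absent
  s3 <- tibble::tibble(chrom = "chr1", pos = c(1000L, 200000L),
                       num = c(NA, 1), den = c(NA, 1))
  w3 <- fst_windows(s3)
  expect_true(all(w3$start >= 150000L))

  # single-site window equals the site statistic
  s4 <- tibble::tibble(chrom = "chr1", pos = 10L, num = 0.3, den = 0.8)
  expect_equal(fst_windows(s4)$fst[1], 0.3 / 0.8)

  expect_error(fst_windows(s, window_bp = 100, step_bp = 200), "step")
})

test_that("windowed F_ST agrees with a brute-force per-window scan", {
  set.seed(8)
  s <- tibble::tibble(chrom = "chr1",
                      pos = sort(sample.int(300000L, 400L)),
                      num = rnorm(400), den = runif(400, 0.1, 1))
  w <- fst_windows(s, window_bp = 50000L, step_bp = 25000L)
  for (i in sample.int(nrow(w), 10)) {
    in_w <- s$pos - 1L >= w$start[i] & s$pos - 1L < w$end[i]
    expect_equal(w$fst[i], sum(s$num[in_w]) / sum(s$den[in_w]))
    expect_identical(w$n_sites[i], sum(in_w))
  }
})

test_that("percentile outliers use strict exceedance of the 99th percentile", {
  flags <- percentile_outliers(1:1000, q = 0.99)
  expect_identical(which(flags), 991:1000)
  expect_equal(attr(flags, "threshold"), 990.01)

  expect_false(any(percentile_outliers(rep(5, 500))))
  expect_warning(empty <- percentile_outliers(1:50, q = 0.99), "fewer")
  expect_false(any(empty))

  set.seed(1)
  x <- rnorm(10000)
  expect_equal(mean(percentile_outliers(x)), 0.01, tolerance = 0.15)
  # permutation invariance
  perm <- sample(10000)
  expect_identical(percentile_outliers(x)[perm],
                   as.logical(percentile_outliers(x[perm])))
})

test_that("PCA selection statistic is uniform on null data", {
  set.seed(17)
  n <- 40; L <- 4000
  p <- runif(L, 0.1, 0.9)
  d <- matrix(rbinom(n * L, 2L, rep(p, each = n)), nrow = n)
  scan <- pca_selection_scan(toy_geno(d), k = 1)
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(scan$selected), 0.05, tolerance = 0.5)
})

test_that("a site aligned with the population split tops the PCA scan", {
  set.seed(18)
  n <- 40; L <- 500
  # two drifted clusters so PC1 is the cluster axis, plus one site with a
  # fixed difference between the clusters
  p <- runif(L, 0.2, 0.8)
  p1 <- pmin(pmax(rbeta(L, p * 6, (1 - p) * 6), 0.02), 0.98)
  p2 <- pmin(pmax(rbeta(L, p * 6, (1 - p) * 6), 0.02), 0.98)
  d <- rbind(
    matrix(rbinom(n / 2 * L, 2L, rep(p1, each = n / 2)), nrow = n / 2),
    matrix(rbinom(n / 2 * L, 2L, rep(p2, each = n / 2)), nrow = n / 2)
  )
  d[, 250] <- c(rep(0L, n / 2), rep(2L, n / 2))
  scan <- pca_selection_scan(toy_geno(d), k = 1)
  expect_identical(scan$pos[which.max(scan$stat)], 250L)
  # constant sites are excluded
  d2 <- d; d2[, 1] <- 1L; d2[, 2] <- 0L
  scan2 <- pca_selection_scan(toy_geno(d2), k = 1)
  expect_false(2L %in% scan2$pos)
})

test_that("EHH matches combinatorial hand counts and is non-increasing", {
  # all carriers identical: EHH = 1 everywhere
  a <- matrix(0L, nrow = 4, ncol = 6)
  e <- ehh(a, core = 3)
  expect_true(all(e$ehh == 1))

  # 4 carriers splitting 2/2 at the first flanking site:
  # beyond it EHH = (C(2,2)+C(2,2))/C(4,2) = 2/6
  a2 <- matrix(0L, nrow = 4, ncol = 3)
  a2[, 3] <- c(0L, 0L, 1L, 1L)
  e2 <- ehh(a2, core = 1, direction = "right")
  expect_equal(e2$ehh, c(1, 1, 1 / 3))

  set.seed(9)
  a3 <- matrix(rbinom(16 * 20, 1, 0.5), nrow = 16)
  e3 <- ehh(a3, core = 10, direction = "right")
  expect_true(all(diff(e3$ehh) <= 1e-12))
  e4 <- ehh(a3, core = 10, direction = "left")
  expect_true(all(diff(e4$ehh) <= 1e-12))

  expect_error(ehh(a3[1, , drop = FALSE], core = 1), "2 carrier")
})

test_that("XP-EHH is zero under symmetry and antisymmetric under swap", {
  set.seed(10)
  a <- matrix(rbinom(12 * 30, 1, 0.5), nrow = 12)
  pos <- sort(sample.int(30000L, 30L))
  h <- toy_haps(a, pos)
  same <- suppressMessages(xpehh(h, h))
  expect_true(all(same$raw == 0))

  b <- matrix(rbinom(8 * 30, 1, 0.5), nrow = 8)
  h2 <- toy_haps(b, pos)
  ab <- suppressMessages(xpehh(h, h2))
  ba <- suppressMessages(xpehh(h2, h))
  expect_equal(ab$raw, -ba$raw, tolerance = 1e-12)
})

test_that("optimized XP-EHH equals the exhaustive partition oracle", {
  set.seed(12)
  for (rep in 1:20) {
    Ha <- 2L * sample(2:8, 1)
    Hb <- 2L * sample(2:8, 1)
    L <- sample(5:20, 1)
    pos <- sort(sample.int(5000L, L))
    a <- matrix(rbinom(Ha * L, 1, runif(1, 0.2, 0.8)), nrow = Ha)
    b <- matrix(rbinom(Hb * L, 1, runif(1, 0.2, 0.8)), nrow = Hb)
    res <- suppressMessages(xpehh(toy_haps(a, pos), toy_haps(b, pos)))
    oracle <- oracle_xpehh_raw(a, b, pos)
    oracle <- oracle[!is.na(oracle)]
    expect_equal(res$raw, unname(oracle), tolerance = 1e-10)
  }
})

test_that("rank p-values follow the strict -log10(p) > 2 rule", {
  set.seed(14)
  x <- sample(rnorm(1000))  # distinct scores
  p <- rank_pvalues(x)
  expect_identical(sum(-log10(p) > 2), 9L)
  # the 9 significant sites are the largest |scores|
  expect_setequal(which(-log10(p) > 2), order(-abs(x))[1:9])

  expect_false(any(-log10(rank_pvalues(rep(1, 500))) > 2))

  # rank invariance under monotone transform of |scores|
  y <- sign(x) * exp(abs(x))
  expect_identical(which(-log10(rank_pvalues(y)) > 2),
                   which(-log10(p) > 2))
  # permutation invariance
  perm <- sample(1000)
  expect_equal(rank_pvalues(x[perm]), p[perm])
})

test_that("a planted sweep yields a top-percentile positive XP-EHH score", {
  cfg <- sim_config(
    populations = tibble::tibble(
      population = c("res", "mig"), clade = "c1",
      phenotype = c("resident", "migrant"), n_diploids = 10L),
    f_clade = 0, f_pop = 0.02, l_sites = 2000L, chrom_length_bp = 2e6,
    n_genes = 4L, n_sweep_genes = 1L, n_clade_sweeps = 0L,
    sweep_radius_bp = 40000L, resident_units = list("res"), seed = 19)
  co <- simulate_cohort(cfg)
  pm <- co$popmap
  ha <- subset_samples(co$haps, pm$sample[pm$population == "res"])
  hb <- subset_samples(co$haps, pm$sample[pm$population == "mig"])
  xp <- suppressMessages(xpehh(ha, hb))
  g <- co$genes[co$genes$sweep_kind == "resident", ]
  core <- (g$start + g$end) / 2
  near <- abs(xp$pos - core) <= 5000
  q99 <- stats::quantile(xp$std, 0.99)
  expect_gt(max(xp$std[near]), q99)
})
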