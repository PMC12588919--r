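test_that("shapiro_wilk wrapper validates its input and calibrates under the null", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  set.seed(13)
  ps <- replicate(400, shapiro_wilk(stats::rnorm(100))$p)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # strong skew is detected nearly always
  rej <- mean(replicate(200, shapiro_wilk(exp(stats::rnorm(100)))$p < 0.05))
  expect_gte(rej, 0.95)
})

test_that("the normalization ladder picks the expected rungs", {
  set.seed(14)
  expect_equal(normalize_trait(stats::rnorm(100))$method, "identity")
  tags <- replicate(200, normalize_trait(exp(stats::rnorm(100)))$method)
  expect_gte(mean(tags == "log"), 0.9)
  # heavy tails with negatives defeat the ladder
  expect_equal(normalize_trait(stats::rcauchy(100))$method, "nonparametric")
  expect_error(normalize_trait(stats::rnorm(10)), ">= 20")
})

test_that("Box-Cox rescues power-skewed positive traits", {
  set.seed(15)
  hits <- replicate(50, {
    y <- (abs(stats::rnorm(150, 4, 1)))^2.5 # needs lambda ~ 0.4
    normalize_trait(y)$method
  })
  expect_gte(mean(hits %in% c("boxcox", "log", "identity")), 0.9)
})

test_that("parametric LOD equals the closed-form regression oracle per marker", {
  cross <- make_test_cross(n = 80, seed = 16)
  set.seed(17)
  y <- stats::setNames(stats::rnorm(80), rownames(cross$geno))
  sc <- scan_parametric(cross, y)
  G <- geno_numeric(cross)
  for (m in seq_len(ncol(G))) {
    fit1 <- stats::lm(y ~ factor(G[, m])) # saturated = additive + dominance
    rss1 <- sum(stats::resid(fit1)^2)
    rss0 <- sum((y - mean(y))^2)
    expect_equal(sc$lod[m], 80 / 2 * log10(rss0 / rss1), tolerance = 1e-8)
  }
})

test_that("a phenotype equal to the additive coding gives a dominating peak", {
  cross <- make_test_cross(n = 100, seed = 18)
  g <- geno_numeric(cross)[, 20] - 1
  y <- stats::setNames(as.numeric(g), rownames(cross$geno))
  sc <- scan_parametric(cross, y)
  expect_gt(sc$lod[20], 15)
  expect_equal(which.max(sc$lod), 20L)
})

test_that("planted-QTL peak LOD matches the closed-form expectation", {
  # E[peak LOD] ~ -(n/2) log10(1 - PVE) = 9.69 at n = 200, PVE 0.20
  map <- simulate_map(3, 20, 80)
  lods <- vapply(1:30, function(i) {
    cr <- simulate_genotypes(200, map, seed = 400 + i)
    y <- simulate_phenotype(cr, map$marker[30], a = 1, d = 0, pve = 0.2,
                            seed = 500 + i)
    max(scan_parametric(cr, y)$lod)
  }, numeric(1))
  expect_lt(abs(mean(lods) - (-(200 / 2) * log10(1 - 0.2))), 1.5)
})

test_that("estimated PVE at the true marker tracks the planted PVE", {
  map <- simulate_map(2, 15, 80)
  est <- vapply(1:40, function(i) {
    cr <- simulate_genotypes(200, map, seed = 600 + i)
    y <- simulate_phenotype(cr, map$marker[8], a = 1, d = 0, pve = 0.2,
                            seed = 700 + i)
    sc <- scan_parametric(cr, y)
    pve(sc$lod[8], attr(sc, "n"))
  }, numeric(1))
  expect_lt(abs(mean(est) - 20), 5)
})

test_that("rank scan is monotone-invariant and behaves under the null", {
  cross <- make_test_cross(n = 200, seed = 19)
  set.seed(20)
  y <- stats::setNames(stats::rnorm(200), rownames(cross$geno))
  sc1 <- scan_nonparametric(cross, y)
  sc2 <- scan_nonparametric(cross, stats::setNames(stats::pnorm(y), names(y)))
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-12)
  # null mean of the LOD analog ~ E[chi2_2]/(2 ln 10) = 0.434
  ms <- replicate(20, mean(scan_nonparametric(
    cross, stats::setNames(stats::rnorm(200), rownames(cross$geno)))$lod))
  expect_lt(abs(mean(ms) - 2 / (2 * log(10))), 0.06)
})

test_that("rank scan matches kruskal.test per marker and finds planted QTL", {
  cross <- make_test_cross(n = 150, seed = 21)
  y <- simulate_phenotype(cross, cross$map$marker[10], a = 1, d = 0,
                          pve = 0.25, seed = 22)
  scp <- scan_parametric(cross, y)
  scn <- scan_nonparametric(cross, y)
  G <- geno_numeric(cross)
  for (m in c(1, 10, 25)) {
    kw <- stats::kruskal.test(unname(y), factor(G[, m]))
    expect_equal(scn$lod[m], unname(kw$statistic) / (2 * log(10)),
                 tolerance = 1e-10)
  }
  expect_equal(which.max(scn$lod), which.max(scp$lod))
  expect_lt(max(scn$lod), max(scp$lod)) # modest efficiency loss on normal data
})

test_that("markers with fewer than two genotype classes are flagged at LOD 0", {
  cross <- make_test_cross(n = 60, seed = 23)
  cross$geno[, 4] <- "A"
  y <- stats::setNames(stats::rnorm(60), rownames(cross$geno))
  sc <- scan_parametric(cross, y)
  expect_equal(sc$lod[4], 0)
  expect_true(cross$map$marker[4] %in% attr(sc, "flagged"))
})

test_that("missing genotype calls are dropped per marker in both scans", {
  cross <- make_test_cross(n = 120, seed = 24)
  set.seed(25)
  cross$geno[sample(length(cross$geno), 300)] <- NA
  y <- stats::setNames(stats::rnorm(120), rownames(cross$geno))
  scp <- scan_parametric(cross, y)
  scn <- scan_nonparametric(cross, y)
  G <- geno_numeric(cross)
  m <- 7
  keep <- !is.na(G[, m])
  fit1 <- stats::lm(y[keep] ~ factor(G[keep, m]))
  rss0 <- sum((y[keep] - mean(y[keep]))^2)
  expect_equal(scp$lod[m],
               sum(keep) / 2 * log10(rss0 / sum(stats::resid(fit1)^2)),
               tolerance = 1e-8)
  kw <- stats::kruskal.test(unname(y[keep]), factor(G[keep, m]))
  expect_equal(scn$lod[m], unname(kw$statistic) / (2 * log(10)),
               tolerance = 1e-10)
})

test_that("permutation thresholds are reproducible and relabeling-invariant", {
  cross <- make_test_cross(n = 100, seed = 26)
  set.seed(27)
  y <- stats::setNames(stats::rnorm(100), rownames(cross$geno))
  t1 <- permutation_threshold(cross, y, "parametric", n_perm = 120,
                              alpha = 0.05, seed = 5)
  t2 <- permutation_threshold(cross, y, "parametric", n_perm = 120,
                              alpha = 0.05, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  # relabeling individuals leaves the threshold unchanged
  yp <- y[sample(names(y))]
  t3 <- permutation_threshold(cross, yp, "parametric", n_perm = 120,
                              alpha = 0.05, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t3))
  expect_gt(as.numeric(t1), 0)
  expect_warning(permutation_threshold(cross, y, "parametric", n_perm = 50,
                                       alpha = 0.05, seed = 5), "unstable")
})

test_that("pve follows the LOD identity", {
  expect_equal(pve(0, 100), 0)
  expect_equal(pve(5, 100), 100 * (1 - 10^(-0.1)))
  expect_lt(abs(pve(5, 100) - 20.57), 0.01)
  lods <- seq(0, 10, by = 0.5)
  expect_true(all(diff(pve(lods, 150)) > 0))
  expect_true(all(pve(lods, 150) < 100))
})

test_that("Bayes intervals localize sharp peaks and respect symmetry", {
  cm <- seq(0, 40, by = 2)
  lod <- rep(0, 21)
  lod[11] <- 10
  ci <- bayes_interval(lod, cm)
  expect_lte(ci[["high"]] - ci[["low"]], 4) # collapses to the peak vicinity
  expect_true(ci[["low"]] <= 20 && ci[["high"]] >= 20)

  sym <- 6 - abs(seq(-10, 10)) * 0.5
  ci2 <- bayes_interval(sym, cm)
  expect_equal(ci2[["high"]] - 20, 20 - ci2[["low"]], tolerance = 2)

  flat <- bayes_interval(rep(2, 21), cm)
  expect_true(attr(flat, "flat"))
  expect_equal(as.numeric(flat), c(0, 40))
})

test_that("Bayes intervals cover the true location at roughly nominal rate", {
  map <- simulate_map(1, 30, 100)
  qm <- 15
  hits <- vapply(1:100, function(i) {
    cr <- simulate_genotypes(150, map, seed = 1000 + i)
    y <- simulate_phenotype(cr, map$marker[qm], a = 1, d = 0, pve = 0.25,
                            seed = 2000 + i)
    sc <- scan_parametric(cr, y)
    ci <- bayes_interval(sc$lod, sc$cM)
    map$cM[qm] >= ci[["low"]] && map$cM[qm] <= ci[["high"]]
  }, logical(1))
  expect_gte(mean(hits), 0.91)
})

test_that("scan_qtl gates normality, reports consistent peaks and is deterministic", {
  map <- simulate_map(4, 15, 80)
  cross <- simulate_genotypes(80, map, seed = 28)
  qmk <- map$marker[22]
  y <- simulate_phenotype(cross, qmk, a = 1, d = 0, pve = 0.35, seed = 29)

  traits <- make_factorial_traits(80, positions = "middle", daylengths = 14L,
                                  years = 2021L)
  traits$genotype_id <- rep(rownames(cross$geno), 1)
  traits$total_area <- exp(y[traits$genotype_id]) # lognormal size trait
  set.seed(30)
  for (p in setdiff(trait_names(), "total_area")) {
    traits[[p]] <- stats::rnorm(nrow(traits))
  }
  traits <- traits[, c(names(traits)[1:6], "total_area", "veins_to_blade")]
  tm <- assemble_trait_matrix(traits)

  cfgs <- scan_config(seed = 31, n_perm = 150)
  peaks <- scan_qtl(tm, cross, cfgs)
  tot <- peaks[peaks$phenotype == "total_area", ]
  expect_gte(nrow(tot), 1L)
  expect_true(qmk %in% tot$peak_marker)
  expect_true(all(tot$transform %in% c("log", "boxcox", "identity")))
  # stored PVE back-computes exactly from LOD and n
  expect_equal(peaks$pve, pve(peaks$lod, peaks$n), tolerance = 1e-12)
  expect_true(all(peaks$lod >= peaks$threshold))
  expect_true(all(peaks$ci_low <= peaks$peak_cM & peaks$peak_cM <= peaks$ci_high))

  peaks2 <- scan_qtl(tm, cross, cfgs)
  expect_identical(peaks, peaks2)
})

test_that("scan_qtl skips thin attributes and rejects orphan genotypes", {
  map <- simulate_map(2, 10, 60)
  cross <- simulate_genotypes(50, map, seed = 32)
  traits <- make_factorial_traits(50, positions = "middle", daylengths = 14L,
                                  years = 2021L)
  traits$genotype_id <- rownames(cross$geno)
  set.seed(33)
  for (p in trait_names()) traits[[p]] <- stats::rnorm(50)
  traits <- traits[, c(names(traits)[1:6], "total_area", "blade_area")]
  traits$blade_area[6:50] <- NA # only 5 values -> skipped
  tm <- assemble_trait_matrix(traits)
  peaks <- scan_qtl(tm, cross, scan_config(seed = 34, n_perm = 100))
  skipped <- attr(peaks, "skipped")
  expect_true(any(grepl("blade_area", skipped$trait)))

  tm_bad <- tm
  tm_bad$genotype[1] <- "stranger"
  rownames(tm_bad$values)[1] <- "stranger"
  expect_error(scan_qtl(tm_bad, cross, scan_config(seed = 35)),
               "reconciliation error.*stranger")
})
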