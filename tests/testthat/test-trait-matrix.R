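test_that("full-factorial assembly yields the expected attribute expansion", {
  traits <- make_factorial_traits(5)
  tm <- assemble_trait_matrix(traits)
  expect_equal(ncol(tm$values), 192L) # 16 x 3 x 2 x 2
  expect_equal(nrow(tm$values), 5L)
  expect_equal(length(tm$values), 5L * 192L)
  expect_true(all(tm$counts == 1L))
  # enumeration oracle: observed level products
  att <- tm$attributes
  expect_equal(ncol(tm$values),
               length(unique(att$phenotype)) * length(unique(att$position)) *
                 length(unique(att$daylength_h)) * length(unique(att$year)))
})

test_that("single-cell input gives 16 columns and duplicates are handled", {
  traits <- make_factorial_traits(1, positions = "middle", daylengths = 14L,
                                  years = 2021L)
  tm <- assemble_trait_matrix(traits)
  expect_equal(ncol(tm$values), 16L)

  dup <- rbind(traits, traits)
  dup$leaf_id <- paste0(dup$leaf_id, c("", "_b"))
  dup[2, trait_names()] <- dup[2, trait_names()] + 2
  tm2 <- assemble_trait_matrix(dup)
  expect_true(all(tm2$counts == 2L))
  expect_equal(unname(tm2$values[1, "total_area__middle__14h__2021"]),
               mean(c(traits$total_area, traits$total_area + 2)))
  expect_error(assemble_trait_matrix(dup, strict = TRUE), "duplicate-record")
})

test_that("missing cells are preserved and round-trip through CSV", {
  traits <- make_factorial_traits(4)
  traits <- traits[-3, ] # drop one leaf -> 16 missing cells for that cell combo
  tm <- assemble_trait_matrix(traits)
  expect_equal(sum(is.na(tm$values)), 16L)
  f <- tempfile(fileext = ".csv")
  write_trait_matrix(tm, f)
  tm2 <- read_trait_matrix(f)
  expect_equal(tm2$values, tm$values)
  expect_equal(tm2$presentation, tm$presentation)
})

test_that("z-transform standardizes within phenotype x position x presentation", {
  traits <- make_factorial_traits(6)
  set.seed(3)
  for (p in trait_names()) traits[[p]] <- stats::rnorm(nrow(traits), 50, 9)
  tm <- z_transform_matrix(assemble_trait_matrix(traits))
  grp <- paste(tm$attributes$phenotype, tm$attributes$position)
  for (g in unique(grp)[1:5]) {
    cells <- tm$values[, grp == g]
    expect_lt(abs(mean(cells)), 1e-12)
    expect_lt(abs(stats::sd(cells) - 1), 1e-12)
  }
  # idempotence
  tm2 <- z_transform_matrix(tm)
  expect_equal(tm2$values, tm$values, tolerance = 1e-12)
})

test_that("z-transform matches the hand example and rejects zero variance", {
  traits <- make_factorial_traits(3, positions = "middle", daylengths = 14L,
                                  years = 2021L)
  traits$total_area <- c(2, 4, 6)
  tm <- z_transform_matrix(assemble_trait_matrix(traits))
  expect_equal(unname(tm$values[, "total_area__middle__14h__2021"]),
               c(-1, 0, 1))
  traits$total_area <- c(5, 5, 5)
  expect_error(z_transform_matrix(assemble_trait_matrix(traits)),
               "zero-variance group")
})

test_that("kruskal_wallis matches hand rank arithmetic and the rank oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # R1 = 6, R2 = 15, N = 6: H = 12/42 * (12 + 75) - 21 = 27/7
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 1L)

  same <- kruskal_wallis(rep(c(7, 7, 7), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), ">= 2 groups")

  set.seed(21)
  for (i in 1:100) {
    n <- sample(12:40, 1)
    vals <- sample(1:8, n, replace = TRUE) # heavy ties
    grp <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(grp)) < 2 || length(unique(vals)) == 1) next
    expect_equal(kruskal_wallis(vals, grp)$H, kw_oracle(vals, grp),
                 tolerance = 1e-10)
  }
})

test_that("kruskal_wallis p-values are uniform under the null", {
  set.seed(8)
  ps <- replicate(2000, {
    kruskal_wallis(stats::rnorm(30), rep(letters[1:3], each = 10))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("trait correlation has the affine and degenerate properties", {
  set.seed(5)
  x <- stats::rnorm(40)
  m <- cbind(a = x, b = -x, c = 2 * x + 3, d = stats::rnorm(40))
  cc <- trait_correlation(m)
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_equal(unname(cc["a", "b"]), -1)
  expect_equal(unname(cc["a", "c"]), 1)
  expect_equal(cc, t(cc))
  expect_true(all(abs(cc) <= 1 + 1e-12))
  m2 <- cbind(m, e = rep(4, 40))
  expect_warning(cc2 <- trait_correlation(m2), "constant")
  expect_true(all(is.na(cc2["e", setdiff(colnames(m2), "e")])))
})

test_that("PCA recovers rank-1 structure and matches the SVD oracle", {
  set.seed(6)
  r1 <- outer(stats::rnorm(20), stats::rnorm(8))
  pc <- trait_pca(r1, scale. = FALSE)
  expect_equal(pc$variance_fractions[1], 1, tolerance = 1e-9)

  x <- matrix(stats::rnorm(20 * 16), 20, 16)
  pc2 <- trait_pca(x, scale. = TRUE)
  xs <- scale(x, center = TRUE, scale = TRUE)
  sv <- svd(xs)
  expect_equal(pc2$variance_fractions, sv$d^2 / sum(sv$d^2), tolerance = 1e-9)
  expect_equal(abs(pc2$loadings), abs(sv$v), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction of the standardized data
  rec <- pc2$scores %*% t(pc2$loadings)
  expect_equal(rec, unclass(xs), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PCA flags sparsity and imputes flagged means", {
  x <- matrix(stats::rnorm(100), 10, 10)
  x[1:6, 1:6] <- NA
  expect_error(trait_pca(x, max_missing = 0.2), "too-sparse")
  x2 <- matrix(stats::rnorm(100), 10, 10)
  x2[1, 1] <- NA
  pc <- trait_pca(x2)
  expect_equal(pc$imputed_cells, 1L)
})

test_that("variance partition attributes constructed signals to their factors", {
  design <- expand.grid(year = 1:2, daylength = 1:2, position = 1:3,
                        genotype = 1:5)
  set.seed(9)
  # pure position signal
  y_pos <- c(0, 5, 12)[design$position] + stats::rnorm(nrow(design), 0, 1e-3)
  vp <- variance_partition(y_pos, design)
  expect_gt(vp$fractions[["position"]], 0.99)
  expect_lt(sum(vp$fractions[setdiff(names(vp$fractions),
                                     c("position", "residual"))]), 0.01)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-12)

  # genotype x position interaction dominates
  inter <- matrix(stats::rnorm(15, 0, 4), 5, 3)
  y_int <- inter[cbind(design$genotype, design$position)] +
    stats::rnorm(nrow(design), 0, 0.3)
  vp2 <- variance_partition(y_int, design)
  expect_equal(names(which.max(vp2$fractions[names(vp2$fractions) != "residual"])),
               "genotype:position")
})

test_that("variance partition matches df/(n-1) expectations under pure noise", {
  design <- expand.grid(year = 1:2, daylength = 1:2, position = 1:3,
                        genotype = 1:5)
  n <- nrow(design)
  set.seed(10)
  fr <- replicate(200, variance_partition(stats::rnorm(n), design)$fractions)
  means <- rowMeans(fr)
  dfs <- c(year = 1, daylength = 1, position = 2, genotype = 4,
           `genotype:year` = 4, `genotype:position` = 8)
  for (term in names(dfs)) {
    expect_lt(abs(means[[term]] - dfs[[term]] / (n - 1)), 0.012)
  }
})

test_that("aliased designs raise an explicit error", {
  design <- data.frame(year = rep(1:2, each = 6),
                       genotype = rep(1:2, each = 6)) # fully confounded
  expect_error(variance_partition(stats::rnorm(12), design), "aliasing")
})

test_that("kruskal_report produces a tidy adjusted table", {
  traits <- make_factorial_traits(8)
  set.seed(12)
  for (p in trait_names()) traits[[p]] <- stats::rnorm(nrow(traits))
  rep_ <- kruskal_report(traits, group_var = "daylength_h")
  expect_equal(nrow(rep_), 16L * 3L)
  expect_true(all(c("test", "trait", "position", "H", "df", "p", "p_adj") %in%
                    names(rep_)))
  expect_true(all(rep_$p_adj >= rep_$p - 1e-12, na.rm = TRUE))
})
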