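#' Idealized landmark template for a leaf position
#'
#' Returns a 21 x 2 landmark prototype for an apical, middle or basal leaf of
#' an idealized non-lobed grapevine leaf, in cm, with the leaf base near the
#' origin and the tip (landmark 21) on the positive y axis. The three vein
#' systems (proximal, distal, middle) fan out to the margin landmarks; the
#' petiolar vein branches off the proximal vein toward the petiolar sinus.
#' Apical leaves are smaller with relatively wider veins, basal leaves larger
#' with relatively narrower veins, mirroring the allometry of heteroblastic
#' shoots. Template coordinates are synthetic fixtures, not measurements.
#'
#' @param position `"apical"`, `"middle"` or `"basal"`.
#' @return 21 x 2 numeric matrix (rows = landmark indices 1..21).
#' @export
leaf_template <- function(position = c("middle", "apical", "basal")) {
  position <- match.arg(position)
  s <- switch(position, apical = 0.65, middle = 1, basal = 1.2)
  w <- switch(position, apical = 1.3, middle = 1, basal = 0.9)

  # base landmarks 1..4 across the vein bases; width factor spreads them
  base <- rbind(c(-0.36, -0.12), c(-0.18, -0.04), c(-0.05, 0.00), c(0.12, 0.00))
  base[, 1] <- mean(base[, 1]) + w * (base[, 1] - mean(base[, 1]))

  # proximal-vein / petiolar-vein junction and its flanking landmarks 5..7
  pj <- c(-1.016, 0.036)
  p5 <- pj + c(w * -0.164, -0.076)
  p6 <- pj + c(w * 0.166, -0.156)
  p7 <- pj + c(w * 0.016, 0.124)

  # distal-vein branch junction, landmarks 8..10
  dj <- c(-1.413, 2.689)
  p8 <- dj + c(w * -0.147, 0.131)
  p9 <- dj + c(w * 0.063, -0.269)
  p10 <- dj + c(w * 0.083, 0.131)

  # midvein branch region, landmarks 11..13 (x offsets scale with width)
  p11 <- c(w * -0.0304, 7.25)
  p12 <- c(w * -0.0358, 6.80)
  p13 <- c(w * 0.0320, 7.00)

  margin <- rbind(c(-1.10, -1.50), c(-4.00, 0.50), c(-3.10, 2.00),
                  c(-3.70, 3.90), c(-3.00, 6.00), c(-1.90, 6.60),
                  c(-1.30, 8.20), c(0.00, 10.00))

  pts <- rbind(base, p5, p6, p7, p8, p9, p10, p11, p12, p13, margin)
  dimnames(pts) <- list(NULL, c("x", "y"))
  pts * s
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators: population and map
#' dimensions, planted QTL, and the leaf-generation effect sizes. Defaults
#' emulate the study design the analysis layer expects: 135 genotypes, a
#' 19-linkage-group map of ~50 markers per group, three leaf positions, two
#' photoperiods (14 h and 13 h) and two years.
#'
#' @param n_genotypes Number of F1 individuals (default 135).
#' @param n_lgs Number of linkage groups (default 19).
#' @param markers_per_lg Markers per linkage group (default 50).
#' @param lg_length_cM Length of each linkage group in cM (default 92, so the
#'   default genome spans ~1750 cM at ~1.9 cM spacing).
#' @param bp_per_cM Physical scale used to synthesize marker names
#'   `rh<lg>_<bp>` (default 1e5).
#' @param qtl Data frame of planted QTL with columns `marker`, `a` (additive
#'   effect), `d` (dominance effect), `pve` (target fraction in (0, 0.95)),
#'   `trait` (affected phenotype: `"size"` or `"shape"`); may be `NULL`.
#' @param daylengths,years,positions Factor levels of the leaf design.
#' @param daylength_effect Log-scale leaf size effect of 13 h vs 14 h.
#' @param year_effect Log-scale leaf size effect of the second year.
#' @param scale_sd SD of the individual log-scale size noise.
#' @param landmark_sd SD (cm) of independent landmark jitter.
#' @param seed Mandatory RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 135, n_lgs = 19, markers_per_lg = 50,
                       lg_length_cM = 92, bp_per_cM = 1e5, qtl = NULL,
                       daylengths = c(14L, 13L), years = c(2021L, 2022L),
                       positions = c("apical", "middle", "basal"),
                       daylength_effect = -0.08, year_effect = 0.05,
                       scale_sd = 0.08, landmark_sd = 0.02, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("config error: seed is mandatory for simulation", call. = FALSE)
  }
  if (n_genotypes < 2) stop("config error: n_genotypes must be >= 2", call. = FALSE)
  if (markers_per_lg < 1 || n_lgs < 1) {
    stop("config error: marker and linkage group counts must be positive",
         call. = FALSE)
  }
  if (!is.null(qtl)) {
    stopifnot(is.data.frame(qtl),
              all(c("marker", "a", "d", "pve", "trait") %in% names(qtl)))
    if (any(qtl$pve <= 0 | qtl$pve >= 0.95)) {
      stop("config error: target PVE must be in (0, 0.95)", call. = FALSE)
    }
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_lgs = as.integer(n_lgs),
                 markers_per_lg = as.integer(markers_per_lg),
                 lg_length_cM = lg_length_cM, bp_per_cM = bp_per_cM, qtl = qtl,
                 daylengths = as.integer(daylengths), years = as.integer(years),
                 positions = positions, daylength_effect = daylength_effect,
                 year_effect = year_effect, scale_sd = scale_sd,
                 landmark_sd = landmark_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate position-structured leaves for a genotyped population
#'
#' Generates one leaf per genotype x position x daylength x year cell. Each
#' leaf is the position template scaled by
#' `exp(genotype size effect + daylength effect + year effect + noise)`,
#' optionally stretched anisotropically along x by planted shape QTL, plus
#' independent Gaussian landmark jitter. Genotype effects come from the
#' planted QTL in `cfg$qtl`: for a QTL with target PVE p the additive effect
#' is `sqrt(2 p / (1 - p)) * scale_sd`, so the marker explains about p of the
#' within-cell log-scale variance.
#'
#' @param cfg A [sim_config()].
#' @param cross An `abh_cross` from [simulate_genotypes()] (its individuals
#'   become the genotypes).
#' @return A `landmark_df` with one row per simulated leaf and attribute
#'   `"manifest"` recording seed and config hash.
#' @export
simulate_leaves <- function(cfg, cross) {
  stopifnot(inherits(cfg, "sim_config"), inherits(cross, "abh_cross"))
  templates <- lapply(stats::setNames(nm = cfg$positions), leaf_template)
  for (tp in templates) {
    if (nrow(tp) != 21L) stop("config error: template must have 21 points", call. = FALSE)
  }
  ids <- rownames(cross$geno)
  set.seed(.child_seed(cfg$seed, 7L))

  size_eff <- rep(0, length(ids))
  shape_eff <- rep(0, length(ids))
  if (!is.null(cfg$qtl)) {
    for (k in seq_len(nrow(cfg$qtl))) {
      q <- cfg$qtl[k, ]
      g <- geno_numeric(cross)[, q$marker]
      scoef <- g - 1 # additive score in {-1, 0, +1}
      eff <- sqrt(2 * q$pve / (1 - q$pve)) * cfg$scale_sd * scoef
      if (identical(q$trait, "shape")) shape_eff <- shape_eff + eff
      else size_eff <- size_eff + eff
    }
  }

  design <- expand.grid(genotype = seq_along(ids), position = cfg$positions,
                        daylength_h = cfg$daylengths, year = cfg$years,
                        stringsAsFactors = FALSE)
  n <- nrow(design)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gi <- design$genotype[i]
    tp <- templates[[design$position[i]]]
    log_scale <- size_eff[gi] +
      cfg$daylength_effect * (design$daylength_h[i] == 13L) +
      cfg$year_effect * (design$year[i] != cfg$years[1L]) +
      stats::rnorm(1, 0, cfg$scale_sd)
    pts <- tp * exp(log_scale)
    pts[, 1] <- pts[, 1] * exp(shape_eff[gi])
    pts <- pts + matrix(stats::rnorm(42L, 0, cfg$landmark_sd), ncol = 2)
    rows[[i]] <- data.frame(
      leaf_id = sprintf("%s_%s_%dh_%d", ids[gi], design$position[i],
                        design$daylength_h[i], design$year[i]),
      genotype_id = ids[gi], presentation = "own_rooted",
      position = design$position[i], daylength_h = design$daylength_h[i],
      year = design$year[i],
      t(as.vector(t(pts))), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- c(.landmark_meta_cols, .landmark_coord_cols())
  out <- as_landmark_df(out)
  attr(out, "manifest") <- list(seed = cfg$seed, config_hash = .config_hash(cfg))
  out
}
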