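#' Default scan configuration
#'
#' @param alpha Genome-wide significance level (default 0.05).
#' @param n_perm Permutations for the threshold (default 1000).
#' @param seed Mandatory base seed; each attribute derives a child seed.
#' @param min_n Minimum phenotyped individuals per attribute (default 30).
#' @param sw_alpha Shapiro-Wilk gate for the normality ladder.
#' @param coverage Bayes credible interval coverage.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(alpha = 0.05, n_perm = 1000L, seed, min_n = 30L,
                        sw_alpha = 0.05, coverage = 0.95) {
  if (missing(seed) || is.null(seed)) {
    stop("config error: seed is mandatory for scans", call. = FALSE)
  }
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), min_n = as.integer(min_n),
                 sw_alpha = sw_alpha, coverage = coverage),
            class = "scan_config")
}

#' Normality-gated genome scan over all trait-matrix attributes
#'
#' For every attribute column with at least `min_n` phenotyped individuals:
#' run the transformation ladder ([normalize_trait()]), scan with the
#' parametric marker regression or, when the ladder fails, the rank-based
#' scan; compute the genome-wide permutation threshold at `alpha`; and
#' report at most one peak per linkage group (the maximal LOD at or above
#' the threshold) with percent variance explained and the 95% Bayes credible
#' interval. Attributes with too few values are skipped and logged. The
#' whole run is deterministic given `config$seed`.
#'
#' @param tm A `trait_matrix`.
#' @param cross An `abh_cross`; its individual ids must cover the matrix
#'   genotypes.
#' @param config A [scan_config()].
#' @return Data frame of QTL peaks (one row per trait x linkage group peak)
#'   with columns `trait`, `phenotype`, `position`, `daylength_h`, `year`,
#'   `presentation`, `method`, `n`, `threshold`, `linkage_group`,
#'   `peak_marker`, `peak_cM`, `lod`, `pve`, `ci_low`, `ci_high`.
#'   Attributes: `skipped` (log of skipped attributes), `provenance`.
#' @export
scan_qtl <- function(tm, cross, config) {
  stopifnot(inherits(tm, "trait_matrix"), inherits(cross, "abh_cross"),
            inherits(config, "scan_config"))
  ids <- rownames(cross$geno)
  orphans <- setdiff(unique(tm$genotype), ids)
  if (length(orphans)) {
    stop("reconciliation error: matrix genotypes missing from cross: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  peaks <- list()
  skipped <- list()
  map <- cross$map
  for (j in seq_len(ncol(tm$values))) {
    key <- colnames(tm$values)[j]
    att <- tm$attributes[j, ]
    for (pres in unique(tm$presentation)) {
      ri <- tm$presentation == pres
      y <- stats::setNames(tm$values[ri, j], tm$genotype[ri])
      y <- y[!is.na(y)]
      tag <- paste0(key, "/", pres)
      if (length(y) < config$min_n) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(trait = key, presentation = pres,
                     reason = sprintf("n=%d < min_n=%d", length(y), config$min_n))
        next
      }
      norm <- normalize_trait(y, sw_alpha = config$sw_alpha)
      method <- if (norm$method == "nonparametric") "nonparametric" else "parametric"
      yv <- stats::setNames(norm$values, names(y))
      seed_j <- .child_seed(config$seed, j * 7L + match(pres, unique(tm$presentation)))
      scan <- if (method == "parametric") {
        scan_parametric(cross, yv, min_n = config$min_n)
      } else {
        scan_nonparametric(cross, yv, min_n = config$min_n)
      }
      thr <- permutation_threshold(cross, yv, method, n_perm = config$n_perm,
                                   alpha = config$alpha, seed = seed_j,
                                   min_n = config$min_n)
      for (lg in unique(map$linkage_group)) {
        sel <- scan$linkage_group == lg
        if (sum(sel) < 3L) next
        lods <- scan$lod[sel]
        imax <- which.max(lods)
        if (lods[imax] < as.numeric(thr)) next
        ci <- bayes_interval(lods, scan$cM[sel], coverage = config$coverage)
        peaks[[length(peaks) + 1L]] <- data.frame(
          trait = key, phenotype = att$phenotype, position = att$position,
          daylength_h = att$daylength_h, year = att$year,
          presentation = pres, method = method,
          transform = norm$method, n = attr(scan, "n"),
          threshold = as.numeric(thr), linkage_group = lg,
          peak_marker = scan$marker[sel][imax], peak_cM = scan$cM[sel][imax],
          lod = lods[imax], pve = pve(lods[imax], attr(scan, "n")),
          ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
          seed = seed_j, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else .empty_peaks()
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(trait = character(0), presentation = character(0),
               reason = character(0))
  attr(out, "provenance") <- list(seed = config$seed, n_perm = config$n_perm,
                                  alpha = config$alpha,
                                  version = as.character(utils::packageVersion("ampelomap")))
  out
}

.empty_peaks <- function() {
  data.frame(trait = character(0), phenotype = character(0),
             position = character(0), daylength_h = integer(0),
             year = integer(0), presentation = character(0),
             method = character(0), transform = character(0), n = integer(0),
             threshold = numeric(0), linkage_group = integer(0),
             peak_marker = character(0), peak_cM = numeric(0),
             lod = numeric(0), pve = numeric(0), ci_low = numeric(0),
             ci_high = numeric(0), seed = integer(0), stringsAsFactors = FALSE)
}

#' Write / read the QTL peak report
#'
#' CSV mirroring the published QTL table layout (year, daylength, trait,
#' position, LOD, peak position and marker, percent variance explained,
#' credible interval, method), with a provenance header recording seed,
#' permutation count, alpha and package version.
#'
#' @param peaks Data frame from [scan_qtl()].
#' @param path CSV path.
#' @export
write_qtl_report <- function(peaks, path) {
  prov <- attr(peaks, "provenance")
  .write_csv_provenance(peaks, path, c(
    seed = as.character(prov$seed %||% NA),
    n_perm = as.character(prov$n_perm %||% NA),
    alpha = as.character(prov$alpha %||% NA)))
}

#' @rdname write_qtl_report
#' @export
read_qtl_report <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
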