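#' Parse physical positions from rhAmpSeq-style marker names
#'
#' Marker names follow the convention `rh<chromosome>_<bp>` (e.g.
#' `rh19_472320`). A sidecar physical-position table can override this when
#' names differ.
#'
#' @param name Character vector of marker names.
#' @return Data frame with `chromosome` and `bp` (integers, bp >= 1).
#' @export
parse_marker_name <- function(name) {
  m <- regmatches(name, regexec("^rh([0-9]+)_([0-9]+)$", name))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("parse error: malformed marker name(s): ",
         paste(utils::head(name[bad], 5), collapse = ", "), call. = FALSE)
  }
  chr <- vapply(m, function(x) as.integer(x[2]), integer(1))
  bp <- vapply(m, function(x) as.integer(x[3]), integer(1))
  if (any(bp < 1L)) {
    stop("parse error: bp must be >= 1 (", paste(name[bp < 1L], collapse = ", "),
         ")", call. = FALSE)
  }
  data.frame(chromosome = chr, bp = bp, stringsAsFactors = FALSE)
}

.abh_calls <- c("A", "B", "H")

.validate_map <- function(map) {
  stopifnot(all(c("marker", "linkage_group", "cM") %in% names(map)))
  map$marker <- as.character(map$marker)
  map$linkage_group <- as.integer(map$linkage_group)
  map$cM <- as.numeric(map$cM)
  if (anyDuplicated(map$marker)) {
    stop("duplicate marker names in map", call. = FALSE)
  }
  if (length(unique(map$linkage_group)) > 19L) {
    stop("more than 19 linkage groups", call. = FALSE)
  }
  map <- map[order(map$linkage_group, map$cM), , drop = FALSE]
  if (!all(c("chromosome", "bp") %in% names(map))) {
    parsed <- tryCatch(parse_marker_name(map$marker), error = function(e) NULL)
    if (is.null(parsed)) {
      map$chromosome <- NA_integer_
      map$bp <- NA_integer_
    } else {
      map$chromosome <- parsed$chromosome
      map$bp <- parsed$bp
    }
  }
  rownames(map) <- NULL
  map
}

#' Construct an ABH cross object
#'
#' @param geno Character matrix of calls in `{A, B, H, NA}`, individuals x
#'   markers, with individual ids as row names and marker names as column
#'   names.
#' @param map Data frame with `marker`, `linkage_group`, `cM` and optionally
#'   `chromosome`, `bp` (parsed from marker names when absent).
#' @return Object of class `abh_cross`.
#' @export
abh_cross <- function(geno, map) {
  map <- .validate_map(map)
  geno <- as.matrix(geno)
  if (!setequal(colnames(geno), map$marker)) {
    orphans <- c(setdiff(colnames(geno), map$marker),
                 setdiff(map$marker, colnames(geno)))
    stop("reconciliation error: genotype/map marker mismatch: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  geno <- geno[, map$marker, drop = FALSE]
  ok <- geno %in% .abh_calls | is.na(geno)
  if (!all(ok)) {
    idx <- which(!matrix(ok, nrow(geno)), arr.ind = TRUE)[1, ]
    stop("format error: invalid call '", geno[idx[1], idx[2]],
         "' at individual ", rownames(geno)[idx[1]], ", marker ",
         colnames(geno)[idx[2]], call. = FALSE)
  }
  structure(list(geno = geno, map = map), class = "abh_cross")
}

#' @export
print.abh_cross <- function(x, ...) {
  cat(sprintf("abh_cross: %d individuals x %d markers on %d linkage groups; %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$linkage_group)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Read ABH genotypes in the R/qtl CSV dialect
#'
#' Row 1 holds `id` plus marker names, row 2 the linkage group of each
#' marker, row 3 its cM position, then one row per individual. Calls are
#' `A`/`B`/`H`; `-`, `NA` or empty cells are missing. A separate map CSV
#' (`marker, linkage_group, cM[, chromosome, bp]`) overrides the in-file map
#' and the name-derived physical positions.
#'
#' @param geno_file Genotype CSV path.
#' @param map_file Optional map CSV path.
#' @return An [abh_cross()].
#' @export
read_abh <- function(geno_file, map_file = NULL) {
  raw <- utils::read.csv(geno_file, header = FALSE, colClasses = "character",
                         comment.char = "#")
  if (nrow(raw) < 4L || ncol(raw) < 2L) {
    stop("format error: ABH file needs 3 header rows and >= 1 individual",
         call. = FALSE)
  }
  markers <- as.character(raw[1, -1])
  map <- data.frame(marker = markers,
                    linkage_group = as.integer(raw[2, -1]),
                    cM = as.numeric(raw[3, -1]), stringsAsFactors = FALSE)
  geno <- as.matrix(raw[-(1:3), -1, drop = FALSE])
  geno[geno %in% c("-", "", "NA", "U")] <- NA_character_
  rownames(geno) <- as.character(raw[-(1:3), 1])
  colnames(geno) <- markers
  if (!is.null(map_file)) {
    map <- utils::read.csv(map_file, comment.char = "#",
                           stringsAsFactors = FALSE)
  }
  abh_cross(geno, map)
}

#' Write an ABH cross in the R/qtl CSV dialect
#'
#' @param cross An `abh_cross`.
#' @param geno_file Output genotype CSV path.
#' @param map_file Optional output path for the map-only CSV.
#' @export
write_abh <- function(cross, geno_file, map_file = NULL) {
  stopifnot(inherits(cross, "abh_cross"))
  g <- cross$geno
  g[is.na(g)] <- "-"
  header <- rbind(c("id", cross$map$marker),
                  c("", cross$map$linkage_group),
                  c("", cross$map$cM))
  body <- cbind(rownames(g), g)
  utils::write.table(rbind(header, body), geno_file, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(map_file)) {
    utils::write.csv(cross$map, map_file, row.names = FALSE)
  }
  invisible(geno_file)
}

#' Genetic map summary statistics
#'
#' Per linkage group: marker count, spanned length (max - min cM) and the
#' largest adjacent-marker gap; overall: total markers, total length, mean
#' inter-marker spacing `total length / (markers - linkage groups)`, the
#' genome-wide maximum gap, an approximate recombination rate (total cM over
#' total spanned Mbp from the parsed physical positions) and, when the
#' number of genotyped markers is supplied, the percentage anchored.
#' Linkage groups with fewer than 2 markers are excluded from spacing and
#' gap statistics with a warning.
#'
#' @param map Map data frame (see [abh_cross()]).
#' @param n_genotyped Optional total number of genotyped markers.
#' @return List of class `map_summary` with `per_lg` (data frame) and the
#'   totals.
#' @export
map_summary <- function(map, n_genotyped = NULL) {
  map <- .validate_map(map)
  lgs <- split(map, map$linkage_group)
  small <- names(lgs)[vapply(lgs, nrow, integer(1)) < 2L]
  if (length(small)) {
    warning("linkage group(s) with < 2 markers excluded from spacing: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  per_lg <- do.call(rbind, lapply(lgs, function(m) {
    data.frame(linkage_group = m$linkage_group[1], n_markers = nrow(m),
               length_cM = if (nrow(m) >= 2L) max(m$cM) - min(m$cM) else NA_real_,
               max_gap_cM = if (nrow(m) >= 2L) max(diff(sort(m$cM))) else NA_real_)
  }))
  rownames(per_lg) <- NULL
  usable <- per_lg[!is.na(per_lg$length_cM), , drop = FALSE]
  total_len <- sum(usable$length_cM)
  n_usable_markers <- sum(usable$n_markers)
  mbp <- sum(vapply(lgs, function(m) {
    if (all(is.na(m$bp)) || nrow(m) < 2L) return(0)
    (max(m$bp, na.rm = TRUE) - min(m$bp, na.rm = TRUE)) / 1e6
  }, numeric(1)))
  res <- list(
    per_lg = per_lg, n_markers = nrow(map),
    n_lg = length(lgs), total_length_cM = total_len,
    mean_spacing_cM = total_len / (n_usable_markers - nrow(usable)),
    max_gap_cM = if (nrow(usable)) max(usable$max_gap_cM) else NA_real_,
    recomb_rate_cM_per_Mbp = if (mbp > 0) total_len / mbp else NA_real_,
    recomb_rate_note = "approximate: total map cM over total spanned Mbp",
    anchored_pct = if (!is.null(n_genotyped)) 100 * nrow(map) / n_genotyped)
  structure(res, class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("map_summary: %d markers on %d LGs, %.1f cM total, mean spacing %.2f cM, max gap %.1f cM\n",
              x$n_markers, x$n_lg, x$total_length_cM, x$mean_spacing_cM,
              x$max_gap_cM))
  if (!is.null(x$anchored_pct)) cat(sprintf("  anchored: %.1f%%\n", x$anchored_pct))
  if (!is.na(x$recomb_rate_cM_per_Mbp)) {
    cat(sprintf("  recombination rate: %.2f cM/Mbp (%s)\n",
                x$recomb_rate_cM_per_Mbp, x$recomb_rate_note))
  }
  invisible(x)
}

#' Map-vs-genome collinearity per linkage group
#'
#' Spearman rank correlation between genetic (cM) and physical (bp) order
#' within each linkage group; groups with fewer than 3 physically anchored
#' markers are reported as `NA`.
#'
#' @param map Map data frame with parsed `bp`.
#' @return Data frame with `linkage_group`, `n`, `rho`.
#' @export
map_collinearity <- function(map) {
  map <- .validate_map(map)
  res <- lapply(split(map, map$linkage_group), function(m) {
    m <- m[!is.na(m$bp), , drop = FALSE]
    rho <- if (nrow(m) >= 3L) {
      suppressWarnings(stats::cor(m$cM, m$bp, method = "spearman"))
    } else NA_real_
    data.frame(linkage_group = m$linkage_group[1] %||% NA_integer_,
               n = nrow(m), rho = rho)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Numeric genotype codes
#'
#' @param cross An `abh_cross`.
#' @return Integer matrix with A = 0, H = 1, B = 2, missing `NA`.
#' @export
geno_numeric <- function(cross) {
  matrix(match(cross$geno, c("A", "H", "B")) - 1L, nrow(cross$geno),
         dimnames = dimnames(cross$geno))
}

#' Pairwise recombination fraction by expectation-maximization
#'
#' Maximum-likelihood recombination fraction between two intercross-coded
#' loci from the 3 x 3 joint genotype table. The only latent class is the
#' double heterozygote (parental vs double-recombinant gamete pair); EM
#' iterates the expected recombinant-gamete count. Both phase orientations
#' are fit and the one with the higher likelihood is kept, so repulsion-coded
#' pairs still yield rf in [0, 0.5].
#'
#' @param cross An `abh_cross` (or numeric 0/1/2 genotype matrix).
#' @param m1,m2 Marker names or column indices.
#' @param min_n Minimum complete pairs required (default 20).
#' @param tol,maxit EM convergence controls.
#' @return Estimated rf in `[0, 0.5]`, or `NA` with a warning when too few
#'   complete pairs exist.
#' @export
recombination_fraction <- function(cross, m1, m2, min_n = 20L, tol = 1e-10,
                                   maxit = 200L) {
  g <- if (inherits(cross, "abh_cross")) geno_numeric(cross) else as.matrix(cross)
  g1 <- g[, m1]
  g2 <- g[, m2]
  keep <- !is.na(g1) & !is.na(g2)
  if (sum(keep) < min_n) {
    warning("recombination_fraction: fewer than ", min_n,
            " complete pairs; returning NA", call. = FALSE)
    return(NA_real_)
  }
  tab <- table(factor(g1[keep], levels = 0:2), factor(g2[keep], levels = 0:2))
  em <- function(N) {
    # recombinant gametes contributed by each unambiguous cell
    R <- matrix(c(0, 1, 2, 1, NA, 1, 2, 1, 0), 3, 3, byrow = TRUE)
    r <- 0.25
    n2 <- 2 * sum(N)
    for (it in seq_len(maxit)) {
      r_hh <- 2 * r^2 / ((1 - r)^2 + r^2)
      exp_rec <- sum(N * ifelse(is.na(R), r_hh, R))
      r_new <- min(max(exp_rec / n2, 1e-9), 0.5)
      if (abs(r_new - r) < tol) { r <- r_new; break }
      r <- r_new
    }
    P <- matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
                  2 * r * (1 - r), 2 * ((1 - r)^2 + r^2), 2 * r * (1 - r),
                  r^2, 2 * r * (1 - r), (1 - r)^2) / 4, 3, 3, byrow = TRUE)
    list(r = r, ll = sum(N[N > 0] * log(P[N > 0])))
  }
  fit1 <- em(tab)
  fit2 <- em(tab[3:1, ]) # swapped coding at locus 1 (repulsion phase)
  if (fit2$ll > fit1$ll) fit2$r else fit1$r
}
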