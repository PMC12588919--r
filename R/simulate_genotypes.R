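#' Simulate an evenly spaced genetic map
#'
#' Markers are placed uniformly along each linkage group and named
#' `rh<lg>_<bp>` with `bp = round(cM * bp_per_cM) + 1`, keeping the physical
#' parsing and gene-window machinery exercisable without a real physical
#' map.
#'
#' @param n_lgs Number of linkage groups.
#' @param markers_per_lg Markers per linkage group (scalar or vector).
#' @param lg_length_cM Linkage group length(s) in cM.
#' @param bp_per_cM Physical bp per cM used for marker names.
#' @return Map data frame (`marker`, `linkage_group`, `cM`, `chromosome`,
#'   `bp`).
#' @export
simulate_map <- function(n_lgs = 19, markers_per_lg = 50, lg_length_cM = 92,
                         bp_per_cM = 1e5) {
  if (any(markers_per_lg < 1)) stop("config error: nonpositive marker count", call. = FALSE)
  mk <- rep_len(as.integer(markers_per_lg), n_lgs)
  len <- rep_len(lg_length_cM, n_lgs)
  map <- do.call(rbind, lapply(seq_len(n_lgs), function(lg) {
    cm <- if (mk[lg] == 1L) 0 else seq(0, len[lg], length.out = mk[lg])
    bp <- as.integer(round(cm * bp_per_cM)) + 1L
    data.frame(marker = sprintf("rh%d_%d", lg, bp), linkage_group = lg,
               cM = cm, chromosome = lg, bp = bp, stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL
  map
}

#' Simulate ABH genotypes for an F1 intercross population
#'
#' Each individual inherits two independent gametes per linkage group; a
#' gamete starts from a fair allele draw and recombines between adjacent
#' markers with Haldane probability `(1 - exp(-2 d / 100)) / 2` for map
#' distance `d` cM. Summed allele doses are coded A/H/B with expected 1:2:1
#' frequencies, matching the intercross coding used by the analysis layer.
#'
#' @param n_individuals Number of individuals.
#' @param map Map data frame (e.g. [simulate_map()]).
#' @param seed Mandatory RNG seed.
#' @return An [abh_cross()] with individuals `ind_001, ...`.
#' @export
simulate_genotypes <- function(n_individuals, map, seed) {
  if (missing(seed) || is.null(seed)) stop("config error: seed required", call. = FALSE)
  if (n_individuals < 2) stop("config error: n_individuals must be >= 2", call. = FALSE)
  map <- .validate_map(map)
  set.seed(as.integer(seed))
  n <- as.integer(n_individuals)
  gam <- function(k, rf) {
    # n x k matrix of 0/1 alleles with switch probability rf between columns
    a <- matrix(0L, n, k)
    a[, 1] <- stats::rbinom(n, 1L, 0.5)
    for (j in seq_len(k - 1L)) {
      a[, j + 1L] <- a[, j] != (stats::runif(n) < rf[j])
    }
    a
  }
  geno <- do.call(cbind, lapply(split(map, map$linkage_group), function(m) {
    k <- nrow(m)
    rf <- if (k > 1L) (1 - exp(-2 * diff(m$cM) / 100)) / 2 else numeric(0)
    dose <- gam(k, rf) + gam(k, rf)
    calls <- matrix(.abh_calls[c(1L, 3L, 2L)][dose + 1L], n, k)
    colnames(calls) <- m$marker
    calls
  }))
  rownames(geno) <- sprintf("ind_%03d", seq_len(n))
  abh_cross(geno, map)
}

#' Simulate a phenotype with a planted QTL
#'
#' `y = mu + a * s(g) + d * h(g) + e` with additive score `s` in
#' `{-1, 0, +1}`, heterozygote indicator `h`, and Gaussian residual whose SD
#' is solved so the expected QTL variance fraction equals the target:
#' `sigma^2 = V_g (1 - pve) / pve` with `V_g = a^2/2 + d^2/4` under 1:2:1
#' genotype frequencies. With `a = d = 0` (or no marker) the phenotype is
#' pure standard-normal noise.
#'
#' @param cross An `abh_cross`.
#' @param marker Marker name carrying the QTL (`NULL` for a null trait).
#' @param a,d Additive and dominance effects.
#' @param pve Target fraction of variance explained, in (0, 0.95).
#' @param mu Intercept.
#' @param seed Mandatory RNG seed.
#' @return Named numeric vector (names = individual ids); attributes record
#'   the solved residual SD.
#' @export
simulate_phenotype <- function(cross, marker = NULL, a = 1, d = 0, pve = 0.1,
                               mu = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("config error: seed required", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- rownames(cross$geno)
  n <- length(ids)
  if (is.null(marker) || (a == 0 && d == 0)) {
    y <- mu + stats::rnorm(n)
    names(y) <- ids
    attr(y, "residual_sd") <- 1
    return(y)
  }
  if (!marker %in% colnames(cross$geno)) {
    stop("config error: QTL marker '", marker, "' not in cross", call. = FALSE)
  }
  if (is.null(pve) || pve <= 0 || pve >= 0.95) {
    stop("config error: unattainable PVE (need 0 < pve < 0.95)", call. = FALSE)
  }
  g <- geno_numeric(cross)[, marker]
  s <- g - 1L
  h <- as.integer(g == 1L)
  vg <- a^2 / 2 + d^2 / 4
  sigma <- sqrt(vg * (1 - pve) / pve)
  y <- mu + a * s + d * h + stats::rnorm(n, 0, sigma)
  # individuals with missing genotype at the QTL get the population mean + noise
  y[is.na(y)] <- mu + stats::rnorm(sum(is.na(y)), 0, sigma)
  names(y) <- ids
  attr(y, "residual_sd") <- sigma
  y
}

#' Simulate a gene table and pathway annotation
#'
#' Uniformly placed genes along each chromosome plus random pathway
#' membership, for exercising hotspot gene windows and enrichment. Both are
#' synthetic stand-ins for a genome annotation, not derived from any real
#' assembly.
#'
#' @param n_genes Total genes.
#' @param chromosomes Chromosome ids.
#' @param chr_length_bp Chromosome length in bp.
#' @param n_pathways Number of pathways.
#' @param mean_pathway_size Expected genes per pathway.
#' @param seed Mandatory RNG seed.
#' @return List with `genes` (`gene_id`, `chromosome`, `bp`) and
#'   `annotation` (`gene_id`, `pathway_id`).
#' @export
simulate_gene_annotation <- function(n_genes = 2000, chromosomes = 1:19,
                                     chr_length_bp = 1e7, n_pathways = 40,
                                     mean_pathway_size = 50, seed) {
  if (missing(seed) || is.null(seed)) stop("config error: seed required", call. = FALSE)
  set.seed(as.integer(seed))
  chr <- sort(rep_len(chromosomes, n_genes))
  bp <- unlist(lapply(split(chr, chr), function(x) {
    sort(sample.int(chr_length_bp, length(x)))
  }), use.names = FALSE)
  genes <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
                      chromosome = chr, bp = bp, stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(seq_len(n_pathways), function(p) {
    size <- max(2L, stats::rpois(1, mean_pathway_size))
    data.frame(gene_id = sample(genes$gene_id, min(size, n_genes)),
               pathway_id = sprintf("path_%03d", p), stringsAsFactors = FALSE)
  }))
  list(genes = genes, annotation = ann)
}
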