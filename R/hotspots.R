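#' Detect QTL hotspots
#'
#' Groups peaks by identical peak marker and keeps groups of at least
#' `min_qtl` members whose Bayes credible intervals pairwise overlap. For
#' 1-D intervals pairwise overlap is equivalent to sharing a common point,
#' so within each marker group the largest such subset is the set of
#' intervals covering the best-covered point. Hotspots are ordered by
#' chromosome then bp (parsed from the peak marker name).
#'
#' @param peaks QTL peak data frame (needs `trait`, `peak_marker`, `lod`,
#'   `ci_low`, `ci_high`).
#' @param min_qtl Minimum collocated QTL per hotspot (default 3).
#' @return Data frame with one row per hotspot: `peak_marker`, `chromosome`,
#'   `bp`, `n_qtl`, `traits` (semicolon-joined); attribute `members` holds
#'   the member peak rows per hotspot.
#' @export
detect_hotspots <- function(peaks, min_qtl = 3L) {
  empty <- data.frame(peak_marker = character(0), chromosome = integer(0),
                      bp = integer(0), n_qtl = integer(0),
                      traits = character(0), stringsAsFactors = FALSE)
  if (!nrow(peaks)) {
    attr(empty, "members") <- list()
    return(empty)
  }
  out <- list()
  members <- list()
  for (mk in unique(peaks$peak_marker)) {
    grp <- peaks[peaks$peak_marker == mk, , drop = FALSE]
    if (nrow(grp) < min_qtl) next
    # best-covered point: candidate stab points are the interval left ends
    cover <- vapply(grp$ci_low, function(p) {
      sum(grp$ci_low <= p + 1e-9 & grp$ci_high >= p - 1e-9)
    }, integer(1))
    best <- grp$ci_low[which.max(cover)]
    inset <- grp$ci_low <= best + 1e-9 & grp$ci_high >= best - 1e-9
    if (sum(inset) < min_qtl) next
    grp <- grp[inset, , drop = FALSE]
    pos <- parse_marker_name(mk)
    out[[length(out) + 1L]] <- data.frame(
      peak_marker = mk, chromosome = pos$chromosome, bp = pos$bp,
      n_qtl = nrow(grp), traits = paste(grp$trait, collapse = ";"),
      stringsAsFactors = FALSE)
    members[[length(members) + 1L]] <- grp
  }
  if (!length(out)) {
    attr(empty, "members") <- list()
    return(empty)
  }
  res <- do.call(rbind, out)
  ord <- order(res$chromosome, res$bp)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "members") <- members[ord]
  res
}

#' Genes in a physical window around a hotspot peak
#'
#' Returns genes on the hotspot chromosome whose annotated position lies
#' within `window_bp` of the peak (closed interval, so a 700 kb half-width
#' spans 1.4 Mb). Genes are represented by their single annotated position.
#'
#' @param chromosome,bp Hotspot peak position (or pass a 1-row hotspot data
#'   frame as `chromosome`).
#' @param genes Gene table with `gene_id`, `chromosome` and `bp` (or
#'   `bp_start`).
#' @param window_bp Half-width in bp (default 700000).
#' @return Character vector of gene ids (possibly empty, with a warning when
#'   the chromosome has no genes at all).
#' @export
gene_window <- function(chromosome, bp = NULL, genes, window_bp = 700000) {
  if (is.data.frame(chromosome)) {
    bp <- chromosome$bp[1]
    chromosome <- chromosome$chromosome[1]
  }
  if (!"bp" %in% names(genes) && "bp_start" %in% names(genes)) {
    genes$bp <- genes$bp_start
  }
  stopifnot(all(c("gene_id", "chromosome", "bp") %in% names(genes)))
  on_chr <- genes[genes$chromosome == chromosome, , drop = FALSE]
  if (!nrow(on_chr)) {
    warning("no genes on chromosome ", chromosome, call. = FALSE)
    return(character(0))
  }
  on_chr$gene_id[abs(on_chr$bp - bp) <= window_bp]
}

# one-sided Fisher exact p for the 2x2 enrichment table: P(overlap >= k)
# with k of the n window genes hitting a pathway of K genes in a universe
# of N. Vectorized over k, K, n, N.
.enrichment_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Fisher exact pathway enrichment
#'
#' For each pathway, tests over-representation of the window genes by the
#' hypergeometric upper tail of the 2 x 2 table (in-window-and-pathway,
#' in-window-only, pathway-only, rest of universe) - the one-sided Fisher
#' exact p. A pathway is flagged significant at raw p < 0.05; BH-adjusted
#' p-values are reported alongside. Pathways with no genes in the universe
#' are skipped with a note.
#'
#' @param window_genes Character vector of genes in the hotspot window.
#' @param annotation Data frame with `gene_id`, `pathway_id`.
#' @param universe Character vector of all genes under consideration
#'   (default: every gene in `annotation`); must contain the window genes.
#' @param sig_alpha Raw-p significance rule (default 0.05).
#' @return Data frame sorted by p: `pathway_id`, `n_window`, `n_overlap`,
#'   `n_pathway`, `n_universe`, `p`, `p_adj`, `significant`; attribute
#'   `skipped` lists pathways absent from the universe.
#' @export
fisher_enrichment <- function(window_genes, annotation, universe = NULL,
                              sig_alpha = 0.05) {
  stopifnot(all(c("gene_id", "pathway_id") %in% names(annotation)),
            nrow(annotation) > 0)
  universe <- unique(universe %||% annotation$gene_id)
  if (!all(window_genes %in% universe)) {
    stop("universe must contain all window genes", call. = FALSE)
  }
  window_genes <- unique(window_genes)
  N <- length(universe)
  nw <- length(window_genes)
  skipped <- character(0)
  rows <- lapply(split(annotation$gene_id, annotation$pathway_id), function(pg) pg)
  res <- list()
  for (pid in names(rows)) {
    path_genes <- intersect(unique(rows[[pid]]), universe)
    K <- length(path_genes)
    if (K == 0L) {
      skipped <- c(skipped, pid)
      next
    }
    k <- length(intersect(window_genes, path_genes))
    p <- .enrichment_p(k, K, nw, N)
    res[[length(res) + 1L]] <- data.frame(
      pathway_id = pid, n_window = nw, n_overlap = k, n_pathway = K,
      n_universe = N, p = p, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(pathway_id = character(0), n_window = integer(0),
               n_overlap = integer(0), n_pathway = integer(0),
               n_universe = integer(0), p = numeric(0))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < sig_alpha
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
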