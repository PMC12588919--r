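#' Default pipeline configuration
#'
#' Nested configuration for the whole pipeline, serializable to YAML.
#' Command-line flags (in the `ampelomap` script) override file values.
#'
#' @param seed Mandatory base seed.
#' @param scan Scan settings (see [scan_config()]).
#' @param hotspot List with `min_qtl` and `window_bp`.
#' @param simulation A [sim_config()] (defaults to one built from `seed`).
#' @param polygon A [polygon_config()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, scan = NULL, hotspot = NULL,
                            simulation = NULL, polygon = polygon_config()) {
  if (missing(seed) || is.null(seed)) {
    stop("config error: seed is mandatory", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    scan = scan %||% scan_config(seed = seed),
    hotspot = utils::modifyList(list(min_qtl = 3L, window_bp = 700000),
                                hotspot %||% list()),
    simulation = simulation %||% sim_config(seed = seed),
    polygon = polygon), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; recognized top-level keys: `seed`, `scan`,
#'   `hotspot`, `simulation`, `polygon` (cycle vectors for
#'   [polygon_config()]).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config error: YAML must set a seed", call. = FALSE)
  polygon <- if (!is.null(y$polygon)) do.call(polygon_config, y$polygon) else
    polygon_config()
  scan <- do.call(scan_config, utils::modifyList(list(seed = y$seed),
                                                 y$scan %||% list()))
  simulation <- do.call(sim_config, utils::modifyList(list(seed = y$seed),
                                                      y$simulation %||% list()))
  pipeline_config(seed = y$seed, scan = scan, hotspot = y$hotspot,
                  simulation = simulation, polygon = polygon)
}

#' Simulate a full synthetic input bundle
#'
#' Writes landmark, ABH genotype, map, gene and annotation CSVs plus a
#' manifest (seed, config hash, file list) into `out_dir`; the files use the
#' same dialects the pipeline readers consume.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible named list of file paths; the manifest is
#'   `manifest.json`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$simulation
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- simulate_map(cfg$n_lgs, cfg$markers_per_lg, cfg$lg_length_cM,
                      cfg$bp_per_cM)
  cross <- simulate_genotypes(cfg$n_genotypes, map, seed = .child_seed(cfg$seed, 1L))
  leaves <- simulate_leaves(cfg, cross)
  ga <- simulate_gene_annotation(seed = .child_seed(cfg$seed, 2L))
  paths <- list(landmarks = file.path(out_dir, "landmarks.csv"),
                genotypes = file.path(out_dir, "genotypes.csv"),
                map = file.path(out_dir, "map.csv"),
                genes = file.path(out_dir, "genes.csv"),
                annotation = file.path(out_dir, "annotation.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_landmarks(leaves, paths$landmarks,
                  provenance = c(seed = as.character(cfg$seed)))
  write_abh(cross, paths$genotypes, paths$map)
  utils::write.csv(ga$genes, paths$genes, row.names = FALSE)
  utils::write.csv(ga$annotation, paths$annotation, row.names = FALSE)
  jsonlite::write_json(list(seed = cfg$seed, config_hash = .config_hash(cfg),
                            version = as.character(utils::packageVersion("ampelomap")),
                            files = lapply(paths, basename)),
                       paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}

#' Compute traits for a landmark CSV
#'
#' Reads the landmark table, computes the 16 phenotypes per leaf, and writes
#' the trait table plus a QC sidecar. Malformed leaves are reported (with
#' row numbers) and excluded; only an empty or unreadable input is fatal.
#'
#' @param landmarks_csv Input landmark CSV.
#' @param out_csv Output trait CSV.
#' @param qc_csv Optional QC report CSV.
#' @param config A [pipeline_config()].
#' @return Invisible trait data frame (attribute `"errors"` lists failures).
#' @export
run_traits <- function(landmarks_csv, out_csv, qc_csv = NULL,
                       config = pipeline_config(seed = 1L)) {
  df <- read_landmarks(landmarks_csv)
  traits <- compute_traits_df(df, config$polygon)
  errs <- attr(traits, "errors")
  if (nrow(errs)) {
    message("run_traits: ", nrow(errs), " leaf/leaves failed geometry: ",
            paste(sprintf("row %d (%s): %s", errs$row, errs$leaf_id,
                          errs$message), collapse = "; "))
  }
  .write_csv_provenance(traits, out_csv,
                        c(input = landmarks_csv,
                          n_leaves = as.character(nrow(traits))))
  if (!is.null(qc_csv)) {
    .write_csv_provenance(qc_landmarks_df(df, config$polygon), qc_csv,
                          c(input = landmarks_csv))
  }
  invisible(traits)
}

#' Run the QTL scan stage
#'
#' Assembles the trait matrix from a per-leaf trait CSV, reads the ABH
#' genotypes, scans every attribute and writes the QTL report.
#'
#' @param traits_csv Trait CSV from [run_traits()].
#' @param geno_csv ABH genotype CSV.
#' @param map_csv Optional sidecar map CSV.
#' @param out_csv Output QTL report CSV.
#' @param config A [pipeline_config()].
#' @return Invisible peak data frame (see [scan_qtl()]).
#' @export
run_scan <- function(traits_csv, geno_csv, map_csv = NULL, out_csv, config) {
  traits <- utils::read.csv(traits_csv, comment.char = "#",
                            stringsAsFactors = FALSE)
  tm <- assemble_trait_matrix(traits)
  cross <- read_abh(geno_csv, map_csv)
  peaks <- scan_qtl(tm, cross, config$scan)
  write_qtl_report(peaks, out_csv)
  invisible(peaks)
}

#' Run hotspot detection and pathway enrichment
#'
#' @param qtl_csv QTL report CSV from [run_scan()].
#' @param genes_csv Gene table CSV (`gene_id`, `chromosome`, `bp`).
#' @param annotation_csv Pathway annotation CSV (`gene_id`, `pathway_id`).
#' @param out_hotspots_csv,out_enrichment_csv Output CSVs.
#' @param config A [pipeline_config()].
#' @return Invisible list with `hotspots` and `enrichment` data frames.
#' @export
run_hotspots <- function(qtl_csv, genes_csv, annotation_csv,
                         out_hotspots_csv, out_enrichment_csv, config) {
  peaks <- read_qtl_report(qtl_csv)
  if (!file.exists(genes_csv)) {
    stop("gene table not found: ", genes_csv, call. = FALSE)
  }
  genes <- utils::read.csv(genes_csv, comment.char = "#",
                           stringsAsFactors = FALSE)
  annotation <- utils::read.csv(annotation_csv, comment.char = "#",
                                stringsAsFactors = FALSE)
  hs <- detect_hotspots(peaks, min_qtl = config$hotspot$min_qtl)
  enr <- list()
  for (i in seq_len(nrow(hs))) {
    wg <- gene_window(hs$chromosome[i], hs$bp[i], genes,
                      window_bp = config$hotspot$window_bp)
    if (!length(wg)) next
    fe <- fisher_enrichment(wg, annotation, universe = genes$gene_id)
    if (nrow(fe)) {
      fe <- cbind(peak_marker = hs$peak_marker[i], fe,
                  stringsAsFactors = FALSE)
      enr[[length(enr) + 1L]] <- fe
    }
  }
  enrichment <- if (length(enr)) do.call(rbind, enr) else
    data.frame(peak_marker = character(0), pathway_id = character(0),
               n_window = integer(0), n_overlap = integer(0),
               n_pathway = integer(0), n_universe = integer(0),
               p = numeric(0), p_adj = numeric(0), significant = logical(0))
  .write_csv_provenance(hs, out_hotspots_csv, c(input = qtl_csv))
  .write_csv_provenance(enrichment, out_enrichment_csv, c(input = qtl_csv))
  invisible(list(hotspots = hs, enrichment = enrichment))
}

#' Run the whole pipeline on a simulated bundle
#'
#' Simulate -> traits -> scan -> hotspots/enrichment, writing every stage's
#' outputs under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisible list of stage outputs.
#' @export
run_all_pipeline <- function(config, out_dir) {
  paths <- run_simulate(config, out_dir)
  traits <- run_traits(paths$landmarks, file.path(out_dir, "traits.csv"),
                       file.path(out_dir, "qc.csv"), config)
  peaks <- run_scan(file.path(out_dir, "traits.csv"), paths$genotypes,
                    paths$map, file.path(out_dir, "qtl.csv"), config)
  hot <- run_hotspots(file.path(out_dir, "qtl.csv"), paths$genes,
                      paths$annotation, file.path(out_dir, "hotspots.csv"),
                      file.path(out_dir, "enrichment.csv"), config)
  invisible(list(paths = paths, traits = traits, peaks = peaks,
                 hotspots = hot$hotspots, enrichment = hot$enrichment))
}
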