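.attribute_key <- function(phenotype, position, daylength_h, year) {
  sprintf("%s__%s__%dh__%d", phenotype, position, daylength_h, year)
}

#' Parse attribute keys back into their four components
#'
#' @param keys Character vector of keys `"<phenotype>__<position>__<Nh>__<year>"`.
#' @return Data frame with columns `phenotype`, `position`, `daylength_h`,
#'   `year`.
#' @export
parse_attribute_key <- function(keys) {
  parts <- strsplit(keys, "__", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed attribute key(s): ", paste(keys[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(phenotype = m[, 1], position = m[, 2],
             daylength_h = as.integer(sub("h$", "", m[, 3])),
             year = as.integer(m[, 4]), stringsAsFactors = FALSE)
}

#' Assemble the genotype x attribute trait matrix
#'
#' Reshapes per-leaf traits into one row per (genotype, presentation) and one
#' column per observed (phenotype, position, daylength, year) combination.
#' The full factorial of 16 phenotypes, 3 positions, 2 daylengths and 2 years
#' yields 192 attribute columns. Replicate leaves falling in the same cell
#' are averaged (their count is tracked); in strict mode they raise a
#' duplicate-record error. Missing cells stay `NA`, never imputed here.
#'
#' @param traits Data frame from [compute_traits_df()] (metadata plus the 16
#'   trait columns).
#' @param strict If `TRUE`, replicate leaves per cell are an error.
#' @return Object of class `trait_matrix`: list with `values` (numeric
#'   matrix), `counts` (leaves per cell), `genotype`, `presentation` (row
#'   metadata) and `attributes` (parsed column metadata).
#' @export
assemble_trait_matrix <- function(traits, strict = FALSE) {
  phen <- intersect(trait_names(), names(traits))
  if (!length(phen)) stop("no trait columns found", call. = FALSE)
  long <- do.call(rbind, lapply(phen, function(p) {
    data.frame(genotype_id = traits$genotype_id,
               presentation = traits$presentation,
               key = .attribute_key(p, traits$position, traits$daylength_h,
                                    traits$year),
               value = traits[[p]], stringsAsFactors = FALSE)
  }))
  row_key <- paste(long$genotype_id, long$presentation, sep = "\r")
  rows <- unique(row_key)
  cols <- unique(long$key)
  ri <- match(row_key, rows)
  ci <- match(long$key, cols)
  counts <- matrix(0L, length(rows), length(cols), dimnames = list(NULL, cols))
  sums <- matrix(0, length(rows), length(cols), dimnames = list(NULL, cols))
  for (k in seq_along(ri)) {
    counts[ri[k], ci[k]] <- counts[ri[k], ci[k]] + 1L
    sums[ri[k], ci[k]] <- sums[ri[k], ci[k]] + long$value[k]
  }
  if (strict && any(counts > 1L)) {
    dup <- which(counts > 1L, arr.ind = TRUE)[1, ]
    stop("duplicate-record: multiple leaves for genotype '",
         sub("\r.*", "", rows[dup[1]]), "', attribute '", cols[dup[2]], "'",
         call. = FALSE)
  }
  values <- sums / counts
  values[counts == 0L] <- NA_real_
  meta <- do.call(rbind, strsplit(rows, "\r", fixed = TRUE))
  rownames(values) <- rownames(counts) <- meta[, 1]
  structure(list(values = values, counts = counts, genotype = meta[, 1],
                 presentation = meta[, 2],
                 attributes = cbind(key = cols, parse_attribute_key(cols))),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d rows (genotype x presentation) x %d attributes; %d non-missing cells\n",
              nrow(x$values), ncol(x$values), sum(!is.na(x$values))))
  invisible(x)
}

#' Write / read a trait matrix as CSV
#'
#' Row key `genotype_id` plus `presentation`, then one column per attribute;
#' missing cells are empty.
#' @param tm A `trait_matrix`.
#' @param path CSV path.
#' @param provenance Optional named character vector of header lines.
#' @export
write_trait_matrix <- function(tm, path, provenance = NULL) {
  df <- data.frame(genotype_id = tm$genotype, presentation = tm$presentation,
                   tm$values, check.names = FALSE, stringsAsFactors = FALSE)
  .write_csv_provenance(df, path, provenance)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("genotype_id", "presentation")),
                       drop = FALSE])
  rownames(vals) <- df$genotype_id
  structure(list(values = vals, counts = (!is.na(vals)) * 1L,
                 genotype = df$genotype_id, presentation = df$presentation,
                 attributes = cbind(key = colnames(vals),
                                    parse_attribute_key(colnames(vals)))),
            class = "trait_matrix")
}

#' Z-transform a trait matrix within phenotype x position x presentation
#'
#' Standardizes each group of cells sharing a phenotype, a leaf position and
#' a presentation (pooling daylengths, years and genotypes) to mean 0 and
#' sample SD 1, removing the scale differences between leaf positions before
#' pooled descriptive displays. Missing cells stay missing. Idempotent.
#'
#' @param tm A `trait_matrix`.
#' @return A `trait_matrix` with standardized `values`.
#' @export
z_transform_matrix <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  vals <- tm$values
  grp_col <- paste(tm$attributes$phenotype, tm$attributes$position)
  for (pres in unique(tm$presentation)) {
    ri <- tm$presentation == pres
    for (g in unique(grp_col)) {
      ci <- grp_col == g
      cells <- vals[ri, ci]
      obs <- cells[!is.na(cells)]
      if (length(obs) < 2L || stats::sd(obs) == 0) {
        stop("zero-variance group: ", g, " / ", pres, call. = FALSE)
      }
      vals[ri, ci] <- (cells - mean(obs)) / stats::sd(obs)
    }
  }
  tm$values <- vals
  tm
}

#' Kruskal-Wallis rank-sum test
#'
#' Nonparametric test for location differences across groups, with the tie
#' correction always applied; the completely tied case is reported as H = 0,
#' p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("kruskal_wallis: need >= 2 groups", call. = FALSE)
  if (any(tabulate(groups) == 0L)) stop("kruskal_wallis: empty group", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Tidy Kruskal-Wallis report over all phenotypes
#'
#' Runs [kruskal_wallis()] for each phenotype and leaf position, comparing a
#' grouping variable (e.g. daylength or year), and adjusts p-values by
#' Benjamini-Hochberg.
#'
#' @param traits Per-leaf trait data frame from [compute_traits_df()].
#' @param group_var Metadata column to compare (default `"daylength_h"`).
#' @return Tidy data frame (test, trait, position, H, df, p, p_adj).
#' @export
kruskal_report <- function(traits, group_var = "daylength_h") {
  phen <- intersect(trait_names(), names(traits))
  grid <- expand.grid(trait = phen, position = unique(traits$position),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- traits$position == grid$position[i]
    kw <- tryCatch(kruskal_wallis(traits[[grid$trait[i]]][sel],
                                  traits[[group_var]][sel]),
                   error = function(e) list(H = NA_real_, df = NA_integer_,
                                            p = NA_real_))
    data.frame(test = paste0("kruskal_wallis:", group_var),
               trait = grid$trait[i], position = grid$position[i],
               H = kw$H, df = kw$df, p = kw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Pairwise Pearson correlation of trait-matrix columns
#'
#' Pairwise-complete Pearson correlations; constant columns yield `NA`
#' entries with a warning.
#'
#' @param tm A `trait_matrix` or plain numeric matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
trait_correlation <- function(tm) {
  vals <- if (inherits(tm, "trait_matrix")) tm$values else as.matrix(tm)
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  if (any(constant <- (is.na(sds) | sds == 0))) {
    warning("constant column(s), correlation undefined: ",
            paste(colnames(vals)[constant], collapse = ", "), call. = FALSE)
  }
  suppressWarnings(cc <- stats::cor(vals, use = "pairwise.complete.obs"))
  diag(cc) <- 1
  cc
}

#' Principal component analysis of a trait matrix
#'
#' Centered (and by default correlation-scaled) PCA via the singular value
#' decomposition. Missing cells are mean-imputed with a flag; matrices with
#' more than `max_missing` missing fraction are rejected as too sparse.
#'
#' @param tm A `trait_matrix` or numeric matrix (rows = observations).
#' @param scale. Scale columns to unit variance (default `TRUE`).
#' @param max_missing Maximum tolerated overall missing fraction.
#' @return List with `scores`, `loadings`, `variance_fractions`, `sdev`,
#'   `center`, `scale`, `imputed_cells`.
#' @export
trait_pca <- function(tm, scale. = TRUE, max_missing = 0.2) {
  vals <- if (inherits(tm, "trait_matrix")) tm$values else as.matrix(tm)
  if (nrow(vals) < 2L || ncol(vals) < 2L) {
    stop("trait_pca: need >= 2 rows and columns", call. = FALSE)
  }
  n_missing <- sum(is.na(vals))
  if (n_missing / length(vals) > max_missing) {
    stop("too-sparse: ", round(100 * n_missing / length(vals), 1),
         "% missing exceeds limit", call. = FALSE)
  }
  if (n_missing > 0L) {
    for (j in seq_len(ncol(vals))) {
      mj <- is.na(vals[, j])
      if (any(mj)) vals[mj, j] <- mean(vals[, j], na.rm = TRUE)
    }
  }
  pc <- stats::prcomp(vals, center = TRUE, scale. = scale.)
  list(scores = pc$x, loadings = pc$rotation,
       variance_fractions = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev,
       center = pc$center, scale = pc$scale, imputed_cells = n_missing)
}

#' Factorial variance partition of component scores
#'
#' Decomposes one score vector over the categorical design factors with
#' sequential (type I) sums of squares in the fixed order year, daylength,
#' position, genotype, genotype:year, genotype:position (terms absent from
#' `factors` are skipped). Fractions are SS(term) / total SS; the residual
#' fraction completes the unit sum. This factorial linear model is the
#' categorical reduction of a smooth-term factor model: with only factor
#' covariates there is nothing to penalize, so the decomposition is exact.
#'
#' @param scores Numeric vector (e.g. one principal component).
#' @param factors Data frame of categorical factors, any of `year`,
#'   `daylength`, `position`, `genotype` (rows aligned with `scores`); rows
#'   with missing values are dropped with a message.
#' @return List of class `variance_partition` with `fractions` (named, incl.
#'   `residual`), `df` and `n`.
#' @export
variance_partition <- function(scores, factors) {
  stopifnot(is.data.frame(factors), length(scores) == nrow(factors))
  keep <- !is.na(scores) & stats::complete.cases(factors)
  if (!all(keep)) message("variance_partition: dropping ", sum(!keep),
                          " incomplete row(s)")
  y <- scores[keep]
  fa <- factors[keep, , drop = FALSE]
  for (j in names(fa)) {
    fa[[j]] <- factor(fa[[j]])
    if (nlevels(fa[[j]]) < 2L) {
      stop("factor '", j, "' has < 2 levels", call. = FALSE)
    }
  }
  order_terms <- c("year", "daylength", "position", "genotype",
                   "genotype:year", "genotype:position")
  have <- names(fa)
  terms <- c(intersect(c("year", "daylength", "position", "genotype"), have),
             if (all(c("genotype", "year") %in% have)) "genotype:year",
             if (all(c("genotype", "position") %in% have)) "genotype:position")
  terms <- order_terms[order_terms %in% terms]
  fml <- stats::reformulate(terms, response = "y")
  dat <- cbind(y = y, fa)
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("aliasing error: collinear terms in design (",
         paste(utils::head(bad, 3), collapse = ", "), ")", call. = FALSE)
  }
  av <- stats::anova(fit)
  tss <- sum(av[["Sum Sq"]])
  fr <- av[["Sum Sq"]] / tss
  names(fr) <- rownames(av)
  names(fr)[names(fr) == "Residuals"] <- "residual"
  # anova orders interaction labels by factor appearance; report the
  # documented genotype-first names
  names(fr)[names(fr) == "year:genotype"] <- "genotype:year"
  names(fr)[names(fr) == "position:genotype"] <- "genotype:position"
  structure(list(fractions = fr, df = stats::setNames(av[["Df"]], names(fr)),
                 n = length(y)), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance partition (sequential SS), n =", x$n, "\n")
  print(round(x$fractions, 4))
  invisible(x)
}
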