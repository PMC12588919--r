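#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard test with an explicit error for constant
#' input; gates the choice between parametric and rank-based genome scans.
#'
#' @param x Numeric vector, 3 <= n <= 5000 after NA removal.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("shapiro_wilk: need 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("shapiro_wilk: constant vector", call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Normalize a trait through the transformation ladder
#'
#' Identity if the trait already passes Shapiro-Wilk at `sw_alpha`; otherwise
#' log (positive traits only), then Box-Cox with the profile-likelihood
#' lambda on the fixed grid -2..2 in steps of 0.1; the first transform whose
#' Shapiro-Wilk p reaches `sw_alpha` wins. Traits that defeat the ladder are
#' tagged `"nonparametric"` and scanned by ranks downstream.
#'
#' @param x Numeric vector (>= 20 non-missing values).
#' @param sw_alpha Shapiro-Wilk gate (default 0.05).
#' @return List with `values`, `method` (`identity`, `log`, `boxcox`,
#'   `nonparametric`), `lambda` (Box-Cox only), `shapiro_p`, and `note`.
#' @export
normalize_trait <- function(x, sw_alpha = 0.05) {
  obs <- x[!is.na(x)]
  if (length(obs) < 20L) {
    stop("normalize_trait: need >= 20 non-missing values", call. = FALSE)
  }
  sw <- shapiro_wilk(obs)
  if (sw$p >= sw_alpha) {
    return(list(values = x, method = "identity", lambda = NA_real_,
                shapiro_p = sw$p, note = ""))
  }
  note <- ""
  if (all(obs > 0)) {
    lx <- log(x)
    swl <- shapiro_wilk(lx[!is.na(lx)])
    if (swl$p >= sw_alpha) {
      return(list(values = lx, method = "log", lambda = NA_real_,
                  shapiro_p = swl$p, note = ""))
    }
    bc <- .boxcox_grid(obs)
    bx <- ifelse(is.na(x), NA_real_,
                 if (abs(bc$lambda) < 1e-12) log(x) else (x^bc$lambda - 1) / bc$lambda)
    swb <- shapiro_wilk(bx[!is.na(bx)])
    if (swb$p >= sw_alpha) {
      return(list(values = bx, method = "boxcox", lambda = bc$lambda,
                  shapiro_p = swb$p, note = ""))
    }
  } else {
    note <- "nonpositive values: log/Box-Cox skipped"
  }
  list(values = x, method = "nonparametric", lambda = NA_real_,
       shapiro_p = sw$p, note = note)
}

# profile-likelihood Box-Cox lambda on the fixed grid -2..2 step 0.1
.boxcox_grid <- function(y, grid = seq(-2, 2, by = 0.1)) {
  stopifnot(all(y > 0))
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(grid, function(lm) {
    yt <- if (abs(lm) < 1e-12) log(y) else (y^lm - 1) / lm
    -n / 2 * log(mean((yt - mean(yt))^2)) + (lm - 1) * slog
  }, numeric(1))
  list(lambda = grid[which.max(ll)], loglik = max(ll))
}

# Vectorized single-locus scan over many phenotype columns.
# G: individuals x markers (0/1/2/NA); Y: individuals x P, no NA.
# Returns markers x P matrix of LOD scores (parametric) or rank-scan LOD
# analogs (nonparametric). The 3-class additive+dominance regression is the
# saturated one-way model, so LOD = (n/2) log10(RSS0/RSS1) with RSS1 the
# within-class residual sum of squares.
.scan_lod_matrix <- function(G, Y, method = c("parametric", "nonparametric")) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("internal: phenotypes must be complete here", call. = FALSE)
  O <- !is.na(G)
  complete_G <- all(O)
  n_all <- nrow(G)

  if (method == "nonparametric") {
    if (!complete_G) {
      return(.scan_np_missing(G, Y))
    }
    R <- apply(Y, 2, rank)
    N <- n_all
    ties <- apply(Y, 2, function(y) {
      t <- table(y)
      1 - sum(t^3 - t) / (N^3 - N)
    })
    lodm <- matrix(0, ncol(G), ncol(Y))
    Nc <- matrix(0, ncol(G), 3)
    Sc2 <- matrix(0, ncol(G), ncol(Y))
    for (cls in 0:2) {
      M <- (G == cls)
      nc <- colSums(M)
      Nc[, cls + 1] <- nc
      S <- crossprod(M, R)
      Sc2 <- Sc2 + S^2 / ifelse(nc == 0, Inf, nc)
    }
    H <- 12 / (N * (N + 1)) * Sc2 - 3 * (N + 1)
    H <- sweep(H, 2, ties, "/")
    H[H < 0] <- 0
    lodm <- H / (2 * log(10))
    lodm[rowSums(Nc > 0) < 2L, ] <- 0
    attr(lodm, "n") <- rep(N, ncol(G))
    attr(lodm, "n_classes") <- rowSums(Nc > 0)
    return(lodm)
  }

  Ysq <- Y^2
  if (complete_G) {
    n <- rep(n_all, ncol(G))
    Tm <- matrix(colSums(Y), ncol(G), ncol(Y), byrow = TRUE)
    Qm <- matrix(colSums(Ysq), ncol(G), ncol(Y), byrow = TRUE)
  } else {
    n <- colSums(O)
    Tm <- crossprod(O, Y)
    Qm <- crossprod(O, Ysq)
  }
  Sc2 <- matrix(0, ncol(G), ncol(Y))
  Nc <- matrix(0, ncol(G), 3)
  for (cls in 0:2) {
    M <- (G == cls) & O
    nc <- colSums(M)
    Nc[, cls + 1] <- nc
    S <- crossprod(M, Y)
    Sc2 <- Sc2 + S^2 / ifelse(nc == 0, Inf, nc)
  }
  RSS0 <- Qm - Tm^2 / n
  RSS1 <- Qm - Sc2
  RSS1 <- pmax(RSS1, RSS0 * 1e-12) # perfect fits stay finite
  lodm <- (n / 2) * log10(RSS0 / RSS1)
  lodm[!is.finite(lodm) | lodm < 0] <- 0
  lodm[rowSums(Nc > 0) < 2L, ] <- 0
  attr(lodm, "n") <- n
  attr(lodm, "n_classes") <- rowSums(Nc > 0)
  lodm
}

# rank scan fallback when genotypes have missing calls: per-marker re-ranking
.scan_np_missing <- function(G, Y) {
  lodm <- matrix(0, ncol(G), ncol(Y))
  ncl <- integer(ncol(G))
  nv <- integer(ncol(G))
  for (m in seq_len(ncol(G))) {
    keep <- !is.na(G[, m])
    g <- G[keep, m]
    nv[m] <- sum(keep)
    ncl[m] <- length(unique(g))
    if (ncl[m] < 2L) next
    for (p in seq_len(ncol(Y))) {
      kw <- stats::kruskal.test(Y[keep, p], factor(g))
      h <- unname(kw$statistic)
      if (!is.finite(h)) h <- 0
      lodm[m, p] <- max(h, 0) / (2 * log(10))
    }
  }
  attr(lodm, "n") <- nv
  attr(lodm, "n_classes") <- ncl
  lodm
}

.align_phenotype <- function(cross, y) {
  ids <- rownames(cross$geno)
  if (!is.null(names(y))) {
    orphans <- setdiff(names(y)[!is.na(y)], ids)
    if (length(orphans)) {
      stop("reconciliation error: phenotyped ids missing from cross: ",
           paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
    }
    y <- y[match(ids, names(y))]
    names(y) <- ids
  } else if (length(y) != length(ids)) {
    stop("reconciliation error: unnamed phenotype of wrong length", call. = FALSE)
  }
  y
}

#' Single-locus genome scan
#'
#' At every marker, compares the intercept-only model to the genotype model
#' with additive (A = -1, H = 0, B = +1) plus dominance (H = 1) coding:
#' `LOD = (n/2) log10(RSS0/RSS1)`, individuals with a missing call dropped
#' per marker. `scan_nonparametric()` replaces the regression with a
#' Kruskal-Wallis rank statistic over the genotype classes and reports the
#' LOD analog `H / (2 ln 10)`. Markers with fewer than two observed genotype
#' classes score 0 and are flagged.
#'
#' @param cross An `abh_cross`.
#' @param y Numeric phenotype, named by individual id (NA allowed; >= 30
#'   complete individuals required).
#' @param min_n Minimum phenotyped-and-genotyped individuals.
#' @return Data frame (`marker`, `linkage_group`, `cM`, `lod`) with
#'   attributes `n` (phenotyped individuals) and `flagged` (markers with < 2
#'   classes).
#' @export
scan_parametric <- function(cross, y, min_n = 30L) {
  .scan_one(cross, y, "parametric", min_n)
}

#' @rdname scan_parametric
#' @export
scan_nonparametric <- function(cross, y, min_n = 30L) {
  .scan_one(cross, y, "nonparametric", min_n)
}

.scan_one <- function(cross, y, method, min_n) {
  y <- .align_phenotype(cross, y)
  keep <- !is.na(y)
  if (sum(keep) < min_n) {
    stop("scan: fewer than ", min_n, " phenotyped individuals", call. = FALSE)
  }
  G <- geno_numeric(cross)[keep, , drop = FALSE]
  lodm <- .scan_lod_matrix(G, matrix(y[keep], ncol = 1), method)
  out <- data.frame(marker = cross$map$marker,
                    linkage_group = cross$map$linkage_group,
                    cM = cross$map$cM, lod = as.numeric(lodm),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- sum(keep)
  attr(out, "method") <- method
  attr(out, "flagged") <- cross$map$marker[attr(lodm, "n_classes") < 2L]
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Empirical `1 - alpha` quantile (type 7) of the genome-wide maximum LOD
#' over `n_perm` random phenotype permutations, holding genotypes fixed.
#' Reproducible given the seed.
#'
#' @inheritParams scan_parametric
#' @param method `"parametric"` or `"nonparametric"` (must match the scan).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param seed Mandatory RNG seed.
#' @param chunk Permutations per vectorized block.
#' @return Threshold (scalar) with attribute `max_lods` (the permutation
#'   distribution).
#' @export
permutation_threshold <- function(cross, y, method = c("parametric", "nonparametric"),
                                  n_perm = 1000L, alpha = 0.05, seed,
                                  min_n = 30L, chunk = 250L) {
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) stop("config error: seed required", call. = FALSE)
  if (n_perm < 100L) warning("n_perm < 100: unstable threshold tail", call. = FALSE)
  y <- .align_phenotype(cross, y)
  keep <- !is.na(y)
  if (sum(keep) < min_n) {
    stop("scan: fewer than ", min_n, " phenotyped individuals", call. = FALSE)
  }
  G <- geno_numeric(cross)[keep, , drop = FALSE]
  # sorting makes the threshold depend on the phenotype multiset only, so
  # relabeling individuals cannot change it
  yy <- sort(y[keep])
  set.seed(as.integer(seed))
  max_lods <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    Y <- vapply(seq_len(b), function(i) sample(yy), numeric(length(yy)))
    lodm <- .scan_lod_matrix(G, Y, method)
    max_lods[done + seq_len(b)] <- apply(lodm, 2, max)
    done <- done + b
  }
  thr <- unname(stats::quantile(max_lods, 1 - alpha, type = 7))
  attr(thr, "max_lods") <- max_lods
  attr(thr, "n_perm") <- n_perm
  attr(thr, "alpha") <- alpha
  attr(thr, "seed") <- as.integer(seed)
  thr
}

#' Percent variance explained from a LOD score
#'
#' The standard single-QTL identity `PVE = 100 (1 - 10^(-2 LOD / n))`.
#'
#' @param lod LOD score(s), >= 0.
#' @param n Sample size used in the scan.
#' @return Percent in `[0, 100)`.
#' @export
pve <- function(lod, n) {
  stopifnot(all(lod >= 0), n >= 2)
  100 * (1 - 10^(-2 * lod / n))
}

#' Bayesian credible interval for a QTL peak
#'
#' Treats `10^LOD`, normalized over one linkage group, as a posterior over
#' marker positions and returns the smallest contiguous cM span that
#' contains the peak and at least `coverage` of the mass (exact search over
#' all windows containing the peak; ties broken toward fewer markers). A
#' flat LOD curve yields the whole linkage group with a flag.
#'
#' @param lod Per-marker LOD on one linkage group (>= 3 markers).
#' @param cM Marker positions, same length, non-decreasing.
#' @param coverage Posterior mass to cover (default 0.95).
#' @return `c(low, high)` in cM with attributes `peak_index` and `flat`.
#' @export
bayes_interval <- function(lod, cM, coverage = 0.95) {
  k <- length(lod)
  stopifnot(k == length(cM), k >= 3L)
  w <- 10^(lod - max(lod))
  w <- w / sum(w)
  peak <- which.max(lod)
  if (diff(range(lod)) < 1e-12) {
    out <- c(low = cM[1], high = cM[k])
    attr(out, "flat") <- TRUE
    attr(out, "peak_index") <- peak
    return(out)
  }
  best <- NULL
  for (lo in seq_len(peak)) {
    cum <- cumsum(w[lo:k])
    his <- which(cum >= coverage - 1e-12) + lo - 1L
    his <- his[his >= peak]
    if (!length(his)) next
    hi <- his[1]
    span <- cM[hi] - cM[lo]
    cand <- c(span = span, lo = lo, hi = hi, nmark = hi - lo + 1L)
    if (is.null(best) || span < best["span"] - 1e-12 ||
        (abs(span - best["span"]) <= 1e-12 && cand["nmark"] < best["nmark"])) {
      best <- cand
    }
  }
  out <- c(low = cM[best["lo"]], high = cM[best["hi"]])
  names(out) <- c("low", "high")
  attr(out, "flat") <- FALSE
  attr(out, "peak_index") <- peak
  out
}
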