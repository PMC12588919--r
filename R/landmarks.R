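#' Polygon configuration for the landmark scheme
#'
#' Defines which landmark indices, in which cyclic order, form the leaf
#' boundary polygon and the three vein polygons, plus the landmark pair
#' measuring the petiolar sinus width (L5). Defaults traverse each vein
#' sliver as: base landmark on the branch side, proximal branch base, branch
#' tip, distal branch base, vein tip, width landmark on the opposite side,
#' far base landmark. The boundary cycle uses the eight margin landmarks
#' (vein tips, lobe tips, sinuses, leaf tip) in margin order.
#'
#' @param boundary Ordered landmark indices of the leaf-boundary cycle.
#' @param mid,dist,prox Ordered landmark indices of the middle, distal and
#'   proximal vein polygons.
#' @param sinus_pair Two landmark indices whose distance is the petiolar
#'   sinus width L5.
#' @return An object of class `polygon_config`.
#' @export
polygon_config <- function(boundary = c(14L, 15L, 16L, 17L, 18L, 19L, 20L, 21L),
                           mid  = c(3L, 12L, 20L, 11L, 21L, 13L, 4L),
                           dist = c(2L, 9L, 17L, 8L, 18L, 10L, 3L),
                           prox = c(1L, 6L, 14L, 5L, 15L, 7L, 2L),
                           sinus_pair = c(6L, 14L)) {
  cycles <- list(boundary = boundary, mid = mid, dist = dist, prox = prox)
  for (nm in names(cycles)) {
    cy <- as.integer(cycles[[nm]])
    if (length(cy) < 3L || anyDuplicated(cy) || any(cy < 1L | cy > 21L)) {
      stop("polygon_config: cycle '", nm,
           "' must have >= 3 distinct indices in 1..21", call. = FALSE)
    }
    cycles[[nm]] <- cy
  }
  sp <- as.integer(sinus_pair)
  if (length(sp) != 2L || sp[1] == sp[2] || any(sp < 1L | sp > 21L)) {
    stop("polygon_config: sinus_pair must be 2 distinct indices in 1..21",
         call. = FALSE)
  }
  structure(c(cycles, list(sinus_pair = sp)), class = "polygon_config")
}

#' @export
print.polygon_config <- function(x, ...) {
  cat("polygon_config\n")
  for (nm in c("boundary", "mid", "dist", "prox")) {
    cat(sprintf("  %-9s %s\n", nm, paste(x[[nm]], collapse = "-")))
  }
  cat("  sinus_pair", paste(x$sinus_pair, collapse = "-"), "\n")
  invisible(x)
}

.positions <- c("apical", "middle", "basal")
.presentations <- c("own_rooted", "grafted")
.daylengths <- c(13L, 14L)

#' Construct a single-leaf landmark set
#'
#' Bundles the 21 labeled landmark coordinates of one leaf with its design
#' metadata (genotype, presentation, canopy position, daylength treatment,
#' year). Coordinates are assumed calibrated to cm with y increasing toward
#' the leaf tip.
#'
#' @param leaf_id,genotype_id Identifiers.
#' @param presentation `"own_rooted"` or `"grafted"`.
#' @param position Leaf position on the shoot: `"apical"`, `"middle"` or
#'   `"basal"`.
#' @param daylength_h Photoperiod treatment in hours (13 or 14).
#' @param year Integer year.
#' @param points 21 x 2 numeric matrix of landmark coordinates, row i being
#'   landmark i.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(leaf_id, genotype_id, presentation, position,
                         daylength_h, year, points) {
  points <- .as_vertex_matrix(points)
  if (nrow(points) != 21L) {
    stop("landmark_set: exactly 21 landmarks required, got ", nrow(points),
         call. = FALSE)
  }
  presentation <- match.arg(presentation, .presentations)
  position <- match.arg(position, .positions)
  daylength_h <- as.integer(daylength_h)
  if (!daylength_h %in% .daylengths) {
    stop("landmark_set: daylength_h must be 13 or 14", call. = FALSE)
  }
  structure(list(leaf_id = as.character(leaf_id),
                 genotype_id = as.character(genotype_id),
                 presentation = presentation, position = position,
                 daylength_h = daylength_h, year = as.integer(year),
                 points = points),
            class = "landmark_set")
}

.landmark_coord_cols <- function() {
  as.vector(rbind(paste0("x", 1:21), paste0("y", 1:21)))
}

.landmark_meta_cols <- c("leaf_id", "genotype_id", "presentation", "position",
                         "daylength_h", "year")

#' Read a landmark coordinate table
#'
#' One row per leaf: the six metadata columns followed by the interleaved
#' coordinate columns `x1, y1, ..., x21, y21`. The reader enforces exactly 21
#' landmarks per leaf and validates the metadata enums. Lines starting with
#' `#` (provenance headers) are skipped.
#'
#' @param path CSV file path.
#' @param scale Optional uniform scale factor applied to all coordinates at
#'   read time (e.g. a px-to-cm calibration), default 1.
#' @return A `data.frame` of class `landmark_df`.
#' @export
read_landmarks <- function(path, scale = 1) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty landmark file: ", path, call. = FALSE)
  as_landmark_df(df, scale = scale)
}

#' Validate a data frame of leaf landmarks
#'
#' @param df Data frame with the landmark CSV columns.
#' @param scale Uniform coordinate scale factor.
#' @return The validated `landmark_df`.
#' @export
as_landmark_df <- function(df, scale = 1) {
  needed <- c(.landmark_meta_cols, .landmark_coord_cols())
  missing_cols <- setdiff(needed, names(df))
  extra_xy <- grep("^[xy][0-9]+$", setdiff(names(df), needed), value = TRUE)
  if (length(missing_cols) || length(extra_xy)) {
    stop("landmark table must carry exactly 21 landmarks per leaf ",
         "(columns x1,y1,...,x21,y21 plus ", paste(.landmark_meta_cols, collapse = ", "),
         "); missing: ", paste(missing_cols, collapse = ", "),
         if (length(extra_xy)) paste0("; unexpected: ", paste(extra_xy, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[, needed]
  coords <- .landmark_coord_cols()
  for (cc in coords) df[[cc]] <- as.numeric(df[[cc]]) * scale
  if (!all(is.finite(as.matrix(df[, coords])))) {
    bad <- which(!stats::complete.cases(df[, coords]) |
                   !apply(is.finite(as.matrix(df[, coords])), 1, all))
    stop("invalid-coordinate: non-finite landmark coordinates in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(df$presentation %in% .presentations)) {
    stop("invalid presentation value(s): ",
         paste(unique(setdiff(df$presentation, .presentations)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$position %in% .positions)) {
    stop("invalid position value(s): ",
         paste(unique(setdiff(df$position, .positions)), collapse = ", "),
         call. = FALSE)
  }
  df$daylength_h <- as.integer(df$daylength_h)
  if (!all(df$daylength_h %in% .daylengths)) {
    stop("daylength_h must be 13 or 14", call. = FALSE)
  }
  df$year <- as.integer(df$year)
  class(df) <- c("landmark_df", "data.frame")
  df
}

#' Write a landmark table to CSV
#'
#' @param df A `landmark_df`.
#' @param path Output CSV path.
#' @param provenance Optional named character vector written as `#`-prefixed
#'   header lines.
#' @export
write_landmarks <- function(df, path, provenance = NULL) {
  .write_csv_provenance(as.data.frame(df), path, provenance)
}

#' Extract one leaf's 21 x 2 coordinate matrix
#'
#' @param df A `landmark_df`.
#' @param i Row index (leaf).
#' @return 21 x 2 numeric matrix.
#' @export
leaf_points <- function(df, i = 1L) {
  x <- as.numeric(df[i, paste0("x", 1:21)])
  y <- as.numeric(df[i, paste0("y", 1:21)])
  cbind(x = x, y = y)
}

#' Quality-control flags for one leaf's landmarks
#'
#' Reports (never raises) geometric anomalies: a self-intersecting boundary
#' cycle, a leaf tip (landmark 21) that is not the most distal boundary
#' point (largest y, with y oriented toward the tip), any vein length
#' exceeding a configurable multiple of the boundary diameter, and duplicate
#' landmark coordinates.
#'
#' @param points 21 x 2 landmark matrix.
#' @param cfg A [polygon_config()].
#' @param max_vein_ratio Flag veins longer than this multiple of the boundary
#'   diameter (default 1.5).
#' @param tol Coordinate tolerance for duplicate detection.
#' @return Character vector of flags (length 0 when clean).
#' @export
qc_landmarks <- function(points, cfg = polygon_config(), max_vein_ratio = 1.5,
                         tol = 1e-9) {
  points <- .as_vertex_matrix(points)
  if (nrow(points) != 21L) stop("qc_landmarks: 21 landmarks required", call. = FALSE)
  flags <- character(0)
  boundary <- points[cfg$boundary, , drop = FALSE]
  if (!polygon_is_simple(boundary)) {
    flags <- c(flags, "boundary-self-intersection")
  }
  if (points[21, 2] < max(boundary[, 2]) - tol) {
    flags <- c(flags, "tip-not-distal")
  }
  diam <- max(stats::dist(boundary))
  lens <- tryCatch(vein_lengths(points, cfg), error = function(e) NULL)
  if (!is.null(lens) && any(lens[c("L1", "L2", "L3", "L4")] > max_vein_ratio * diam)) {
    flags <- c(flags, "vein-length-anomaly")
  }
  if (any(stats::dist(points) < tol)) {
    flags <- c(flags, "duplicate-coordinate")
  }
  flags
}

#' Quality-control report for a landmark table
#'
#' @param df A `landmark_df`.
#' @param cfg A [polygon_config()].
#' @param ... Passed to [qc_landmarks()].
#' @return Data frame with `leaf_id` and semicolon-joined `flags` (empty
#'   string when clean).
#' @export
qc_landmarks_df <- function(df, cfg = polygon_config(), ...) {
  flags <- vapply(seq_len(nrow(df)), function(i) {
    paste(qc_landmarks(leaf_points(df, i), cfg, ...), collapse = ";")
  }, character(1))
  data.frame(leaf_id = df$leaf_id, flags = flags, stringsAsFactors = FALSE)
}
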