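#' Names of the 16 leaf phenotypes
#'
#' Ten size traits (four vein lengths, six areas) and six shape ratios, in
#' canonical order.
#' @return Character vector of length 16.
#' @export
trait_names <- function() {
  c("mid_vein_length", "prox_vein_length", "dist_vein_length",
    "xvii_vein_length",
    "total_area", "blade_area", "vein_area",
    "mid_vein_area", "prox_vein_area", "dist_vein_area",
    "veins_to_blade", "prox_to_dist", "prox_to_mid", "dist_to_mid",
    "xvii_to_mid", "petiolar_sinus_to_area")
}

#' Vein length measures L1-L5
#'
#' L1 (middle vein) runs from the midpoint of landmarks 3 and 4 to landmark
#' 21; L2 (distal vein) from the midpoint of 2 and 3 to 18; L3 (xvii vein)
#' from 2 to 17; L4 (proximal vein) from the midpoint of 1 and 2 to 15; L5
#' is the petiolar sinus width, the distance across the configured
#' `sinus_pair`.
#'
#' @param points 21 x 2 landmark matrix.
#' @param cfg A [polygon_config()] (only `sinus_pair` is used here).
#' @return Named numeric vector `L1..L5` in cm.
#' @export
vein_lengths <- function(points, cfg = polygon_config()) {
  points <- .as_vertex_matrix(points)
  if (nrow(points) != 21L) stop("vein_lengths: 21 landmarks required", call. = FALSE)
  if (max(stats::dist(points)) < 1e-12) {
    stop("degenerate-geometry: all landmarks coincide", call. = FALSE)
  }
  sp <- cfg$sinus_pair
  c(L1 = euclidean_distance(midpoint(points[3, ], points[4, ]), points[21, ]),
    L2 = euclidean_distance(midpoint(points[2, ], points[3, ]), points[18, ]),
    L3 = euclidean_distance(points[2, ], points[17, ]),
    L4 = euclidean_distance(midpoint(points[1, ], points[2, ]), points[15, ]),
    L5 = euclidean_distance(points[sp[1], ], points[sp[2], ]))
}

#' Leaf and vein polygon areas
#'
#' Shoelace areas of the configured boundary and vein cycles; `vein_area` is
#' the sum of the three vein polygon areas and `blade_area` the difference
#' between total and vein area.
#'
#' @inheritParams vein_lengths
#' @param check_simple Passed to [shoelace_area()].
#' @return Named numeric vector with `total_area`, `mid_vein_area`,
#'   `prox_vein_area`, `dist_vein_area`, `vein_area`, `blade_area` (cm^2).
#' @export
leaf_areas <- function(points, cfg = polygon_config(), check_simple = FALSE) {
  points <- .as_vertex_matrix(points)
  if (nrow(points) != 21L) stop("leaf_areas: 21 landmarks required", call. = FALSE)
  area_of <- function(idx) {
    as.numeric(shoelace_area(points[idx, , drop = FALSE], check_simple = check_simple))
  }
  total <- area_of(cfg$boundary)
  mid <- area_of(cfg$mid)
  prox <- area_of(cfg$prox)
  dist <- area_of(cfg$dist)
  vein <- mid + prox + dist
  blade <- total - vein
  if (blade <= 0) {
    stop("inconsistent-geometry: vein polygons exceed the leaf boundary ",
         sprintf("(total %.4g, vein %.4g)", total, vein), call. = FALSE)
  }
  c(total_area = total, mid_vein_area = mid, prox_vein_area = prox,
    dist_vein_area = dist, vein_area = vein, blade_area = blade)
}

#' The six shape ratios
#'
#' `veins_to_blade` is the natural log of vein area over blade area; the four
#' length ratios are L4/L2, L4/L1, L2/L1, L3/L1; `petiolar_sinus_to_area` is
#' L5 over the total leaf area (cm^-1).
#'
#' @param lengths Named vector from [vein_lengths()].
#' @param areas Named vector from [leaf_areas()].
#' @return Named numeric vector of the six shape traits.
#' @export
shape_ratios <- function(lengths, areas) {
  denoms <- c(prox_to_dist = unname(lengths["L2"]),
              prox_to_mid = unname(lengths["L1"]),
              dist_to_mid = unname(lengths["L1"]),
              xvii_to_mid = unname(lengths["L1"]),
              petiolar_sinus_to_area = unname(areas["total_area"]),
              veins_to_blade = unname(areas["blade_area"]))
  bad <- names(denoms)[!is.finite(denoms) | denoms <= 0]
  if (length(bad)) {
    stop("undefined-ratio: zero or invalid denominator for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (areas[["vein_area"]] <= 0) {
    stop("undefined-ratio: non-positive vein_area for veins_to_blade",
         call. = FALSE)
  }
  c(veins_to_blade = log(areas[["vein_area"]] / areas[["blade_area"]]),
    prox_to_dist = lengths[["L4"]] / lengths[["L2"]],
    prox_to_mid = lengths[["L4"]] / lengths[["L1"]],
    dist_to_mid = lengths[["L2"]] / lengths[["L1"]],
    xvii_to_mid = lengths[["L3"]] / lengths[["L1"]],
    petiolar_sinus_to_area = lengths[["L5"]] / areas[["total_area"]])
}

#' Compute the 16 phenotypes of one leaf
#'
#' Composes [vein_lengths()], [leaf_areas()] and [shape_ratios()] into the
#' full named phenotype vector (see [trait_names()]).
#'
#' @inheritParams leaf_areas
#' @return Named numeric vector of length 16.
#' @export
compute_traits <- function(points, cfg = polygon_config(), check_simple = FALSE) {
  lens <- vein_lengths(points, cfg)
  areas <- leaf_areas(points, cfg, check_simple = check_simple)
  ratios <- shape_ratios(lens, areas)
  out <- c(mid_vein_length = lens[["L1"]],
           prox_vein_length = lens[["L4"]],
           dist_vein_length = lens[["L2"]],
           xvii_vein_length = lens[["L3"]],
           areas[c("total_area", "blade_area", "vein_area",
                   "mid_vein_area", "prox_vein_area", "dist_vein_area")],
           ratios[c("veins_to_blade", "prox_to_dist", "prox_to_mid",
                    "dist_to_mid", "xvii_to_mid", "petiolar_sinus_to_area")])
  stopifnot(identical(names(out), trait_names()))
  out
}

#' Compute traits for every leaf in a landmark table
#'
#' Applies [compute_traits()] row-wise; rows whose geometry fails are
#' collected (with leaf id and message) into the `"errors"` attribute and
#' excluded from the result rather than aborting the run.
#'
#' @param df A `landmark_df` (see [read_landmarks()]).
#' @param cfg A [polygon_config()].
#' @return Data frame with the six metadata columns plus 16 trait columns;
#'   attribute `"errors"` holds a data frame of failed leaves.
#' @export
compute_traits_df <- function(df, cfg = polygon_config()) {
  res <- vector("list", nrow(df))
  errs <- list()
  for (i in seq_len(nrow(df))) {
    tr <- tryCatch(compute_traits(leaf_points(df, i), cfg),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        row = i, leaf_id = df$leaf_id[i], message = conditionMessage(tr),
        stringsAsFactors = FALSE)
    } else {
      res[[i]] <- tr
    }
  }
  keep <- !vapply(res, is.null, logical(1))
  out <- cbind(as.data.frame(df[keep, .landmark_meta_cols, drop = FALSE],
                             stringsAsFactors = FALSE),
               do.call(rbind, res[keep]))
  rownames(out) <- NULL
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), leaf_id = character(0), message = character(0))
  out
}
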