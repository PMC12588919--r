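#' Euclidean distance between two points
#'
#' Plain Pythagorean distance between two 2-D coordinate pairs, the primitive
#' behind all vein-length phenotypes.
#'
#' @param p,q Numeric vectors of length 2, `(x, y)` in cm.
#' @return Non-negative distance in cm.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != 2L || length(q) != 2L) {
    stop("invalid-coordinate: points must be (x, y) pairs", call. = FALSE)
  }
  if (!all(is.finite(p)) || !all(is.finite(q))) {
    stop("invalid-coordinate: non-finite coordinate", call. = FALSE)
  }
  sqrt(sum((p - q)^2))
}

midpoint <- function(p, q) (as.numeric(p) + as.numeric(q)) / 2

# orientation of the triplet (p, q, r); 0 = collinear
.orient <- function(px, py, qx, qy, rx, ry) {
  v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
  sign(v)
}

# do closed segments p1-p2 and p3-p4 intersect (including collinear overlap)?
.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (d1 != d2 && d3 != d4) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection test over all non-adjacent edges of the
#' closed cycle. Used by landmark quality control and by [shoelace_area()]
#' to flag cycles whose area is geometrically ambiguous.
#'
#' @param vertices Numeric matrix with 2 columns (x, y), one row per vertex,
#'   interpreted as a closed cycle.
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(vertices) {
  v <- .as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # skip adjacent edges (shared endpoint), including the wraparound pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_intersect(v[idx[i], ], v[idx[i + 1L], ],
                              v[idx[j], ], v[idx[j + 1L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

.as_vertex_matrix <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("vertices must be an n x 2 matrix", call. = FALSE)
  if (!all(is.finite(v))) {
    stop("invalid-coordinate: non-finite vertex", call. = FALSE)
  }
  storage.mode(v) <- "double"
  v
}

#' Polygon area by the shoelace formula
#'
#' Absolute value of the signed shoelace (surveyor's) sum over the closed
#' vertex cycle, so the result is invariant under cyclic rotation and
#' reversal of the vertex order.
#'
#' @param vertices Numeric matrix with 2 columns (x, y), >= 3 rows; the cycle
#'   closes from the last vertex back to the first.
#' @param check_simple If `TRUE` (default), self-intersecting cycles trigger a
#'   warning and the returned value carries attribute
#'   `self_intersecting = TRUE`; the area is still returned.
#' @return Area in cm^2 (non-negative scalar).
#' @examples
#' shoelace_area(rbind(c(0, 0), c(4, 0), c(0, 3))) # 6
#' @export
shoelace_area <- function(vertices, check_simple = TRUE) {
  v <- .as_vertex_matrix(vertices)
  n <- nrow(v)
  if (n < 3L) stop("shoelace_area needs at least 3 vertices", call. = FALSE)
  x <- v[, 1]
  y <- v[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  a <- abs(sum(x * yn - xn * y)) / 2
  if (isTRUE(check_simple) && !polygon_is_simple(v)) {
    warning("self-intersecting polygon: shoelace area may not equal the enclosed area",
            call. = FALSE)
    attr(a, "self_intersecting") <- TRUE
  }
  a
}
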