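# Independent oracles used by the tests. Deliberately naive implementations
# that never share code with the package.

# polygon area by triangulation: fan decomposition from a known kernel point
# (star-shaped polygons), else ear clipping (any simple polygon)
tri_area_oracle <- function(v, kernel_point = NULL) {
  v <- as.matrix(v)
  n <- nrow(v)
  stopifnot(n >= 3)
  if (!is.null(kernel_point)) {
    a <- 0
    for (i in seq_len(n)) {
      p <- v[i, ] - kernel_point
      q <- v[if (i == n) 1 else i + 1, ] - kernel_point
      a <- a + abs(p[1] * q[2] - p[2] * q[1]) / 2
    }
    return(a)
  }
  cross3 <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  # orientation from the bottom-most (then left-most) vertex, which is convex
  i0 <- order(v[, 2], v[, 1])[1]
  prev <- function(i, n) if (i == 1) n else i - 1
  nxt <- function(i, n) if (i == n) 1 else i + 1
  orient <- sign(cross3(v[prev(i0, n), ], v[i0, ], v[nxt(i0, n), ]))
  in_tri <- function(p, a, b, c) {
    d1 <- cross3(a, b, p); d2 <- cross3(b, c, p); d3 <- cross3(c, a, p)
    !(any(c(d1, d2, d3) < 0) && any(c(d1, d2, d3) > 0))
  }
  idx <- seq_len(n)
  area <- 0
  guard <- 0
  while (length(idx) > 3) {
    m <- length(idx)
    clipped <- FALSE
    for (j in seq_len(m)) {
      a <- v[idx[if (j == 1) m else j - 1], ]
      b <- v[idx[j], ]
      c <- v[idx[if (j == m) 1 else j + 1], ]
      if (sign(cross3(a, b, c)) * orient <= 0) next # reflex or degenerate
      others <- idx[-c(if (j == 1) m else j - 1, j, if (j == m) 1 else j + 1)]
      blocked <- FALSE
      for (o in others) {
        if (in_tri(v[o, ], a, b, c)) { blocked <- TRUE; break }
      }
      if (blocked) next
      area <- area + abs(cross3(a, b, c)) / 2
      idx <- idx[-j]
      clipped <- TRUE
      break
    }
    guard <- guard + 1
    if (!clipped || guard > 10000) stop("ear clipping failed (polygon not simple?)")
  }
  a <- v[idx[1], ]; b <- v[idx[2], ]; c <- v[idx[3], ]
  area + abs(cross3(a, b, c)) / 2
}

# random simple (star-shaped) polygon generator; the generating center is a
# kernel point, attached for the fan-triangulation oracle
random_simple_polygon <- function(n_vertices, center = stats::runif(2, -5, 5)) {
  # angular gaps normalized to wrap the full circle, so the polygon always
  # encloses `center` and is simple (star-shaped about it)
  gaps <- stats::runif(n_vertices, 0.2, 1)
  ang <- 2 * pi * cumsum(gaps) / sum(gaps)
  rad <- stats::runif(n_vertices, 0.5, 3)
  out <- cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  attr(out, "center") <- center
  out
}

# Kruskal-Wallis H by direct rank arithmetic with tie correction
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  t <- table(values)
  h / (1 - sum(t^3 - t) / (N^3 - N))
}

# hypergeometric upper-tail by explicit density summation
hyper_tail_oracle <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# rigid motion of a point matrix
apply_motion <- function(pts, theta = 0, dx = 0, dy = 0, mirror = FALSE) {
  if (mirror) pts[, 1] <- -pts[, 1]
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(pts %*% t(R), 2, c(dx, dy), "+")
}
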