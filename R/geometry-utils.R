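# Low-level planar geometry used by rasterization and coordinate estimation.
# Conventions: continuous pixel coordinates are 0-based, x = column, y = row;
# the center of array element [i, j] is (x = j - 1, y = i - 1).

#' Signed polygon area (shoelace)
#'
#' Positive for anticlockwise vertex order in a y-down image frame traversed
#' with increasing x to the right.
#'
#' @param xy two-column matrix of vertices (x, y), open (no repeated last row).
#' @return signed area in squared pixel units.
#' @keywords internal
polygon_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Polygon centroid (area-weighted)
#' @inheritParams polygon_area
#' @return numeric length-2 (x, y).
#' @keywords internal
polygon_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((xy[, 1] + xy[j, 1]) * cr), sum((xy[, 2] + xy[j, 2]) * cr)) / (6 * a)
}

# TRUE where segments (p1,p2) and (p3,p4) properly intersect (shared endpoints
# between adjacent edges are handled by the caller).
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Is a closed polygon simple (non-self-intersecting)?
#' @inheritParams polygon_area
#' @keywords internal
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(2:n, 1L))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # skip adjacent edges (share a vertex)
      if (abs(a - b) <= 1 || (a == 1 && b == n)) next
      if (.segments_cross(xy[idx[a, 1], ], xy[idx[a, 2], ],
                          xy[idx[b, 1], ], xy[idx[b, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Vectorized point-in-polygon (even-odd rule)
#'
#' Points whose distance to the polygon boundary is below `eps` count as
#' inside (deterministic boundary tie-break).
#'
#' @param px,py point coordinates (equal length).
#' @param xy polygon vertex matrix, open.
#' @param eps boundary tolerance in pixels.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, xy, eps = 1e-9) {
  n <- nrow(xy)
  jn <- c(2:n, 1L)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  eps2 <- eps^2
  for (k in seq_len(n)) {
    ax <- xy[k, 1]; ay <- xy[k, 2]
    bx <- xy[jn[k], 1]; by <- xy[jn[k], 2]
    crosses <- (ay > py) != (by > py)
    if (any(crosses)) {
      xint <- ax + (py - ay) * (bx - ax) / (by - ay)
      hit <- crosses & (px < xint)
      hit[is.na(hit)] <- FALSE
      inside <- xor(inside, hit)
    }
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    tt <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + tt * vx); dy <- py - (ay + tt * vy)
    onedge <- onedge | (dx * dx + dy * dy <= eps2)
  }
  inside | onedge
}

#' Unsigned Euclidean distance from points to a closed polyline
#' @inheritParams point_in_polygon
#' @return numeric vector of distances (pixels).
#' @keywords internal
dist_to_polyline <- function(px, py, xy) {
  n <- nrow(xy)
  jn <- c(2:n, 1L)
  best <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    ax <- xy[k, 1]; ay <- xy[k, 2]
    bx <- xy[jn[k], 1]; by <- xy[jn[k], 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    tt <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + tt * vx); dy <- py - (ay + tt * vy)
    d2 <- dx * dx + dy * dy
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Rasterize a polygon onto a pixel grid
#'
#' Pixel-center-in-polygon with the even-odd rule; centers exactly on an edge
#' are in. With `oversample > 1` the grid is refined in-plane and fine pixel
#' centers are tested directly against the polygon.
#'
#' @param xy polygon vertex matrix (0-based pixel coordinates).
#' @param dim integer c(nrow, ncol) of the base grid.
#' @param oversample integer in-plane refinement factor.
#' @return logical matrix of dimension `dim * oversample`.
#' @keywords internal
rasterize_polygon <- function(xy, dim, oversample = 1L) {
  s <- as.integer(oversample)
  nr <- dim[1] * s; nc <- dim[2] * s
  out <- matrix(FALSE, nr, nc)
  # restrict to the polygon's bounding box (fine-grid indices)
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  j0 <- max(1L, floor((xr[1] + 0.5) * s)); j1 <- min(nc, ceiling((xr[2] + 1.5) * s))
  i0 <- max(1L, floor((yr[1] + 0.5) * s)); i1 <- min(nr, ceiling((yr[2] + 1.5) * s))
  if (j0 > j1 || i0 > i1) return(out)
  jj <- j0:j1; ii <- i0:i1
  xs <- (jj - 0.5) / s - 0.5
  ys <- (ii - 0.5) / s - 0.5
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  out[cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))] <-
    point_in_polygon(px, py, xy)
  out
}

#' Coordinates of fine-grid pixel centers
#' @keywords internal
fine_grid_centers <- function(dim, oversample = 1L) {
  s <- as.integer(oversample)
  nr <- dim[1] * s; nc <- dim[2] * s
  list(
    x = matrix(rep((seq_len(nc) - 0.5) / s - 0.5, each = nr), nr, nc),
    y = matrix(rep((seq_len(nr) - 0.5) / s - 0.5, times = nc), nr, nc)
  )
}

# circular helpers on [0, 1)
circ_wrap <- function(x) x - floor(x)

# signed circular difference a - b mapped to (-0.5, 0.5]
circ_diff <- function(a, b) {
  d <- circ_wrap(a - b)
  ifelse(d > 0.5, d - 1, d)
}

#' Regular polygon approximation of a circle
#' @keywords internal
circle_polygon <- function(center, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
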