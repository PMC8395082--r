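#' Hand-drawn region-of-interest polygon
#'
#' A closed polygon in pixel coordinates (0-based, x right, y down; the
#' centre of pixel (0,0) is at coordinate (0, 0)). Used for whole-cell
#' and plasma-membrane-band intensity quantification.
#'
#' @param vertices Two-column matrix or data frame of (x, y) vertices in
#'   pixel units, in drawing order; at least 3 vertices. The polygon is
#'   treated as closed (last vertex joins the first).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) < 2L) stop("`vertices` needs x and y columns", call. = FALSE)
  v <- v[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ])) {
    v <- v[-nrow(v), , drop = FALSE]  # drop explicit closing vertex
  }
  if (nrow(v) < 3L) stop("a polygon needs >= 3 vertices", call. = FALSE)
  if (anyNA(v)) stop("vertices contain NA", call. = FALSE)
  if (polygon_self_intersects(v)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  structure(list(vertices = v, closed = TRUE), class = "roi_polygon")
}

#' Read an ROI polygon from a CSV vertex list
#'
#' Expects columns `x` and `y` with vertex coordinates in pixels.
#'
#' @param path CSV file path.
#' @return An [roi_polygon()].
#' @export
read_roi_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("x", "y") %in% names(d))) {
    stop("ROI CSV must have columns `x` and `y`", call. = FALSE)
  }
  roi_polygon(d[, c("x", "y")])
}

# Proper segment-segment intersection test between non-adjacent edges.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (they share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Even-odd point-in-polygon, vectorized over query points.
points_in_polygon <- function(px, py, roi) {
  v <- roi$vertices
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from points to the polygon boundary (min over edges).
dist_to_polygon_boundary <- function(px, py, roi) {
  v <- roi$vertices
  n <- nrow(v)
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- v[j, 1]; ay <- v[j, 2]
    bx <- v[i, 1]; by <- v[i, 2]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx^2 + aby^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * abx + (py - ay) * aby) / len2))
    dx <- px - (ax + t * abx)
    dy <- py - (ay + t * aby)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
    j <- i
  }
  dmin
}

# Logical mask of pixels (centres) inside the polygon, for an nr x nc image.
roi_mask <- function(roi, nrow_img, ncol_img) {
  xs <- rep(seq_len(ncol_img) - 1L, each = nrow_img)
  ys <- rep(seq_len(nrow_img) - 1L, times = ncol_img)
  matrix(points_in_polygon(xs, ys, roi), nrow_img, ncol_img)
}
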