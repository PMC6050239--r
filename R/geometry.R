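# Planar geometry primitives for pond polygons and reach polylines.
# Coordinates are planar Cartesian metres throughout; no projections.

#' Parse a WKT POLYGON into its rings
#'
#' Minimal reader for `POLYGON ((x y, ...))` and `POLYGON ((...), (...))`
#' (exterior ring first, holes after), planar coordinates.
#'
#' @param wkt length-one character, WKT `POLYGON`.
#' @return List of numeric matrices (n x 2), one per ring; rings are closed
#'   (first vertex repeated last) as stored in the WKT.
#' @export
wkt_polygon <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1L)
  s <- trimws(wkt)
  if (!grepl("^POLYGON", s, ignore.case = TRUE))
    stop("not a WKT POLYGON: ", substr(s, 1, 30))
  body <- sub("^POLYGON\\s*\\(", "", s, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  rings <- regmatches(body, gregexpr("\\(([^()]*)\\)", body))[[1]]
  if (length(rings) == 0L) stop("empty POLYGON body")
  lapply(rings, function(r) {
    r <- gsub("[()]", "", r)
    parse_coord_seq(r)
  })
}

#' Parse a WKT LINESTRING
#' @param wkt length-one character, WKT `LINESTRING`.
#' @return Numeric matrix (n x 2) of vertices.
#' @export
wkt_linestring <- function(wkt) {
  stopifnot(is.character(wkt), length(wkt) == 1L)
  s <- trimws(wkt)
  if (!grepl("^LINESTRING", s, ignore.case = TRUE))
    stop("not a WKT LINESTRING: ", substr(s, 1, 30))
  body <- sub("^LINESTRING\\s*\\(", "", s, ignore.case = TRUE)
  body <- sub("\\)\\s*$", "", body)
  parse_coord_seq(body)
}

parse_coord_seq <- function(txt) {
  pts <- strsplit(trimws(txt), "\\s*,\\s*")[[1]]
  xy <- vapply(pts, function(p) {
    v <- as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    if (length(v) < 2L || anyNA(v[1:2])) stop("bad coordinate: ", p)
    v[1:2]
  }, numeric(2))
  t(xy)
}

#' Serialize a ring to WKT POLYGON text
#' @param ring numeric matrix (n x 2); closed automatically if open.
#' @param digits significant digits written.
#' @return length-one character.
#' @export
wkt_from_ring <- function(ring, digits = 10) {
  ring <- close_ring(ring)
  coords <- apply(ring, 1, function(p)
    paste(format(p, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " "))
  paste0("POLYGON ((", paste(coords, collapse = ", "), "))")
}

close_ring <- function(ring) {
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE)))
    ring <- rbind(ring, ring[1, ])
  ring
}

# shoelace signed area; positive for counter-clockwise rings
ring_signed_area <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

ring_perimeter <- function(ring) {
  ring <- close_ring(ring)
  sum(sqrt(rowSums(diff(ring)^2)))
}

# area-weighted (shoelace) centroid of a simple ring
ring_centroid <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, max(abs(ring))))
    stop("degenerate polygon: zero area")
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}

#' Area, perimeter and centroid of a (possibly holed) polygon
#'
#' Net area subtracts interior rings; the perimeter is the exterior ring's
#' length (holes excluded); the centroid is the net-area centroid.
#'
#' @param rings list of rings as returned by [wkt_polygon()], or a single
#'   matrix ring.
#' @return list with `area` (m^2), `perimeter` (m), `centroid` (length-2).
#' @export
polygon_properties <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  areas <- vapply(rings, ring_area, numeric(1))
  cents <- vapply(rings, ring_centroid, numeric(2))
  # exterior = largest-area ring; remaining rings are holes
  ext <- which.max(areas)
  sgn <- rep(-1, length(rings)); sgn[ext] <- 1
  net <- sum(sgn * areas)
  if (net <= 0) stop("degenerate polygon: non-positive net area")
  cen <- as.numeric(cents %*% (sgn * areas)) / net
  list(area = net, perimeter = ring_perimeter(rings[[ext]]), centroid = cen)
}

polyline_length <- function(line) {
  if (nrow(line) < 2L) return(0)
  sum(sqrt(rowSums(diff(line)^2)))
}

#' Point at half the arc length of a polyline
#' @param line numeric matrix (n x 2).
#' @return length-2 numeric point.
#' @export
polyline_midpoint <- function(line) {
  if (nrow(line) < 2L) return(line[1, ])
  seg <- sqrt(rowSums(diff(line)^2))
  cum <- c(0, cumsum(seg))
  half <- cum[length(cum)] / 2
  i <- findInterval(half, cum, rightmost.closed = TRUE)
  i <- min(i, length(seg))
  f <- if (seg[i] > 0) (half - cum[i]) / seg[i] else 0
  line[i, ] + f * (line[i + 1, ] - line[i, ])
}

#' Elliptical pond outline
#'
#' Vertex ring of an ellipse with given centre, semi-axes and rotation.
#'
#' @param center length-2 numeric.
#' @param a,b semi-major / semi-minor axes (m).
#' @param theta rotation of the major axis (radians).
#' @param n number of vertices.
#' @return numeric matrix (n x 2), open ring.
#' @export
ellipse_ring <- function(center, a, b, theta = 0, n = 64L) {
  stopifnot(a > 0, b > 0, n >= 8L)
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  ct <- cos(theta); st <- sin(theta)
  cbind(center[1] + ct * x - st * y,
        center[2] + st * x + ct * y)
}

#' Ramanujan's approximation to the ellipse perimeter
#'
#' First Ramanujan approximation; relative error below 1e-4 for
#' aspect ratios up to about 20.
#'
#' @param a,b semi-axes (m).
#' @return perimeter (m).
#' @export
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}
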