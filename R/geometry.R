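# Planar geometry primitives used by the range and habitat modules.
# Rings are 2-column (x, y) matrices, not closed (last vertex != first);
# a "polygon set" is a list of disjoint rings treated as a union.

#' Polygon area by the shoelace formula
#'
#' @param ring two-column matrix of vertex coordinates (meters), open ring.
#' @return Absolute area in the square of the coordinate unit.
#' @examples
#' ring_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
ring_area <- function(ring) abs(signed_ring_area(ring))

signed_ring_area <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

as_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L) stop("a ring must be a two-column (x, y) matrix")
  if (!all(is.finite(ring))) stop("ring coordinates must be finite")
  # drop an explicit closing vertex
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L) stop("a ring needs at least three distinct vertices")
  ring
}

polygon_set_area <- function(polys) {
  if (is.matrix(polys)) polys <- list(polys)
  sum(vapply(polys, ring_area, numeric(1)))
}

# Even-odd (ray casting) point-in-ring test; boundary points count as inside.
point_in_ring <- function(px, py, ring) {
  ring <- as_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_polys <- function(px, py, polys) {
  if (is.matrix(polys)) polys <- list(polys)
  inside <- rep(FALSE, length(px))
  for (ring in polys) inside <- inside | point_in_ring(px, py, ring)
  inside
}

# Sutherland-Hodgman: clip `subject` (any simple ring) against one half-plane
# a*x + b*y <= c.
clip_halfplane <- function(subject, a, b, c) {
  n <- nrow(subject)
  if (n == 0L) return(subject)
  out_x <- numeric(0); out_y <- numeric(0)
  sx <- subject[n, 1]; sy <- subject[n, 2]
  s_in <- a * sx + b * sy <= c + 1e-12
  for (i in seq_len(n)) {
    ex <- subject[i, 1]; ey <- subject[i, 2]
    e_in <- a * ex + b * ey <= c + 1e-12
    if (e_in != s_in) {
      t <- (c - a * sx - b * sy) / (a * (ex - sx) + b * (ey - sy))
      out_x <- c(out_x, sx + t * (ex - sx)); out_y <- c(out_y, sy + t * (ey - sy))
    }
    if (e_in) { out_x <- c(out_x, ex); out_y <- c(out_y, ey) }
    sx <- ex; sy <- ey; s_in <- e_in
  }
  cbind(out_x, out_y, deparse.level = 0)
}

# Clip a simple ring by an axis-aligned rectangle (exact, rectangle is convex).
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  ring <- as_ring(ring)
  out <- clip_halfplane(ring, -1, 0, -xmin)
  if (nrow(out) > 0L) out <- clip_halfplane(out, 1, 0, xmax)
  if (nrow(out) > 0L) out <- clip_halfplane(out, 0, -1, -ymin)
  if (nrow(out) > 0L) out <- clip_halfplane(out, 0, 1, ymax)
  out
}

# Clip a simple ring by a convex ring (Sutherland-Hodgman over its edges).
clip_ring_convex <- function(subject, clip) {
  subject <- as_ring(subject)
  clip <- as_ring(clip)
  if (signed_ring_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  n <- nrow(clip)
  out <- subject
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # edge i -> j, interior on the left for a CCW ring:
    # half-plane (y_j - y_i) x - (x_j - x_i) y <= x_i y_j - x_j y_i ... derive:
    a <- clip[j, 2] - clip[i, 2]
    b <- clip[i, 1] - clip[j, 1]
    c <- a * clip[i, 1] + b * clip[i, 2]
    out <- clip_halfplane(out, a, b, c)
    if (nrow(out) == 0L) break
  }
  out
}

is_convex_ring <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  v <- ring[c(2:n, 1L), ] - ring
  cross <- v[, 1] * v[c(2:n, 1L), 2] - v[, 2] * v[c(2:n, 1L), 1]
  all(cross >= -1e-9) || all(cross <= 1e-9)
}

## ---- regular grids -------------------------------------------------------

#' Define a regular planar grid
#'
#' Grids are axis-aligned with square cells; cell `(i, j)` has its center at
#' `(xmin + (i - 0.5) cs, ymin + (j - 0.5) cs)`.
#'
#' @param xmin,ymin lower-left corner of the grid (meters).
#' @param nx,ny number of columns / rows.
#' @param cell_size cell side length in meters.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymin, nx, ny, cell_size) {
  stopifnot(nx >= 1, ny >= 1, cell_size > 0, is.finite(xmin), is.finite(ymin))
  structure(list(xmin = xmin, ymin = ymin, nx = as.integer(nx),
                 ny = as.integer(ny), cell_size = cell_size),
            class = "grid_spec")
}

grid_centers <- function(grid) {
  cs <- grid$cell_size
  list(x = grid$xmin + (seq_len(grid$nx) - 0.5) * cs,
       y = grid$ymin + (seq_len(grid$ny) - 0.5) * cs)
}

# column/row index of the cell containing each point; NA outside the grid.
cell_index <- function(grid, x, y) {
  cs <- grid$cell_size
  ix <- floor((x - grid$xmin) / cs) + 1L
  iy <- floor((y - grid$ymin) / cs) + 1L
  bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  cbind(ix = as.integer(ix), iy = as.integer(iy))
}

## ---- cell-union boundary tracing -----------------------------------------

# Turn a logical nx x ny cell mask into boundary rings. Each TRUE cell
# contributes its four CCW-directed edges on the corner lattice; edges shared
# by two cells appear in opposite directions and cancel, and the survivors are
# stitched into closed rings (outer rings CCW, holes CW — interior kept on
# the left throughout).
polygonize_cells <- function(mask, grid) {
  stopifnot(is.matrix(mask), nrow(mask) == grid$nx, ncol(mask) == grid$ny)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  nxc <- grid$nx + 1L   # corners per lattice row
  corner_id <- function(ci, cj) ci + 1L + (cj) * nxc  # ci, cj in 0..nx / 0..ny
  i <- idx[, 1]; j <- idx[, 2]
  ll <- corner_id(i - 1L, j - 1L); lr <- corner_id(i, j - 1L)
  ur <- corner_id(i, j);           ul <- corner_id(i - 1L, j)
  from <- c(ll, lr, ur, ul)
  to   <- c(lr, ur, ul, ll)
  # cancel edge pairs traversed in both directions
  key <- paste(pmin(from, to), pmax(from, to))
  dup <- key %in% key[duplicated(key)]
  from <- from[!dup]; to <- to[!dup]
  if (length(from) == 0L) return(list())

  corner_xy <- function(id) {
    id0 <- id - 1L
    cbind(grid$xmin + (id0 %% nxc) * grid$cell_size,
          grid$ymin + (id0 %/% nxc) * grid$cell_size)
  }
  # outgoing edges per vertex
  out_by_from <- split(seq_along(from), from)
  used <- rep(FALSE, length(from))
  rings <- list()
  dir_of <- function(e) {
    d <- corner_xy(to[e]) - corner_xy(from[e])
    c(sign(d[1]), sign(d[2]))
  }
  for (start in seq_along(from)) {
    if (used[start]) next
    path <- integer(0)
    e <- start
    repeat {
      used[e] <- TRUE
      path <- c(path, e)
      if (to[e] == from[start]) break   # ring closed
      nxt <- out_by_from[[as.character(to[e])]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      if (length(nxt) > 1L) {
        # at a corner where boundaries touch diagonally: take the sharpest
        # left turn so each ring stays simple
        d_in <- dir_of(e)
        turn <- vapply(nxt, function(k) {
          d_out <- dir_of(k)
          atan2(d_in[1] * d_out[2] - d_in[2] * d_out[1],
                d_in[1] * d_out[1] + d_in[2] * d_out[2])
        }, numeric(1))
        nxt <- nxt[which.max(turn)]
      }
      e <- nxt
    }
    verts <- corner_xy(from[path])
    rings[[length(rings) + 1L]] <- verts
  }
  rings
}
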