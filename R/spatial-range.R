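# Representative range and core area: kernel utilization distributions with
# LSCV bandwidths, isopleth extraction, minimum convex polygon, and polygon
# overlay arithmetic. All coordinates are projected meters.

#' Keep one record per school per day
#'
#' Repeated records of the same school on the same day are not independent;
#' only the earliest record of each (school, date) pair is retained.
#'
#' @param sightings data frame with at least columns `id`, `date` and,
#'   optionally, `time` (any orderable representation; rows are kept in
#'   ascending `time` order within a day, or input order if absent).
#' @return The deduplicated data frame, original column set preserved.
#' @export
dedupe_daily <- function(sightings) {
  stopifnot(is.data.frame(sightings), all(c("id", "date") %in% names(sightings)))
  ord <- if ("time" %in% names(sightings)) {
    order(sightings$id, sightings$date, sightings$time)
  } else {
    seq_len(nrow(sightings))
  }
  s <- sightings[ord, , drop = FALSE]
  keep <- !duplicated(s[, c("id", "date")])
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Least-squares cross-validation bandwidth for a bivariate Gaussian kernel
#'
#' Minimizes the standard LSCV score for a product Gaussian kernel with a
#' common bandwidth in both coordinates, over a log-spaced grid bracketed by
#' `[0.05, 2]` times the bivariate normal-reference bandwidth
#' `h_ref = sigma * n^(-1/6)`, with `sigma^2` the mean of the coordinate
#' variances. If the score is monotone over the bracket (minimum at an
#' endpoint) the normal-reference bandwidth is returned with a warning.
#'
#' @param points two-column matrix or data frame of projected coordinates (m).
#' @param n_grid number of candidate bandwidths.
#' @return Bandwidth in meters, with attributes `method` (`"lscv"` or
#'   `"reference"`), `h_ref`, `grid` and `score`.
#' @export
lscv_bandwidth <- function(points, n_grid = 50L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 10L) stop("need at least 10 points for LSCV")
  sig2 <- (var(pts[, 1]) + var(pts[, 2])) / 2
  if (!is.finite(sig2) || sig2 <= 0) stop("degenerate point set: no spread")
  h_ref <- sqrt(sig2) * n^(-1 / 6)
  d2 <- as.vector(dist(pts))^2        # n(n-1)/2 pairwise squared distances
  hs <- exp(seq(log(0.05 * h_ref), log(2 * h_ref), length.out = n_grid))
  score <- vapply(hs, function(h) {
    t1 <- (n + 2 * sum(exp(-d2 / (4 * h^2)))) / (4 * pi * h^2 * n^2)
    t2 <- 2 * sum(exp(-d2 / (2 * h^2))) / (pi * h^2 * n * (n - 1))
    t1 - t2
  }, numeric(1))
  k <- which.min(score)
  if (k == 1L || k == n_grid) {
    warning("LSCV score is monotone on the bracket; using the normal-reference bandwidth")
    h <- h_ref
    method <- "reference"
  } else {
    h <- hs[k]
    method <- "lscv"
  }
  structure(h, method = method, h_ref = h_ref, grid = hs, score = score)
}

#' Kernel utilization distribution on a regular grid
#'
#' Bivariate Gaussian product-kernel density of the sighting locations,
#' evaluated at cell centers and renormalized so that
#' `sum(density) * cell_size^2 = 1`.
#'
#' @param points two-column matrix or data frame of projected coordinates (m).
#' @param bandwidth kernel standard deviation in meters.
#' @param cell_size grid resolution in meters (default 250).
#' @param grid optional [grid_spec()]; when omitted, a grid covering the
#'   points plus `pad_bandwidths` bandwidths of padding is built. A supplied
#'   grid must cover every point plus 3 bandwidths.
#' @param pad_bandwidths padding, in bandwidths, around the point cloud.
#' @return An object of class `ud_surface`: list with `grid` and `density`
#'   (an `nx` by `ny` matrix, per square meter).
#' @export
kernel_ud <- function(points, bandwidth, cell_size = 250, grid = NULL,
                      pad_bandwidths = 3) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  stopifnot(nrow(pts) >= 1, all(is.finite(pts)))
  if (!is.finite(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  h <- as.numeric(bandwidth)
  if (is.null(grid)) {
    pad <- pad_bandwidths * h
    xmin <- min(pts[, 1]) - pad; xmax <- max(pts[, 1]) + pad
    ymin <- min(pts[, 2]) - pad; ymax <- max(pts[, 2]) + pad
    grid <- grid_spec(xmin, ymin,
                      nx = ceiling((xmax - xmin) / cell_size),
                      ny = ceiling((ymax - ymin) / cell_size),
                      cell_size = cell_size)
  } else {
    cs <- grid$cell_size
    if (min(pts[, 1]) - 3 * h < grid$xmin || max(pts[, 1]) + 3 * h > grid$xmin + grid$nx * cs ||
        min(pts[, 2]) - 3 * h < grid$ymin || max(pts[, 2]) + 3 * h > grid$ymin + grid$ny * cs)
      stop("grid must cover all points plus 3 bandwidths of padding")
  }
  ctr <- grid_centers(grid)
  kx <- dnorm(outer(ctr$x, pts[, 1], "-"), sd = h)   # nx x n
  ky <- dnorm(outer(ctr$y, pts[, 2], "-"), sd = h)   # ny x n
  dens <- (kx %*% t(ky)) / nrow(pts)
  dens <- dens / (sum(dens) * grid$cell_size^2)
  structure(list(grid = grid, density = dens), class = "ud_surface")
}

#' Utilization-distribution isopleth
#'
#' Selects the smallest set of grid cells whose probability mass reaches
#' `level` (descending-density thresholding), polygonizes their union, and
#' reports the enclosed area.
#'
#' @param surface a `ud_surface` from [kernel_ud()].
#' @param level isopleth level in (0, 1), e.g. 0.95 for the representative
#'   range or 0.50 for the core area.
#' @return An object of class `range_estimate`: list with `level`, `grid`,
#'   `mask` (logical cell-inclusion matrix), `polygons` (list of boundary
#'   rings; outer rings counter-clockwise, holes clockwise), `area_km2`, and
#'   `mass` (probability mass actually enclosed).
#' @export
isopleth <- function(surface, level) {
  stopifnot(inherits(surface, "ud_surface"), level > 0, level < 1)
  grid <- surface$grid
  mass <- as.vector(surface$density) * grid$cell_size^2
  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level * cum[length(cum)])[1L]
  mask <- matrix(FALSE, grid$nx, grid$ny)
  mask[ord[seq_len(k)]] <- TRUE
  structure(list(level = level, grid = grid, mask = mask,
                 polygons = polygonize_cells(mask, grid),
                 area_km2 = sum(mask) * grid$cell_size^2 / 1e6,
                 mass = cum[k]),
            class = "range_estimate")
}

#' @export
print.range_estimate <- function(x, ...) {
  cat(sprintf("%g%% UD isopleth: %.1f km2 (%d cells of %g m, %d ring%s)\n",
              100 * x$level, x$area_km2, sum(x$mask), x$grid$cell_size,
              length(x$polygons), if (length(x$polygons) == 1L) "" else "s"))
  invisible(x)
}

#' Minimum convex polygon and its area
#'
#' Convex hull of occurrence locations — the IUCN-recommended estimator of
#' extent of occurrence (EOO). Records flagged as vagrant can be excluded.
#'
#' @param points two-column matrix or data frame of projected coordinates (m).
#' @param vagrant optional logical vector marking vagrant/extralimital
#'   records.
#' @param exclude_outliers if `TRUE`, rows with `vagrant = TRUE` are dropped
#'   before the hull is taken.
#' @return List with `polygon` (counter-clockwise hull ring) and `area_km2`.
#' @export
mcp_area <- function(points, vagrant = NULL, exclude_outliers = FALSE) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (exclude_outliers && !is.null(vagrant)) pts <- pts[!vagrant, , drop = FALSE]
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (nrow(unique(pts)) < 3L) stop("need at least 3 distinct points for an MCP")
  hull <- pts[chull(pts), , drop = FALSE]          # chull returns clockwise
  if (nrow(hull) < 3L) stop("points are collinear; MCP undefined")
  hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  a <- signed_ring_area(hull)
  if (abs(a) < 1e-9) stop("points are collinear; MCP undefined")
  list(polygon = hull, area_km2 = abs(a) / 1e6)
}

#' Fraction of a range inside reference polygons
#'
#' Computes `area(range intersect reference) / area(range)` — e.g. the
#' share of a representative range inside marine-park zones or a proposed
#' development footprint. Intersection areas are exact: cell-based ranges
#' are clipped rectangle by rectangle, plain convex rings by
#' Sutherland-Hodgman clipping.
#'
#' @param range a `range_estimate` (cell-based) or a single convex ring.
#' @param reference a ring, or list of disjoint rings, in the same
#'   projection.
#' @return List with `fraction` and `area_km2` of the intersection.
#' @export
overlay_fraction <- function(range, reference) {
  if (is.matrix(reference) || is.data.frame(reference))
    reference <- list(as.matrix(reference))
  reference <- lapply(reference, as_ring)
  if (inherits(range, "range_estimate")) {
    grid <- range$grid; cs <- grid$cell_size
    idx <- which(range$mask, arr.ind = TRUE)
    inter <- 0
    for (ring in reference) {
      bb <- apply(ring, 2, range)
      x0 <- grid$xmin + (idx[, 1] - 1L) * cs
      y0 <- grid$ymin + (idx[, 2] - 1L) * cs
      cand <- which(x0 < bb[2, 1] & x0 + cs > bb[1, 1] &
                    y0 < bb[2, 2] & y0 + cs > bb[1, 2])
      for (k in cand) {
        clp <- clip_ring_rect(ring, x0[k], x0[k] + cs, y0[k], y0[k] + cs)
        if (nrow(clp) >= 3L) inter <- inter + ring_area(clp)
      }
    }
    range_area <- sum(range$mask) * cs^2
  } else {
    rng <- as_ring(as.matrix(range))
    if (!is_convex_ring(rng))
      stop("plain-ring ranges must be convex; use a range_estimate for general shapes")
    inter <- 0
    for (ring in reference) {
      clp <- clip_ring_convex(ring, rng)
      if (nrow(clp) >= 3L) inter <- inter + ring_area(clp)
    }
    range_area <- ring_area(rng)
  }
  if (range_area <= 0) stop("range has zero area")
  list(fraction = inter / range_area, area_km2 = inter / 1e6)
}

#' Erase avoided habitat from a range
#'
#' Removes, at the habitat grid's resolution, the cells belonging to habitat
#' classes used less often than expected (avoided classes) from a range
#' polygon, yielding the preferred-habitat area. The habitat grid must be
#' aligned with and nested in the range grid (its cell size an integer
#' divisor of the range cell size).
#'
#' @param range a `range_estimate`.
#' @param habitat a `habitat_grid` from [classify_depth()].
#' @param avoided integer or character vector of avoided class indices or
#'   labels (empty for none).
#' @return List with `area_km2` of the remaining preferred habitat, `mask`
#'   (logical matrix at habitat-grid resolution) and `polygons`.
#' @export
erase_avoided <- function(range, habitat, avoided) {
  stopifnot(inherits(range, "range_estimate"), inherits(habitat, "habitat_grid"))
  hg <- habitat$grid; rg <- range$grid
  ratio <- rg$cell_size / hg$cell_size
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("habitat cell size must divide the range cell size")
  if (is.character(avoided)) avoided <- match(avoided, habitat$labels)
  ctr <- grid_centers(hg)
  cx <- rep(ctr$x, times = hg$ny); cy <- rep(ctr$y, each = hg$nx)
  ci <- cell_index(rg, cx, cy)
  inside <- !is.na(ci[, 1]) & range$mask[cbind(ci[, 1], ci[, 2])]
  inside <- matrix(inside, hg$nx, hg$ny)
  avoided_mask <- matrix(as.vector(habitat$class) %in% avoided, hg$nx, hg$ny)
  keep <- inside & !avoided_mask
  list(area_km2 = sum(keep) * hg$cell_size^2 / 1e6,
       mask = keep,
       polygons = polygonize_cells(keep, hg))
}
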