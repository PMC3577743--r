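# Plain-text interchange: sightings/soundings CSV, capture-history CSV and
# MARK .inp, polygons as GeoJSON, UD grids as ESRI ASCII rasters. All
# coordinates are projected meters (e.g. UTM); nothing geodesic.

#' Read a sightings CSV
#'
#' Expects columns `id`, `date`, `x`, `y` and optionally `school_size`,
#' `time`, `vagrant`.
#'
#' @param path CSV file path.
#' @return Data frame with `date` parsed to `Date`.
#' @export
read_sightings <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "date", "x", "y")
  if (!all(need %in% names(s)))
    stop("sightings CSV needs columns: ", paste(need, collapse = ", "))
  s$date <- as.Date(s$date)
  if (any(!is.finite(s$x)) || any(!is.finite(s$y)))
    stop("non-finite coordinates in sightings")
  s
}

#' Write a sightings CSV
#' @param sightings data frame.
#' @param path output path.
#' @export
write_sightings <- function(sightings, path) {
  write.csv(sightings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read bathymetry soundings CSV (columns `x`, `y`, `depth`)
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_soundings <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "depth") %in% names(s)))
    stop("soundings CSV needs columns x, y, depth")
  s
}

#' Read capture histories from CSV or MARK-style .inp
#'
#' CSV: 0/1 columns per occasion, individual IDs in the first column or as
#' row names. `.inp`: lines like `"110010 1;"` (history, frequency,
#' semicolon; comments `/* ... */` ignored), frequencies expanded to rows.
#'
#' @param path file path; format chosen by extension (`.inp` vs anything
#'   else as CSV).
#' @return Binary matrix, individuals x occasions.
#' @export
read_capture_histories <- function(path) {
  if (grepl("\\.inp$", path, ignore.case = TRUE)) {
    txt <- readLines(path, warn = FALSE)
    txt <- gsub("/\\*.*?\\*/", "", paste(txt, collapse = "\n"))
    recs <- regmatches(txt, gregexpr("[01]+\\s+[0-9]+\\s*;", txt))[[1]]
    if (length(recs) == 0L) stop("no capture-history records found in ", path)
    hist_str <- sub("^([01]+).*", "\\1", recs)
    freq <- as.integer(sub("^[01]+\\s+([0-9]+)\\s*;$", "\\1", recs))
    hist_str <- rep(hist_str, freq)
    ch <- do.call(rbind, lapply(strsplit(hist_str, ""), as.integer))
  } else {
    d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    first <- d[[1L]]
    if (!all(first %in% c(0, 1)) || is.character(first)) {
      rownames(d) <- first
      d <- d[, -1L, drop = FALSE]
    }
    ch <- as.matrix(d)
  }
  storage.mode(ch) <- "integer"
  check_histories(ch)
}

#' Write capture histories as CSV (IDs as first column, years as headers)
#' @param ch binary matrix with optional dimnames.
#' @param path output path.
#' @export
write_capture_histories <- function(ch, path) {
  d <- data.frame(id = if (is.null(rownames(ch))) seq_len(nrow(ch)) else rownames(ch),
                  ch, check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write polygons as GeoJSON
#'
#' Each ring becomes one Polygon feature (rings are closed on write);
#' coordinates are planar projected meters.
#'
#' @param polys a ring matrix or list of rings (see [ring_area()]).
#' @param path output path.
#' @param properties optional data frame of per-ring properties.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  if (is.matrix(polys)) polys <- list(polys)
  features <- lapply(seq_along(polys), function(i) {
    ring <- as_ring(polys[[i]])
    ring <- rbind(ring, ring[1L, ])
    coords <- lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1], ring[r, 2]))
    props <- if (!is.null(properties)) as.list(properties[i, , drop = FALSE]) else
      list(ring = i)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Supports Polygon and MultiPolygon geometries; only outer rings are
#' returned (holes are rare in overlay references and unsupported).
#'
#' @param path GeoJSON file path.
#' @return List of ring matrices.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  rings <- list()
  add_poly <- function(coords) {
    outer <- coords[[1L]]            # first ring = outer
    m <- do.call(rbind, lapply(outer, function(pt) c(pt[[1]], pt[[2]])))
    rings[[length(rings) + 1L]] <<- as_ring(m)
  }
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "Polygon")) add_poly(geom$coordinates)
    else if (identical(geom$type, "MultiPolygon"))
      for (p in geom$coordinates) add_poly(p)
    else stop("unsupported geometry type: ", geom$type)
  }
  rings
}

#' Write a gridded surface as an ESRI ASCII raster
#'
#' Portable `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by rows from the top of the grid down.
#'
#' @param surface a `ud_surface` or `depth_grid`.
#' @param path output path.
#' @export
write_ascii_grid <- function(surface, path) {
  grid <- surface$grid
  z <- if (!is.null(surface$density)) surface$density else surface$depth
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$nx),
               sprintf("nrows %d", grid$ny),
               sprintf("xllcorner %.6f", grid$xmin),
               sprintf("yllcorner %.6f", grid$ymin),
               sprintf("cellsize %.6f", grid$cell_size),
               "NODATA_value -9999"), con)
  for (j in rev(seq_len(grid$ny)))
    writeLines(paste(formatC(z[, j], format = "g", digits = 8), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster into a `depth_grid`
#' @param path raster path.
#' @return A `depth_grid` (values in the `depth` matrix).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  z <- do.call(rbind, vals)               # nrows x ncols, top row first
  z[z == hdr$nodata_value] <- NA
  m <- t(z[rev(seq_len(nrow(z))), , drop = FALSE])  # -> nx x ny
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$ncols, hdr$nrows, hdr$cellsize)
  structure(list(grid = g, depth = m), class = "depth_grid")
}
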