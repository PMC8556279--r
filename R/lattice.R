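#' Build a rectangular lattice of square county cells
#'
#' Creates an `n_rows` by `n_cols` grid of congruent square cells of side
#' `cell_km`, used as a stand-in geometry for a county map. Cells are indexed
#' row-major from the lower-left corner; county identifiers are zero-padded
#' strings so that lexical and numeric order agree.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param cell_km positive number, side length of each cell in kilometres.
#' @return An object of class `lattice_geometry`: a list with `county_id`,
#'   centroid coordinates `x`, `y` (km), cell bounds `xmin`, `xmax`, `ymin`,
#'   `ymax`, and the grid dimensions.
#' @examples
#' geom <- make_lattice(3, 3, 10)
#' geom$x[1:3]
#' @export
make_lattice <- function(n_rows, n_cols, cell_km) {
  if (length(n_rows) != 1L || length(n_cols) != 1L || length(cell_km) != 1L)
    stop("n_rows, n_cols and cell_km must be scalars")
  if (!is.finite(n_rows) || !is.finite(n_cols) || !is.finite(cell_km))
    stop("n_rows, n_cols and cell_km must be finite")
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers")
  if (cell_km <= 0) stop("cell_km must be positive")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  geom <- list(
    county_id = sprintf("C%04d", seq_len(n)),
    x = (col - 0.5) * cell_km,
    y = (row - 0.5) * cell_km,
    xmin = (col - 1) * cell_km, xmax = col * cell_km,
    ymin = (row - 1) * cell_km, ymax = row * cell_km,
    n_rows = n_rows, n_cols = n_cols, cell_km = cell_km
  )
  class(geom) <- "lattice_geometry"
  geom
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("Lattice geometry: %d x %d cells of %g km (%d counties)\n",
              x$n_rows, x$n_cols, x$cell_km, length(x$county_id)))
  invisible(x)
}

n_counties <- function(geometry) length(geometry$county_id)

#' Write / read lattice geometry as GeoJSON
#'
#' Serializes the square cells as a GeoJSON `FeatureCollection` of `Polygon`
#' features (property `county_id`), and reads such a file back into a polygon
#' collection usable by [queen_weights()]. Reading recovers each cell's
#' bounding box; arbitrary (non-rectangular) polygons are reduced to their
#' bounding boxes, which is exact for lattice cells.
#'
#' @param geometry a `lattice_geometry` (or compatible polygon collection).
#' @param path file path.
#' @return `read_geometry` returns a list with the same fields as
#'   [make_lattice()] output (grid dimensions may be absent).
#' @export
write_geometry <- function(geometry, path) {
  feats <- lapply(seq_along(geometry$county_id), function(i) {
    ring <- list(
      c(geometry$xmin[i], geometry$ymin[i]),
      c(geometry$xmax[i], geometry$ymin[i]),
      c(geometry$xmax[i], geometry$ymax[i]),
      c(geometry$xmin[i], geometry$ymax[i]),
      c(geometry$xmin[i], geometry$ymin[i])
    )
    list(
      type = "Feature",
      properties = list(county_id = geometry$county_id[i]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  n <- length(fc$features)
  id <- character(n)
  xmin <- xmax <- ymin <- ymax <- numeric(n)
  for (i in seq_len(n)) {
    f <- fc$features[[i]]
    id[i] <- as.character(f$properties$county_id %||% sprintf("C%04d", i))
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    xmin[i] <- min(xs); xmax[i] <- max(xs)
    ymin[i] <- min(ys); ymax[i] <- max(ys)
  }
  geom <- list(county_id = id, x = (xmin + xmax) / 2, y = (ymin + ymax) / 2,
               xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  class(geom) <- "lattice_geometry"
  geom
}

`%||%` <- function(a, b) if (is.null(a)) b else a
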