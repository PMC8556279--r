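#' Queen contiguity spatial weights
#'
#' Two polygons are neighbours under the Queen criterion when their boundaries
#' share at least one point, so on a regular lattice each interior cell has
#' eight neighbours (edge- and corner-sharing). Contiguity is decided by
#' closed-interval overlap of the cell rectangles with a snap tolerance of
#' 1e-9 of the typical cell size, which absorbs floating-point boundary
#' coordinates from files.
#'
#' @param geometry a `lattice_geometry` or any polygon collection carrying
#'   `county_id`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @return An object of class `sp_weights`: list with `ids`, `n`,
#'   `neighbors` (list of integer indices, ascending), `weights` (aligned
#'   nonnegative reals; binary 1 here), and `standardized` flag. Isolated
#'   units keep empty lists.
#' @seealso [row_standardize()], [spatial_lag()], [weights_matrix()]
#' @export
queen_weights <- function(geometry) {
  n <- length(geometry$county_id)
  if (n < 1L) stop("empty geometry")
  if (any(!is.finite(geometry$xmin)) || any(!is.finite(geometry$xmax)) ||
      any(!is.finite(geometry$ymin)) || any(!is.finite(geometry$ymax)) ||
      any(geometry$xmax < geometry$xmin) || any(geometry$ymax < geometry$ymin))
    stop("invalid geometry: degenerate or non-finite cell bounds")
  size <- max(geometry$xmax - geometry$xmin, geometry$ymax - geometry$ymin, 1)
  tol <- 1e-9 * size
  nbs <- vector("list", n)
  for (i in seq_len(n)) {
    touch <- which(
      geometry$xmin <= geometry$xmax[i] + tol &
      geometry$xmax >= geometry$xmin[i] - tol &
      geometry$ymin <= geometry$ymax[i] + tol &
      geometry$ymax >= geometry$ymin[i] - tol
    )
    nbs[[i]] <- sort(touch[touch != i])
  }
  if (all(lengths(nbs) == 0L) && n > 1L)
    warning("fully disconnected geometry: every unit is isolated")
  w <- list(
    ids = as.character(geometry$county_id), n = n,
    neighbors = nbs,
    weights = lapply(lengths(nbs), function(k) rep(1, k)),
    standardized = FALSE
  )
  class(w) <- "sp_weights"
  w
}

#' @export
print.sp_weights <- function(x, ...) {
  k <- lengths(x$neighbors)
  cat(sprintf("Spatial weights: %d units, %d links, %s; neighbours per unit %d-%d\n",
              x$n, sum(k), if (x$standardized) "row-standardized" else "binary",
              min(k), max(k)))
  invisible(x)
}

#' Row-standardize spatial weights
#'
#' Rescales each non-isolated unit's weights to sum to one; for binary Queen
#' weights every neighbour of unit i then carries weight 1/|N(i)|, the
#' equal-share neighbourhood averaging the spatial panel models assume.
#' Idempotent; isolated rows stay all-zero.
#'
#' @param w an `sp_weights` object with nonnegative weights.
#' @return the standardized `sp_weights`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "sp_weights"))
  for (i in seq_len(w$n)) {
    s <- sum(w$weights[[i]])
    if (any(w$weights[[i]] < 0)) stop("negative weights cannot be standardized")
    if (s > 0) w$weights[[i]] <- w$weights[[i]] / s
  }
  w$standardized <- TRUE
  w
}

#' Spatial lag of a vector
#'
#' Computes `out_i = sum_j w_ij value_j`: with row-standardized contiguity
#' weights this is the mean of each unit's neighbours (the neighbourhood PM2.5
#' term of the spatial lag model). Isolated units get 0.
#'
#' @param w an `sp_weights` object.
#' @param values numeric vector of length `w$n`.
#' @return numeric vector of length `w$n`.
#' @export
spatial_lag <- function(w, values) {
  stopifnot(inherits(w, "sp_weights"))
  if (length(values) != w$n)
    stop("values must have length ", w$n, " (one per spatial unit)")
  vapply(seq_len(w$n), function(i) {
    nb <- w$neighbors[[i]]
    if (length(nb) == 0L) 0 else sum(w$weights[[i]] * values[nb])
  }, numeric(1))
}

#' Sparse matrix form of spatial weights
#'
#' @param w an `sp_weights` object.
#' @return a `dgCMatrix` of dimension n x n.
#' @export
weights_matrix <- function(w) {
  stopifnot(inherits(w, "sp_weights"))
  k <- lengths(w$neighbors)
  Matrix::sparseMatrix(
    i = rep(seq_len(w$n), k),
    j = unlist(w$neighbors, use.names = FALSE) %||% integer(0),
    x = unlist(w$weights, use.names = FALSE) %||% numeric(0),
    dims = c(w$n, w$n), dimnames = list(w$ids, w$ids)
  )
}

# Real eigenvalues of the weights matrix. A row-standardized symmetric
# contiguity matrix is similar to a symmetric matrix, so its spectrum is real;
# tiny imaginary parts from numerics are dropped.
weights_eigenvalues <- function(w) {
  ev <- eigen(as.matrix(weights_matrix(w)), only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8)
    warning("weights matrix has noticeably complex eigenvalues; using real parts")
  sort(Re(ev))
}

#' Serialize spatial weights
#'
#' `write_weights_triplet` writes a sparse triplet CSV (`i`, `j`, `w` with
#' unit identifiers); `write_weights_gal` writes the classic text adjacency
#' format (header line with n, then per unit an `id count` line followed by
#' the neighbour id line). `read_weights_gal` reads the latter back as binary
#' weights.
#'
#' @param w an `sp_weights` object.
#' @param path file path.
#' @export
write_weights_triplet <- function(w, path) {
  k <- lengths(w$neighbors)
  df <- data.frame(
    i = rep(w$ids, k),
    j = w$ids[unlist(w$neighbors, use.names = FALSE) %||% integer(0)],
    w = unlist(w$weights, use.names = FALSE) %||% numeric(0)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_triplet
#' @export
write_weights_gal <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(w$n), con)
  for (i in seq_len(w$n)) {
    writeLines(paste(w$ids[i], length(w$neighbors[[i]])), con)
    writeLines(paste(w$ids[w$neighbors[[i]]], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_weights_triplet
#' @export
read_weights_gal <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  ids <- character(n)
  raw_nbs <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    hd <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    ids[i] <- hd[1]
    cnt <- as.integer(hd[2])
    raw_nbs[[i]] <- if (cnt > 0) strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]] else character(0)
    pos <- pos + 2L
  }
  nbs <- lapply(raw_nbs, function(v) sort(match(v, ids)))
  w <- list(ids = ids, n = n, neighbors = nbs,
            weights = lapply(lengths(nbs), function(k) rep(1, k)),
            standardized = FALSE)
  class(w) <- "sp_weights"
  w
}
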