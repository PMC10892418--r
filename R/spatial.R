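#' Define a regular interpolation grid
#'
#' A planar grid in projected metres. `xmin`/`ymin` are the lower-left
#' corner of the lower-left cell (the ESRI ASCII `xllcorner` convention);
#' cell centers sit half a cell in from the corner.
#'
#' @param xmin,ymin Lower-left corner, metres.
#' @param cellsize Cell edge length, metres, positive.
#' @param ncols,nrows Grid dimensions, at least 1.
#' @return An object of class `metal_grid` with an all-`NA` value matrix
#'   (row 1 = southernmost row).
#' @export
make_grid <- function(xmin, ymin, cellsize, ncols, nrows) {
  if (cellsize <= 0) stop("'cellsize' must be positive", call. = FALSE)
  if (ncols < 1 || nrows < 1) stop("grid must have at least one cell", call. = FALSE)
  structure(
    list(xmin = xmin, ymin = ymin, cellsize = cellsize,
         ncols = as.integer(ncols), nrows = as.integer(nrows),
         values = matrix(NA_real_, nrows, ncols)),
    class = "metal_grid"
  )
}

#' @export
print.metal_grid <- function(x, ...) {
  cat(sprintf("<metal_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cellsize, x$xmin, x$ymin))
  if (!all(is.na(x$values))) {
    cat(sprintf("values: [%g, %g]\n", min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}

grid_centers <- function(grid) {
  cx <- grid$xmin + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  cy <- grid$ymin + (seq_len(grid$nrows) - 0.5) * grid$cellsize
  list(x = cx, y = cy)
}

#' Grid to long data frame
#'
#' @param grid A `metal_grid` with values.
#' @return A tibble `x`, `y`, `value` over cell centers.
#' @export
grid_to_df <- function(grid) {
  stopifnot(inherits(grid, "metal_grid"))
  ctr <- grid_centers(grid)
  tibble::tibble(
    x = rep(ctr$x, times = grid$nrows),
    y = rep(ctr$y, each = grid$ncols),
    value = as.vector(t(grid$values))
  )
}

#' Inverse-distance-weighted interpolation
#'
#' Deterministic interpolation of scattered point values onto a grid:
#' each cell takes the weighted mean of the `max_neighbors` nearest sample
#' values with weights `d^-power`. A cell within `snap_tol` of a sample
#' takes that sample's value exactly, so the surface honours the data.
#' Interpolated values always lie within the range of the inputs.
#'
#' Coordinates must be planar (projected); geographic lon/lat must be
#' projected upstream.
#'
#' @param points Data frame with columns `x`, `y`, `value` (at least one
#'   row).
#' @param grid A `metal_grid` from [make_grid()].
#' @param power Distance-decay exponent, positive; default 2.
#' @param max_neighbors Number of nearest samples used per cell; default all.
#' @param snap_tol Snap radius in metres within which a cell reproduces a
#'   sample exactly; also the radius within which two samples count as
#'   coincident. Default 1e-9.
#' @param average_duplicates Average coincident samples (within `snap_tol`)
#'   before interpolating; if `FALSE` (default), coincident samples with
#'   different values are an error.
#' @return The grid with its `values` matrix filled.
#' @export
idw <- function(points, grid, power = 2, max_neighbors = Inf,
                snap_tol = 1e-9, average_duplicates = FALSE) {
  stopifnot(inherits(grid, "metal_grid"))
  points <- as.data.frame(points)
  if (!all(c("x", "y", "value") %in% names(points))) {
    stop("'points' needs columns x, y, value", call. = FALSE)
  }
  if (nrow(points) == 0) stop("no points to interpolate", call. = FALSE)
  if (power <= 0) stop("'power' must be positive", call. = FALSE)
  if (any(!is.finite(points$x)) || any(!is.finite(points$y)) ||
      any(!is.finite(points$value))) {
    stop("non-finite coordinates or values in 'points'", call. = FALSE)
  }

  # Coincident samples: average them or refuse conflicting values.
  if (nrow(points) > 1) {
    d <- as.matrix(stats::dist(points[, c("x", "y")]))
    diag(d) <- Inf
    if (any(d <= snap_tol)) {
      pairs <- which(d <= snap_tol, arr.ind = TRUE)
      conflict <- any(abs(points$value[pairs[, 1]] - points$value[pairs[, 2]]) > 0)
      if (conflict && !average_duplicates) {
        stop("coincident points with conflicting values; set average_duplicates = TRUE",
             call. = FALSE)
      }
      grp <- cutree_coincident(d, snap_tol)
      points <- stats::aggregate(points[, c("x", "y", "value")],
                                 by = list(grp = grp), FUN = mean)[, -1]
    }
  }

  ctr <- grid_centers(grid)
  px <- points$x; py <- points$y; pv <- points$value
  k <- min(max_neighbors, length(pv))
  vals <- matrix(NA_real_, grid$nrows, grid$ncols)
  dx2 <- outer(ctr$x, px, `-`)^2                     # ncols x npts, row-invariant
  for (i in seq_len(grid$nrows)) {
    dy <- matrix(ctr$y[i] - py, grid$ncols, length(py), byrow = TRUE)
    dd <- sqrt(dx2 + dy^2)
    for (j in seq_len(grid$ncols)) {
      dj <- dd[j, ]
      nearest <- which.min(dj)
      if (dj[nearest] <= snap_tol) {
        vals[i, j] <- pv[nearest]
        next
      }
      use <- if (k < length(dj)) order(dj)[seq_len(k)] else seq_along(dj)
      w <- dj[use]^(-power)
      vals[i, j] <- sum(w * pv[use]) / sum(w)
    }
  }
  grid$values <- vals
  grid
}

# Single-linkage grouping of coincident points from a distance matrix.
cutree_coincident <- function(d, tol) {
  n <- nrow(d)
  grp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (d[i, j] <= tol) grp[grp == grp[j]] <- grp[i]
    }
  }
  match(grp, unique(grp))
}

#' Write a grid as an ESRI ASCII raster
#'
#' Standard `.asc` header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows from north to south, for
#' import into GIS software.
#'
#' @param grid A filled `metal_grid`.
#' @param path Output path.
#' @param nodata Value written for `NA` cells; default -9999.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "metal_grid"))
  vals <- grid$values
  vals[is.na(vals)] <- nodata
  header <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(vals[rev(seq_len(grid$nrows)), , drop = FALSE], 1,
                function(row) paste(sprintf("%.10g", row), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path Path to a `.asc` file written by [write_esri_ascii()] (or any
#'   corner-referenced ESRI ASCII grid).
#' @return A `metal_grid`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  grid <- make_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                    hdr$ncols, hdr$nrows)
  body <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  vals <- do.call(rbind, body)
  vals[vals == hdr$nodata_value] <- NA_real_
  grid$values <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  grid
}
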