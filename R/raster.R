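#' Gridded raster layers
#'
#' `meltpot` uses a minimal in-memory raster: a numeric matrix whose first row
#' is the northernmost row, cell values located at cell centres, plus the
#' geometry needed to place cells in space. Grids are either `"planar"`
#' (coordinates in km; all distances Euclidean) or `"lonlat"` (decimal
#' degrees; distances great-circle). Synthetic worlds are planar by design.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (km for planar grids, degrees for lonlat).
#' @param crs `"planar"` or `"lonlat"`.
#' @param nodata value marking missing cells.
#' @return an object of class `meltpot_raster`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        crs = c("planar", "lonlat"), nodata = -9999) {
  crs <- match.arg(crs)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a positive scalar")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         crs = crs, nodata = nodata),
    class = "meltpot_raster"
  )
}

#' @export
print.meltpot_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<meltpot_raster> %d x %d cells, cellsize %g (%s)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$crs))
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.meltpot_raster <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol && a$crs == b$crs
}

#' Coordinates of all cell centres
#'
#' @param r a `meltpot_raster`.
#' @return data frame with `row`, `col` (1-based matrix indices), `x`, `y`
#'   (centre coordinates in the grid's units).
#' @export
cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(row = row, col = col,
             x = r$xll + (col - 0.5) * r$cellsize,
             y = r$yll + (nr - row + 0.5) * r$cellsize)
}

#' Cell index of a point
#'
#' Points on a cell edge belong to the cell to the north-east of the edge.
#'
#' @param r a `meltpot_raster`.
#' @param xy two-column matrix or data frame of point coordinates.
#' @return data frame with `row`, `col`; `NA` for points outside the grid.
#' @export
cell_of <- function(r, xy) {
  xy <- as.matrix(xy)
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((xy[, 1] - r$xll) / r$cellsize) + 1L
  row <- nr - floor((xy[, 2] - r$yll) / r$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' @param r a `meltpot_raster`.
#' @param xy two-column matrix of coordinates.
#' @return numeric vector; `NA` outside the grid or at nodata cells.
#' @export
extract_values <- function(r, xy) {
  rc <- cell_of(r, xy)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc$row)
  out[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  out[!is.na(out) & out == r$nodata] <- NA_real_
  out
}

#' Environmental layer stacks
#'
#' A named list of rasters sharing one geometry.
#'
#' @param layers named list of `meltpot_raster` objects.
#' @return object of class `meltpot_stack`.
#' @export
env_stack <- function(layers) {
  if (length(layers) == 0L) stop("a stack needs at least one layer")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  ref <- layers[[1L]]
  for (l in layers)
    if (!same_geometry(ref, l)) stop("all layers must share one geometry")
  structure(list(layers = layers), class = "meltpot_stack")
}

#' @export
print.meltpot_stack <- function(x, ...) {
  cat(sprintf("<meltpot_stack> %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Per-cell design matrix of a stack
#'
#' @param stack a `meltpot_stack`.
#' @param vars layer names to include (default all).
#' @return list with `X` (cells x vars matrix, nodata rows NA) and `cells`
#'   (row/col/x/y of each matrix row).
#' @export
stack_design <- function(stack, vars = names(stack$layers)) {
  missing_v <- setdiff(vars, names(stack$layers))
  if (length(missing_v))
    stop("scenario stack is missing layer(s): ", paste(missing_v, collapse = ", "))
  cells <- cell_centres(stack$layers[[1L]])
  X <- sapply(vars, function(v) {
    r <- stack$layers[[v]]
    vals <- r$values[cbind(cells$row, cells$col)]
    vals[vals == r$nodata] <- NA_real_
    vals
  })
  X <- matrix(X, nrow = nrow(cells), dimnames = list(NULL, vars))
  list(X = X, cells = cells)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param crs coordinate system of the grid (`"planar"` or `"lonlat"`).
#' @return a `meltpot_raster`.
#' @export
read_ascii_grid <- function(path, crs = "planar") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[a-zA-Z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param r a `meltpot_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  )
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE,
                                                  digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## pairwise / point-to-set distances honouring the grid crs (km)
point_distances <- function(a, b, crs) {
  a <- matrix(as.numeric(as.matrix(a)), ncol = 2L)
  b <- matrix(as.numeric(as.matrix(b)), ncol = 2L)
  if (crs == "lonlat") {
    out <- matrix(0, nrow(a), nrow(b))
    for (j in seq_len(nrow(b)))
      out[, j] <- geosphere::distHaversine(a, b[j, , drop = FALSE]) / 1000
    out
  } else {
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    sqrt(dx^2 + dy^2)
  }
}
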