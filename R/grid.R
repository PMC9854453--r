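#' Georeferenced raster grid
#'
#' A minimal single-band raster container: a numeric matrix of cell values
#' plus the geometry needed to place it in a projected (planar, metric)
#' coordinate system. Row 1 of `values` is the *bottom* (southernmost) row,
#' so `values[i, j]` sits at the cell with lower-left corner
#' `origin + c((j - 1), (i - 1)) * cell_size`. Missing/nodata cells are held
#' as `NA` in memory; the `nodata` sentinel is only used on disk.
#'
#' @param values numeric matrix (rows = south to north, cols = west to east).
#' @param cell_size cell edge length in metres (default 1000, i.e. ~1 km
#'   resolution).
#' @param origin numeric length-2, projected coordinates (m) of the grid's
#'   lower-left corner.
#' @param nodata sentinel written to file for `NA` cells.
#' @return an object of class `rs_grid`.
#' @export
rs_grid <- function(values, cell_size = 1000, origin = c(0, 0),
                    nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar (metres)")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be two finite coordinates (metres)")
  if (any(is.infinite(values)))
    stop("grid values must be finite or NA")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "rs_grid"
  )
}

#' @export
print.rs_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<rs_grid> %d x %d cells, %.0f m, origin (%.0f, %.0f)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%s, %s], %d NA\n",
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' @export
dim.rs_grid <- function(x) dim(x$values)

is_rs_grid <- function(x) inherits(x, "rs_grid")

#' Do two grids share geometry?
#'
#' Same dimensions, cell size and origin (to a metre-scale tolerance).
#' @param a,b `rs_grid` objects.
#' @export
grid_aligned <- function(a, b) {
  is_rs_grid(a) && is_rs_grid(b) &&
    identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-6))
}

stop_if_misaligned <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!grid_aligned(gs[[1]], gs[[i]]))
      stop("grids are not aligned (dimensions/origin/cell size differ)")
  invisible(TRUE)
}

#' Make a grid with the same geometry but new values
#' @param template an `rs_grid` supplying geometry.
#' @param values replacement matrix (or scalar, recycled).
#' @export
grid_like <- function(template, values) {
  if (length(values) == 1L)
    values <- matrix(values, nrow(template$values), ncol(template$values))
  rs_grid(values, template$cell_size, template$origin, template$nodata)
}

#' Cell-centre coordinates
#'
#' @param grid an `rs_grid`.
#' @param rows,cols 1-based indices (row 1 = bottom). Defaults: all cells in
#'   column-major order.
#' @return two-column matrix of x, y centre coordinates (metres).
#' @export
cell_centers <- function(grid, rows = NULL, cols = NULL) {
  d <- dim(grid$values)
  if (is.null(rows)) {
    idx <- arrayInd(seq_len(prod(d)), d)
    rows <- idx[, 1]; cols <- idx[, 2]
  }
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
        y = grid$origin[2] + (rows - 0.5) * grid$cell_size)
}

#' Locate points on the grid
#'
#' Half-open convention: a point belongs to the cell whose interval
#' `[x0, x0 + cell)` contains it, so points on an upper/right cell edge fall
#' into the next cell.
#'
#' @param grid an `rs_grid`.
#' @param x,y point coordinates (metres).
#' @return data.frame with columns `row`, `col` (1-based, `NA` outside grid).
#' @export
xy_to_cell <- function(grid, x, y) {
  d <- dim(grid$values)
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Grid values at point locations
#' @inheritParams xy_to_cell
#' @return numeric vector (`NA` for points outside the grid or on nodata).
#' @export
extract_at <- function(grid, x, y) {
  rc <- xy_to_cell(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Write / read ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (`.asc`): a 6-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows from north to south. `NA` cells are written as the grid's nodata
#' sentinel.
#'
#' @param grid an `rs_grid`.
#' @param path file path.
#' @export
write_asc <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %s", format(grid$nodata))
  ), con)
  # file rows run north->south; storage rows run south->north
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(format(v[i, ], trim = TRUE, digits = 12),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  stopifnot(length(body) == nr)
  m <- matrix(NA_real_, nr, nc)
  for (k in seq_len(nr)) {
    row <- as.numeric(strsplit(trimws(body[k]), "\\s+")[[1]])
    m[nr - k + 1L, ] <- row   # undo north->south ordering
  }
  m[m == nodata] <- NA_real_
  rs_grid(m, val("cellsize"), c(val("xllcorner"), val("yllcorner")), nodata)
}
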