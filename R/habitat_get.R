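# Habitat-preference (GET-score) raster surface.
#
# The surface is a 50-m integer grid of scores 1-10 (higher = more preferred
# by eagles; 6+ increasingly preferred). Stored in memory as a matrix in map
# orientation (row 1 = northernmost row) with an affine georeference given
# by the lower-left corner and cell size, read/written as ESRI ASCII grid
# (plain text). Cell ownership is half-open: west and north cell edges are
# inclusive, so any point maps to exactly one cell.

#' Construct a GET raster
#'
#' @param values Integer matrix in map orientation (row 1 northernmost);
#'   non-`NA` values must be in 1..10.
#' @param xll,yll Planar coordinates (m) of the lower-left corner of the grid.
#' @param cellsize Cell size in metres (default 50).
#' @param nodata_value Sentinel written to file for `NA` cells.
#' @return An object of class `get_raster`.
#' @export
get_raster <- function(values, xll, yll, cellsize = 50, nodata_value = -9999) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  vals <- values[!is.na(values)]
  if (length(vals) > 0 && (any(vals != round(vals)) || any(vals < 1 | vals > 10))) {
    abort("non-nodata GET scores must be integers in 1..10")
  }
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata_value = nodata_value),
            class = "get_raster")
}

#' @export
print.get_raster <- function(x, ...) {
  cat(sprintf("<get_raster> %d x %d cells of %g m, lower-left (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' @export
dim.get_raster <- function(x) dim(x$values)

# row/col (map orientation) of the cell owning each point; errors if outside
raster_cell <- function(raster, x, y) {
  ncol <- ncol(raster$values); nrow <- nrow(raster$values)
  ytop <- raster$yll + nrow * raster$cellsize
  col <- floor((x - raster$xll) / raster$cellsize) + 1
  row <- floor((ytop - y) / raster$cellsize) + 1
  # the north edge of the grid belongs to row 1; the east/south outer edges
  # are outside (half-open convention)
  row[y == ytop] <- 1
  if (any(col < 1 | col > ncol | row < 1 | row > nrow)) {
    abort("point outside raster extent")
  }
  list(row = row, col = col)
}

#' Test whether points fall inside a raster's extent
#'
#' Half-open convention: the west and north outer edges are inside, the east
#' and south outer edges are not.
#'
#' @param raster A [get_raster()].
#' @param x,y Planar coordinates (m).
#' @return Logical vector.
#' @export
raster_contains <- function(raster, x, y) {
  ytop <- raster$yll + nrow(raster$values) * raster$cellsize
  xright <- raster$xll + ncol(raster$values) * raster$cellsize
  x >= raster$xll & x < xright & y > raster$yll & y <= ytop
}

#' GET score of the pixel containing a point
#'
#' @param raster A [get_raster()].
#' @param x,y Planar coordinates (m); must lie within the raster extent.
#' @return Integer scores (1-10); `NA` for nodata pixels.
#' @export
point_get_score <- function(raster, x, y) {
  rc <- raster_cell(raster, x, y)
  raster$values[cbind(rc$row, rc$col)]
}

#' GET score of a turbine location
#'
#' The mode of the pixel containing the turbine tower and its four
#' edge-adjacent (rook) neighbours; ties broken by the highest tied score.
#' All five pixels must be inside the extent and non-nodata.
#'
#' @param raster A [get_raster()].
#' @param x,y Turbine tower planar coordinates (m). Vectorised.
#' @return Integer scores (1-10).
#' @export
turbine_get_score <- function(raster, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i) {
    rc <- raster_cell(raster, x[i], y[i])
    nbr <- rbind(c(rc$row, rc$col),
                 c(rc$row - 1, rc$col), c(rc$row + 1, rc$col),
                 c(rc$row, rc$col - 1), c(rc$row, rc$col + 1))
    if (any(nbr[, 1] < 1 | nbr[, 1] > nrow(raster$values) |
              nbr[, 2] < 1 | nbr[, 2] > ncol(raster$values))) {
      abort("turbine 5-pixel neighbourhood extends outside raster extent")
    }
    v <- raster$values[nbr]
    if (any(is.na(v))) abort("nodata pixel in turbine 5-pixel neighbourhood")
    tab <- table(v)
    modes <- as.integer(names(tab)[tab == max(tab)])
    max(modes)   # highest tied score
  }, integer(1))
}

#' Read an ESRI ASCII grid as a GET raster
#'
#' @param path Path to an `.asc` file.
#' @return A [get_raster()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("raster file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) abort(sprintf("ASCII grid header lacks %s", k))
  }
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  nodata <- hdr$nodata_value %||% -9999
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows) {
    abort("ASCII grid body does not match ncols x nrows")
  }
  m <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  get_raster(m, xll = xll, yll = yll, cellsize = hdr$cellsize,
             nodata_value = nodata)
}

#' Write a GET raster as an ESRI ASCII grid
#'
#' @param raster A [get_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  m <- raster$values
  m[is.na(m)] <- raster$nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6f", raster$xll),
    sprintf("yllcorner %.6f", raster$yll),
    sprintf("cellsize %.6f", raster$cellsize),
    sprintf("NODATA_value %g", raster$nodata_value)
  )
  rows <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
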