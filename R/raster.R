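#' Gridded canopy raster
#'
#' Lightweight container for a regular raster such as a canopy height model
#' (CHM), a crown-label map or an exposure map. The grid uses the common
#' remote-sensing convention: `origin` is the outer corner of cell
#' `(1, 1)` at the *upper-left* of the grid, rows run north-to-south
#' (decreasing y), columns west-to-east (increasing x), and cell
#' `(r, c)` covers the half-open square
#' `[x0 + (c-1) res, x0 + c res) x (y0 - r res, y0 - (r-1) res]`.
#' Cells with no data hold `NA`.
#'
#' @param values numeric matrix (rows = north to south).
#' @param resolution cell size in metres (> 0).
#' @param origin numeric length-2, `c(x, y)` of the upper-left corner.
#' @param layer short name for printing, e.g. `"chm"`.
#' @return An object of class `canopy_raster`.
#' @export
canopy_raster <- function(values, resolution, origin = c(0, 0), layer = "layer") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  stopifnot_scalar_number(resolution, "resolution", lo = 1e-9)
  if (length(origin) != 2L || !all(is.finite(origin))) {
    stop("`origin` must be two finite numbers (x, y of the upper-left corner)")
  }
  structure(
    list(values = values, resolution = as.numeric(resolution),
         origin = as.numeric(origin), layer = layer),
    class = "canopy_raster"
  )
}

#' @export
dim.canopy_raster <- function(x) dim(x$values)

#' @export
print.canopy_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<canopy_raster '%s'> %d x %d cells @ %.2f m\n",
              x$layer, nrow(v), ncol(v), x$resolution))
  cat(sprintf("  origin (UL corner): (%.2f, %.2f)\n", x$origin[1], x$origin[2]))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  data cells: %d (%.1f%%), range [%.2f, %.2f]\n",
                length(fin), 100 * length(fin) / length(v), min(fin), max(fin)))
  } else {
    cat("  data cells: 0\n")
  }
  invisible(x)
}

#' @export
plot.canopy_raster <- function(x, main = x$layer, ...) {
  v <- x$values
  # image() draws x along rows, so transpose and flip rows to get map view
  z <- t(v[rev(seq_len(nrow(v))), , drop = FALSE])
  xs <- x$origin[1] + x$resolution * (seq_len(ncol(v)) - 0.5)
  ys <- x$origin[2] - x$resolution * (rev(seq_len(nrow(v))) - 0.5)
  graphics::image(xs, ys, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

# Map point coordinates to (row, col); points outside the grid get NA.
xy_to_cell <- function(raster, x, y) {
  res <- raster$resolution
  col <- floor((x - raster$origin[1]) / res) + 1L
  row <- floor((raster$origin[2] - y) / res) + 1L
  # points exactly on the top/left outer edge belong to the first row/col
  row[raster$origin[2] - y == 0] <- 1L
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  bad <- row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

# Cell-centre coordinates of (row, col).
cell_to_xy <- function(raster, row, col) {
  data.frame(
    x = raster$origin[1] + raster$resolution * (col - 0.5),
    y = raster$origin[2] - raster$resolution * (row - 0.5)
  )
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by GDAL/QGIS; `NA` cells are
#' written as the nodata value.
#'
#' @param raster a [canopy_raster].
#' @param path output file path (conventionally `.asc`).
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_esri_ascii <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", raster$origin[1]),
    sprintf("yllcorner %.6f", raster$origin[2] - nrow(v) * raster$resolution),
    sprintf("cellsize %.6f", raster$resolution),
    sprintf("NODATA_value %s", format(nodata))
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_esri_ascii()] or any GIS tool.
#' @param layer layer name for the returned raster.
#' @return A [canopy_raster].
#' @export
read_esri_ascii <- function(path, layer = "layer") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals[vals == nodata] <- NA_real_
  canopy_raster(
    vals, hdr$cellsize,
    origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
    layer = layer
  )
}
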