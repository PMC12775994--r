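#' Mapcode raster
#'
#' An integer single-band grid in which each cell holds the identifier of the
#' forest-inventory plot imputed to that pixel (TreeMap-style), or a nodata
#' value for non-forested / out-of-domain cells. Row 1 of `grid` is the
#' northernmost row, matching on-disk ESRI ASCII grid layout.
#'
#' @param grid Integer matrix of cell values (row 1 = top of map).
#' @param xll,yll Coordinates of the lower-left corner of the grid, in the
#'   map units of `crs`.
#' @param cell_size_m Cell edge length in map units (metres for projected CRS).
#' @param crs CRS identifier string, e.g. `"EPSG:3857"`.
#' @param nodata Integer nodata sentinel; non-nodata values must be positive.
#' @return A `mapcode_raster` object.
#' @export
mapcode_raster <- function(grid, xll, yll, cell_size_m, crs = "EPSG:3857",
                           nodata = -9999L) {
  if (!is.matrix(grid)) ricb_stop("ricb_argument_error", "grid must be a matrix")
  storage.mode(grid) <- "integer"
  nodata <- as.integer(nodata)
  vals <- grid[!is.na(grid) & grid != nodata]
  if (any(vals <= 0L)) {
    ricb_stop("ricb_argument_error", "all non-nodata mapcode values must be positive")
  }
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L || cell_size_m <= 0) {
    ricb_stop("ricb_argument_error", "cell_size_m must be a positive scalar")
  }
  grid[is.na(grid)] <- nodata
  structure(
    list(grid = grid, xll = as.numeric(xll), yll = as.numeric(yll),
         cell_size_m = as.numeric(cell_size_m), crs = as.character(crs),
         nodata = nodata),
    class = "mapcode_raster"
  )
}

#' @export
print.mapcode_raster <- function(x, ...) {
  vals <- raster_values(x)
  cat(sprintf(
    "mapcode_raster: %d x %d cells @ %g m [%s]\n  extent x [%g, %g] y [%g, %g]\n  %d non-nodata cells, %d distinct codes (nodata = %d)\n",
    nrow(x$grid), ncol(x$grid), x$cell_size_m, x$crs,
    x$xll, x$xll + ncol(x$grid) * x$cell_size_m,
    x$yll, x$yll + nrow(x$grid) * x$cell_size_m,
    length(vals), length(unique(vals)), x$nodata))
  invisible(x)
}

#' Non-nodata cell values of a mapcode raster
#' @param raster A [mapcode_raster()].
#' @return Integer vector of the non-nodata cell values.
#' @export
raster_values <- function(raster) {
  g <- raster$grid
  as.integer(g[g != raster$nodata])
}

# Cell-center coordinates. Row r (from top), column c:
#   x = xll + (c - 1/2) * cs ;  y = yll + (nrow - r + 1/2) * cs
raster_cell_centers <- function(raster) {
  cs <- raster$cell_size_m
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  list(x = raster$xll + (seq_len(nc) - 0.5) * cs,
       y = raster$yll + (nr - seq_len(nr) + 0.5) * cs)
}

#' Read a mapcode raster from an ESRI ASCII grid
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by the cell matrix.
#' A `.prj` sidecar next to the file, when present, supplies the CRS
#' identifier; otherwise `default_crs` is used.
#'
#' @param path Path to the `.asc` file.
#' @param default_crs CRS used when no `.prj` sidecar exists.
#' @return A [mapcode_raster()].
#' @export
read_mapcode_raster <- function(path, default_crs = "EPSG:3857") {
  if (!file.exists(path)) ricb_stop("ricb_io_error", "raster file not found: %s", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) {
      ricb_stop("ricb_format_error", "malformed ASCII grid header line: '%s'", ln)
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    ricb_stop("ricb_format_error", "ASCII grid header missing: %s",
              paste(miss, collapse = ", "))
  }
  vals <- scan(path, what = integer(), skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    ricb_stop("ricb_format_error", "ASCII grid has %d values, expected %d",
              length(vals), hdr$ncols * hdr$nrows)
  }
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) trimws(readLines(prj, n = 1L)) else default_crs
  mapcode_raster(grid, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 crs = crs, nodata = as.integer(hdr$nodata_value))
}

#' Write a mapcode raster as an ESRI ASCII grid
#'
#' Writes the `.asc` grid plus a `.prj` sidecar holding the CRS identifier,
#' so a read/write round trip preserves georeferencing.
#'
#' @param raster A [mapcode_raster()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_mapcode_raster <- function(raster, path) {
  g <- raster$grid
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", raster$xll),
    sprintf("yllcorner %.10g", raster$yll),
    sprintf("cellsize %.10g", raster$cell_size_m),
    sprintf("NODATA_value %d", raster$nodata)), con)
  writeLines(apply(g, 1L, paste, collapse = " "), con)
  writeLines(raster$crs, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}
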