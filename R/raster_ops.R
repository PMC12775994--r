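#' Clip a mapcode raster to an area of interest
#'
#' The AOI polygon is reprojected into the raster's CRS (the imputation grid
#' itself is never resampled or reprojected, so cell values stay bit-exact).
#' The output extent is the AOI bounding box snapped outward to the source
#' grid, and cells whose *centers* fall outside the polygon are set to
#' nodata. Clipping twice with the same AOI equals clipping once.
#'
#' @param raster A [mapcode_raster()].
#' @param aoi An [aoi_polygon()] in any supported CRS.
#' @return The clipped `mapcode_raster`.
#' @export
clip_to_aoi <- function(raster, aoi) {
  aoi <- transform_aoi(aoi, raster$crs)
  bb <- aoi_bbox(aoi)
  cs <- raster$cell_size_m
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  xmax_r <- raster$xll + nc * cs
  ymax_r <- raster$yll + nr * cs
  if (bb["xmax"] <= raster$xll || bb["xmin"] >= xmax_r ||
      bb["ymax"] <= raster$yll || bb["ymin"] >= ymax_r) {
    ricb_stop("ricb_empty_clip", "AOI does not intersect the raster extent")
  }
  # snap AOI bbox outward to the source grid
  c0 <- max(1L, floor((bb["xmin"] - raster$xll) / cs) + 1L)
  c1 <- min(nc, ceiling((bb["xmax"] - raster$xll) / cs))
  r1 <- min(nr, nr - floor((bb["ymin"] - raster$yll) / cs))
  r0 <- max(1L, nr - ceiling((bb["ymax"] - raster$yll) / cs) + 1L)
  grid <- raster$grid[r0:r1, c0:c1, drop = FALSE]
  out <- mapcode_raster(grid,
                        xll = raster$xll + (c0 - 1L) * cs,
                        yll = raster$yll + (nr - r1) * cs,
                        cell_size_m = cs, crs = raster$crs,
                        nodata = raster$nodata)
  ctr <- raster_cell_centers(out)
  xs <- rep(ctr$x, each = nrow(out$grid))
  ys <- rep(ctr$y, times = ncol(out$grid))
  inside <- matrix(points_in_aoi(xs, ys, aoi), nrow = nrow(out$grid))
  if (!any(inside)) {
    ricb_stop("ricb_empty_clip", "no cell centers fall inside the AOI")
  }
  out$grid[!inside] <- out$nodata
  out
}

#' Remap mapcode values to a sequential range
#'
#' Distinct non-nodata values, sorted ascending, become `1..K`; nodata cells
#' are untouched. The returned remap table is the bijection later used to
#' link sequential map codes back to their source plot ids (and hence tiles).
#'
#' @param raster A [mapcode_raster()] with at least one non-nodata cell.
#' @return List with elements `raster` (remapped) and `remap` (data frame
#'   `original`, `sequential`).
#' @export
remap_sequential <- function(raster) {
  vals <- raster_values(raster)
  if (!length(vals)) {
    ricb_stop("ricb_empty_clip", "raster is entirely nodata; nothing to remap")
  }
  orig <- sort(unique(vals))
  remap <- data.frame(original = orig, sequential = seq_along(orig))
  g <- raster$grid
  keep <- g != raster$nodata
  g[keep] <- remap$sequential[match(g[keep], remap$original)]
  out <- raster
  out$grid <- g
  list(raster = out, remap = remap)
}

#' Aggregate a mapcode raster to coarser resolution by mode
#'
#' Each `factor` x `factor` block of cells collapses to one cell holding the
#' block's most frequent non-nodata value (factor 10 turns a 30 m grid into
#' the 300 m companion product). Blocks that are entirely nodata stay nodata;
#' frequency ties break to the smallest value; trailing partial blocks at the
#' right/bottom edges are aggregated over the cells they actually contain.
#'
#' @param raster A [mapcode_raster()].
#' @param factor Integer block edge, at least 2.
#' @return The aggregated `mapcode_raster` (cell size multiplied by `factor`).
#' @export
mode_aggregate <- function(raster, factor) {
  if (!is_count(factor) || factor < 2) {
    ricb_stop("ricb_argument_error", "factor must be an integer >= 2")
  }
  factor <- as.integer(factor)
  g <- raster$grid
  nr <- nrow(g); nc <- ncol(g)
  nr2 <- ceiling(nr / factor); nc2 <- ceiling(nc / factor)
  out <- matrix(raster$nodata, nrow = nr2, ncol = nc2)
  for (i in seq_len(nr2)) {
    rows <- ((i - 1L) * factor + 1L):min(i * factor, nr)
    for (j in seq_len(nc2)) {
      cols <- ((j - 1L) * factor + 1L):min(j * factor, nc)
      block <- g[rows, cols]
      block <- block[block != raster$nodata]
      if (length(block)) {
        uv <- sort(unique(block))
        counts <- tabulate(match(block, uv))
        out[i, j] <- uv[which.max(counts)]  # first max = smallest value
      }
    }
  }
  new_cs <- raster$cell_size_m * factor
  ytop <- raster$yll + nr * raster$cell_size_m
  mapcode_raster(out, xll = raster$xll, yll = ytop - nr2 * new_cs,
                 cell_size_m = new_cs, crs = raster$crs, nodata = raster$nodata)
}
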