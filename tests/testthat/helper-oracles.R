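# Independent oracles the tests compare the implementation against.
# These deliberately share no code with the package internals.

# Even-odd ray-casting point-in-polygon (single ring, open form).
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Per-block frequency count with smallest-value tie-break.
oracle_block_mode <- function(vals, nodata) {
  vals <- vals[vals != nodata]
  if (!length(vals)) return(nodata)
  tab <- table(vals)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}

# Exhaustive mode aggregation of a full grid.
oracle_mode_aggregate <- function(grid, factor, nodata) {
  nr <- nrow(grid); nc <- ncol(grid)
  nr2 <- ceiling(nr / factor); nc2 <- ceiling(nc / factor)
  out <- matrix(nodata, nr2, nc2)
  for (i in seq_len(nr2)) {
    for (j in seq_len(nc2)) {
      rows <- ((i - 1) * factor + 1):min(i * factor, nr)
      cols <- ((j - 1) * factor + 1):min(j * factor, nc)
      out[i, j] <- oracle_block_mode(as.vector(grid[rows, cols]), nodata)
    }
  }
  out
}

# Exhaustive counting oracle for the representative-species rule.
oracle_representative <- function(trees) {
  out <- character()
  for (grp in sort(unique(trees$e_spgrpcd))) {
    sub <- trees[trees$e_spgrpcd == grp, ]
    best <- NULL; best_n <- -1L
    for (sym in sort(unique(sub$species_symbol))) {
      n <- sum(sub$species_symbol == sym)
      if (n > best_n) { best <- sym; best_n <- n }
    }
    out[[as.character(grp)]] <- best
  }
  out
}

# Axis-aligned rectangular AOI in the raster's own CRS.
rect_aoi <- function(xmin, ymin, xmax, ymax, crs) {
  aoi_polygon(rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                    c(xmin, ymax)), crs = crs)
}

# Small end-to-end landscape with tiles written to disk; returns all paths.
make_run_dirs <- function(seed = 7, rows = 30, cols = 30, n_plots = 10,
                          root = withr::local_tempdir(.local_envir = parent.frame())) {
  land <- generate_landscape(fixture_config(
    seed = seed, grid_rows = rows, grid_cols = cols, n_plots = n_plots))
  tiles <- augment_and_build_tiles(land$trees, land$plots, land$species_ref,
                                   land$carmean)
  paths <- write_landscape(land, file.path(root, "land"))
  write_tiles(tiles, file.path(root, "tiles"))
  list(land = land, tiles = tiles, paths = paths,
       tiles_dir = file.path(root, "tiles"),
       out_dir = file.path(root, "out"), root = root)
}

# Pixel-weighted total grams of selected alive-tree biomass: the quantity
# cohort assembly must conserve, computed straight from tiles and raster.
oracle_total_grams <- function(tiles, raster, remap, selected) {
  vals <- raster_values(raster)
  px <- table(vals)
  total <- 0
  for (k in seq_along(px)) {
    code <- as.integer(names(px)[k])
    orig <- remap$original[remap$sequential == code]
    tile <- tiles[[as.character(orig)]]
    sel <- tile$biomass[tile$SPECIES_SYMBOL %in% selected]
    total <- total + sum(sel) * 1000 * as.numeric(px[k])
  }
  total
}
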