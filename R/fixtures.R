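#' Default species pool for synthetic landscapes
#'
#' Eight common southeastern-US tree species with their USDA PLANTS symbols,
#' eastern species group codes, Jenkins species-group codes and the published
#' Jenkins total-aboveground-biomass coefficients for those groups (pine;
#' soft maple/birch; mixed hardwood; hard maple/oak/hickory/beech).
#'
#' @return Data frame with one row per species.
#' @export
default_species_pool <- function() {
  data.frame(
    species_symbol = c("PITA", "PIEC2", "QUNI", "QULA3", "QUAL",
                       "ACRU", "LIST2", "LITU"),
    common_name = c("loblolly pine", "shortleaf pine", "water oak",
                    "laurel oak", "white oak", "red maple", "sweetgum",
                    "yellow-poplar"),
    e_spgrpcd = c(2L, 2L, 28L, 28L, 25L, 22L, 22L, 22L),
    jenkins_spgrpcd = c(4L, 4L, 8L, 8L, 8L, 6L, 7L, 7L),
    jenkins_b1 = c(-2.5356, -2.5356, -2.0127, -2.0127, -2.0127,
                   -1.9123, -2.4800, -2.4800),
    jenkins_b2 = c(2.4349, 2.4349, 2.4342, 2.4342, 2.4342,
                   2.3651, 2.4835, 2.4835),
    stringsAsFactors = FALSE)
}

#' Default Carmean coefficient pool for synthetic landscapes
#'
#' One decay-form site-index curve per eastern species group code in
#' [default_species_pool()], with coefficients in the range of published
#' Carmean fits for southern pines, maples and upland oaks.
#'
#' @return Data frame `e_spgrpcd`, `b1`..`b5`.
#' @export
default_carmean_pool <- function() {
  data.frame(
    e_spgrpcd = c(2L, 22L, 25L, 28L),
    b1 = c(1.1421, 2.9435, 4.5598, 1.8326),
    b2 = c(0.9947, 0.9132, 0.8136, 0.9802),
    b3 = c(-0.0269, -0.0141, -0.0132, -0.0230),
    b4 = c(1.1344, 1.6580, 2.2410, 1.1898),
    b5 = c(-0.0109, -0.1095, -0.1880, -0.0289),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-landscape generator
#'
#' Describes the statistical structure of a generated landscape: grid shape
#' and resolution, number of imputation plots, the species and site-curve
#' pools, and the tree-level distributions. The defaults emulate a small
#' southeastern mixed pine-hardwood landscape on a 30 m imputation grid.
#'
#' @param seed Integer RNG seed; equal seeds give byte-identical landscapes.
#' @param grid_rows,grid_cols Raster dimensions.
#' @param cell_size_m Cell edge in metres (default 30, the imputation-grid
#'   native resolution).
#' @param n_plots Number of distinct inventory plots imputed to the grid.
#' @param species_pool Data frame as [default_species_pool()].
#' @param carmean_pool Data frame as [default_carmean_pool()]; must cover
#'   every group code in `species_pool`.
#' @param nodata_fraction Fraction of non-forested (nodata) cells.
#' @param trees_per_plot_range Integer range of trees per plot.
#' @param dead_fraction Probability a tree is standing dead.
#' @param site_index_range Uniform range of plot site indices (feet).
#' @param dia_range_in Uniform range of tree diameters (inches).
#' @param age_range_yr Uniform range of true tree ages (years).
#' @param crs_id Raster CRS (default Web Mercator).
#' @return A validated `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, grid_rows = 60L, grid_cols = 60L,
                           cell_size_m = 30, n_plots = 25L,
                           species_pool = default_species_pool(),
                           carmean_pool = default_carmean_pool(),
                           nodata_fraction = 0.1,
                           trees_per_plot_range = c(20L, 60L),
                           dead_fraction = 0.15,
                           site_index_range = c(50, 90),
                           dia_range_in = c(1, 30),
                           age_range_yr = c(5, 120),
                           crs_id = "EPSG:3857") {
  if (!is_count(seed)) ricb_stop("ricb_argument_error", "seed must be an integer")
  for (f in c(nodata_fraction, dead_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      ricb_stop("ricb_argument_error", "fractions must lie in [0, 1]")
    }
  }
  for (rng in list(trees_per_plot_range, site_index_range, dia_range_in,
                   age_range_yr)) {
    if (length(rng) != 2L || any(!is.finite(rng)) || rng[1] > rng[2]) {
      ricb_stop("ricb_argument_error", "ranges must be nonempty (lo <= hi)")
    }
  }
  if (!is_count(n_plots) || n_plots < 1 ||
      !is_count(grid_rows) || grid_rows < 1 ||
      !is_count(grid_cols) || grid_cols < 1) {
    ricb_stop("ricb_argument_error", "grid dims and n_plots must be positive integers")
  }
  miss <- setdiff(unique(species_pool$e_spgrpcd), carmean_pool$e_spgrpcd)
  if (length(miss)) {
    ricb_stop("ricb_config_error",
              "species group(s) without Carmean coefficients in the pool: %s",
              paste(miss, collapse = ", "))
  }
  structure(list(
    seed = as.integer(seed), grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols), cell_size_m = cell_size_m,
    n_plots = as.integer(n_plots), species_pool = species_pool,
    carmean_pool = carmean_pool, nodata_fraction = nodata_fraction,
    trees_per_plot_range = as.integer(trees_per_plot_range),
    dead_fraction = dead_fraction, site_index_range = site_index_range,
    dia_range_in = dia_range_in, age_range_yr = age_range_yr,
    crs_id = crs_id), class = "fixture_config")
}

#' Generate a synthetic landscape
#'
#' Draws a complete, internally consistent input set for the pipeline: a
#' mapcode raster whose cells hold non-sequential 5-digit plot ids (or
#' nodata), a tree table, a plot site-index table, the species reference and
#' Carmean coefficient tables, and an AOI polygon. Tree heights are produced
#' by the *forward* Carmean curve from drawn true ages, so the age-inversion
#' stage has a known ground truth (returned as `truth`, row-parallel to
#' `trees`). The AOI is a rectangle rotated 15 degrees covering a strict
#' subset of the grid, expressed in geographic coordinates (EPSG:4326) while
#' the raster is in Web Mercator, so the reprojection path is always
#' exercised.
#'
#' @param config A [fixture_config()].
#' @return List: `raster` ([mapcode_raster()]), `trees`, `plots`,
#'   `species_ref`, `carmean`, `aoi` ([aoi_polygon()]), `truth`
#'   (`true_age_yr` per tree row), and the `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  sp <- config$species_pool

  plot_ids <- sort(sample(10000:99999, config$n_plots))
  ncell <- config$grid_rows * config$grid_cols
  cells <- plot_ids[sample.int(config$n_plots, ncell, replace = TRUE)]
  cells[stats::runif(ncell) < config$nodata_fraction] <- -9999L
  grid <- matrix(cells, nrow = config$grid_rows, ncol = config$grid_cols)

  # southeastern-US Web Mercator origin (~ 85.07 W, 33.8 N)
  raster <- mapcode_raster(grid, xll = -9470000, yll = 4005000,
                           cell_size_m = config$cell_size_m,
                           crs = config$crs_id, nodata = -9999L)

  plots <- data.frame(
    plot_id = plot_ids,
    site_index = stats::runif(config$n_plots, config$site_index_range[1],
                              config$site_index_range[2]))

  n_choices <- seq(config$trees_per_plot_range[1],
                   config$trees_per_plot_range[2])
  n_per <- n_choices[sample.int(length(n_choices), config$n_plots,
                                replace = TRUE)]
  n_tree <- sum(n_per)
  pid <- rep(plot_ids, n_per)
  sp_idx <- sample(nrow(sp), n_tree, replace = TRUE)
  true_age <- stats::runif(n_tree, config$age_range_yr[1],
                           config$age_range_yr[2])
  si_tree <- plots$site_index[match(pid, plots$plot_id)]
  ht <- numeric(n_tree)
  for (grp in unique(sp$e_spgrpcd)) {
    crow <- config$carmean_pool[match(grp, config$carmean_pool$e_spgrpcd), ]
    cf <- carmean_coefficients(crow$b1, crow$b2, crow$b3, crow$b4, crow$b5)
    idx <- which(sp$e_spgrpcd[sp_idx] == grp)
    ht[idx] <- carmean_height(true_age[idx], si_tree[idx], cf)
  }
  trees <- data.frame(
    plot_id = pid,
    species_symbol = sp$species_symbol[sp_idx],
    common_name = sp$common_name[sp_idx],
    e_spgrpcd = sp$e_spgrpcd[sp_idx],
    dia_in = stats::runif(n_tree, config$dia_range_in[1],
                          config$dia_range_in[2]),
    ht_ft = ht,
    alive = stats::runif(n_tree) >= config$dead_fraction,
    stringsAsFactors = FALSE)

  species_ref <- data.frame(
    SPECIES_SYMBOL = sp$species_symbol,
    COMMON_NAME = sp$common_name,
    E_SPGRPCD = sp$e_spgrpcd,
    JENKINS_SPGRPCD = sp$jenkins_spgrpcd,
    JENKINS_TOTAL_B1 = sp$jenkins_b1,
    JENKINS_TOTAL_B2 = sp$jenkins_b2,
    stringsAsFactors = FALSE)

  aoi <- make_rotated_aoi(raster, inset = 0.18, angle_deg = 15)

  list(raster = raster, trees = trees, plots = plots,
       species_ref = species_ref, carmean = config$carmean_pool,
       aoi = aoi, truth = data.frame(true_age_yr = true_age),
       config = config)
}

# Rotated interior rectangle of the raster extent, returned in EPSG:4326.
make_rotated_aoi <- function(raster, inset, angle_deg) {
  w <- ncol(raster$grid) * raster$cell_size_m
  h <- nrow(raster$grid) * raster$cell_size_m
  cx <- raster$xll + w / 2; cy <- raster$yll + h / 2
  hw <- w * (0.5 - inset); hh <- h * (0.5 - inset)
  corners <- rbind(c(-hw, -hh), c(hw, -hh), c(hw, hh), c(-hw, hh))
  th <- angle_deg * pi / 180
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  ring <- sweep(corners %*% t(rot), 2L, c(cx, cy), "+")
  transform_aoi(aoi_polygon(ring, crs = raster$crs), "EPSG:4326")
}

#' Write a synthetic landscape to disk
#'
#' Serializes every piece of a [generate_landscape()] result in the formats
#' the pipeline reads: `mapcode.asc` (+ `.prj`), `trees.csv`, `plots.csv`,
#' `species_ref.csv`, `carmean.csv`, `aoi.geojson`, `aoi.kml`, and
#' `truth_synthetic.csv` (the generator's true ages — synthetic ground
#' truth, not an inventory attribute).
#'
#' @param land Result of [generate_landscape()].
#' @param dir Output directory (created if absent).
#' @return Named list of the written paths, invisibly.
#' @export
write_landscape <- function(land, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    raster = file.path(dir, "mapcode.asc"),
    trees = file.path(dir, "trees.csv"),
    plots = file.path(dir, "plots.csv"),
    species_ref = file.path(dir, "species_ref.csv"),
    carmean = file.path(dir, "carmean.csv"),
    aoi_geojson = file.path(dir, "aoi.geojson"),
    aoi_kml = file.path(dir, "aoi.kml"),
    truth = file.path(dir, "truth_synthetic.csv"))
  write_mapcode_raster(land$raster, paths$raster)
  write_plain_csv(land$trees, paths$trees)
  write_plain_csv(land$plots, paths$plots)
  write_plain_csv(land$species_ref, paths$species_ref)
  write_plain_csv(land$carmean, paths$carmean)
  write_aoi_geojson(land$aoi, paths$aoi_geojson)
  write_aoi_kml(land$aoi, paths$aoi_kml)
  write_plain_csv(land$truth, paths$truth)
  invisible(paths)
}

#' Read the tabular landscape inputs
#'
#' Column-checked readers for the four CSV tables the pipeline consumes.
#' `read_species_ref` expects the reference layout
#' `SPECIES_SYMBOL,COMMON_NAME,E_SPGRPCD,JENKINS_SPGRPCD,JENKINS_TOTAL_B1,JENKINS_TOTAL_B2`;
#' `read_carmean_table` expects `e_spgrpcd,b1,b2,b3,b4,b5`.
#'
#' @param path CSV path.
#' @return The table as a data frame.
#' @export
read_tree_table <- function(path) {
  df <- read_checked_csv(path, c("plot_id", "species_symbol", "common_name",
                                 "e_spgrpcd", "dia_in", "ht_ft", "alive"))
  df$alive <- as.logical(df$alive)
  df
}

#' @rdname read_tree_table
#' @export
read_plot_table <- function(path) {
  read_checked_csv(path, c("plot_id", "site_index"))
}

#' @rdname read_tree_table
#' @export
read_species_ref <- function(path) {
  read_checked_csv(path, c("SPECIES_SYMBOL", "COMMON_NAME", "E_SPGRPCD",
                           "JENKINS_SPGRPCD", "JENKINS_TOTAL_B1",
                           "JENKINS_TOTAL_B2"))
}

#' @rdname read_tree_table
#' @export
read_carmean_table <- function(path) {
  read_checked_csv(path, c("e_spgrpcd", "b1", "b2", "b3", "b4", "b5"))
}

read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) ricb_stop("ricb_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(columns, names(df))
  if (length(miss)) {
    ricb_stop("ricb_format_error", "%s missing column '%s'",
              basename(path), miss[1])
  }
  df[columns]
}
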