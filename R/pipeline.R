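#' Write the initial-communities lookup table
#'
#' CSV with header exactly
#' `MapCode,SpeciesName,CohortAge,CohortBiomass,WoodBiomass,LeafBiomass`
#' (biomass columns in g/m^2). By default values are written at full
#' precision; `round_int = TRUE` rounds biomass to integers (half away from
#' zero), drops cohorts that round to zero and logs how many.
#'
#' @param records Cohort table from [build_cohorts()].
#' @param path Output CSV path.
#' @param overwrite Refuse to replace an existing file unless `TRUE`.
#' @param round_int Write integer biomass values.
#' @return `path` invisibly, with attribute `log`.
#' @export
write_initial_communities <- function(records, path, overwrite = FALSE,
                                      round_int = FALSE) {
  if (file.exists(path) && !overwrite) {
    ricb_stop("ricb_overwrite_error",
              "output exists (use overwrite = TRUE): %s", path)
  }
  log <- character()
  out <- data.frame(
    MapCode = records$map_code,
    SpeciesName = records$species_symbol,
    CohortAge = records$cohort_age_yr,
    CohortBiomass = records$cohort_biomass_g_m2,
    WoodBiomass = records$wood_biomass_g_m2,
    LeafBiomass = records$leaf_biomass_g_m2,
    stringsAsFactors = FALSE)
  if (round_int) {
    out$CohortBiomass <- round_half_away(out$CohortBiomass)
    out$WoodBiomass <- round_half_away(out$WoodBiomass)
    out$LeafBiomass <- round_half_away(out$LeafBiomass)
    zero <- out$CohortBiomass == 0
    if (any(zero)) {
      log <- c(log, sprintf("dropped_cohort reason=rounds_to_zero n=%d", sum(zero)))
      out <- out[!zero, , drop = FALSE]
    }
  }
  if (nrow(out) == 0L) {
    ricb_warn("ricb_empty_output", "no cohort records; writing header-only file")
  }
  write_plain_csv(out, path)
  invisible(structure(path, log = log))
}

#' Write the initial-communities map
#'
#' The sequential mapcode raster written with nodata encoded as 0 (the
#' LANDIS-II inactive-cell convention), georeferencing and CRS preserved
#' from the clipped source. Format: ESRI ASCII grid with `.prj` sidecar.
#'
#' @param raster A remapped [mapcode_raster()] (values `1..K`).
#' @param path Output `.asc` path.
#' @param overwrite Refuse to replace an existing file unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_map <- function(raster, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    ricb_stop("ricb_overwrite_error",
              "output exists (use overwrite = TRUE): %s", path)
  }
  if (is.null(raster$crs) || !nzchar(raster$crs)) {
    ricb_stop("ricb_crs_error", "raster has no CRS; refusing to write map")
  }
  out <- raster
  out$grid[out$grid == out$nodata] <- 0L
  out$nodata <- 0L
  write_mapcode_raster(out, path)
  invisible(path)
}

#' Write the species parameterization list
#'
#' CSV with header `SPECIES_SYMBOL,COMMON_NAME`, one row per selected
#' species sorted by symbol — the lookup users parameterize succession
#' extensions from.
#'
#' @param summaries Abundance table from [species_abundance()].
#' @param selected Character vector of selected symbols.
#' @param path Output CSV path.
#' @param overwrite Refuse to replace an existing file unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_parameterization_list <- function(summaries, selected, path,
                                        overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    ricb_stop("ricb_overwrite_error",
              "output exists (use overwrite = TRUE): %s", path)
  }
  rows <- summaries[summaries$species_symbol %in% selected, , drop = FALSE]
  rows <- rows[order(rows$species_symbol), ]
  out <- data.frame(SPECIES_SYMBOL = rows$species_symbol,
                    COMMON_NAME = rows$common_name,
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    ricb_warn("ricb_empty_output", "no species selected; writing header-only file")
  }
  write_plain_csv(out, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every choice a run needs: input paths, spatial resolution factor,
#' cohort timestep, the species-selection threshold and overrides, the
#' wood/leaf split, and output behaviour. The pipeline is deterministic, so
#' no seed is involved.
#'
#' @param raster_path Path to the mapcode `.asc` raster.
#' @param tiles_dir Directory of landis tiles with a `manifest.csv`.
#' @param aoi_path Path to the AOI polygon (GeoJSON or KML).
#' @param out_dir Output directory (created if absent).
#' @param resolution_factor 1 for native resolution, or an integer >= 2 to
#'   mode-aggregate (10 turns 30 m into 300 m).
#' @param timestep Positive integer cohort age-class width in years.
#' @param threshold Species-selection biomass fraction cutoff.
#' @param include,exclude Species symbol overrides for the selection.
#' @param leaf_fraction Leaf share of cohort biomass in `[0, 1]`.
#' @param round_int Write Table-style integer biomass values.
#' @param overwrite Replace existing outputs.
#' @return A validated `ricb_config` list.
#' @export
ricb_config <- function(raster_path, tiles_dir, aoi_path, out_dir,
                        resolution_factor = 1, timestep = 10,
                        threshold = 0.01, include = character(),
                        exclude = character(), leaf_fraction = 0,
                        round_int = FALSE, overwrite = FALSE) {
  for (p in c(raster_path, aoi_path)) {
    if (!file.exists(p)) ricb_stop("ricb_io_error", "input not found: %s", p)
  }
  if (!dir.exists(tiles_dir)) {
    ricb_stop("ricb_io_error", "tiles directory not found: %s", tiles_dir)
  }
  if (!is_count(resolution_factor) || resolution_factor < 1) {
    ricb_stop("ricb_argument_error", "resolution_factor must be an integer >= 1")
  }
  if (!is_count(timestep) || timestep < 1) {
    ricb_stop("ricb_argument_error", "timestep must be a positive integer")
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    ricb_stop("ricb_argument_error", "threshold must be in [0, 1]")
  }
  structure(list(
    raster_path = raster_path, tiles_dir = tiles_dir, aoi_path = aoi_path,
    out_dir = out_dir, resolution_factor = as.integer(resolution_factor),
    timestep = as.integer(timestep), threshold = threshold,
    include = include, exclude = exclude, leaf_fraction = leaf_fraction,
    round_int = isTRUE(round_int), overwrite = isTRUE(overwrite)),
    class = "ricb_config")
}

run_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (!inherits(e, "ricb_stage_error")) {
      stop(errorCondition(
        sprintf("[%s] %s", stage, conditionMessage(e)),
        class = unique(c("ricb_stage_error", class(e)))))
    }
  })
}

#' Run the full initial-communities pipeline
#'
#' Executes clip -> optional mode aggregation -> sequential remap -> species
#' abundance -> selection -> cohort assembly, then writes the three outputs
#' into `out_dir`: `ricb_initial_communities.csv`,
#' `ricb_initial_communities.asc` (+ `.prj`), and
#' `parameterization_list.csv`, plus `run_log.txt` with one structured line
#' per event (dropped cohort, empty mapcode, ...). Any stage failure raises
#' an error prefixed with the stage name.
#'
#' @param config A [ricb_config()].
#' @return Invisibly, a list: output `paths`, the `log`, the abundance
#'   `summaries`, the `selected` symbols, and the cohort `records`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ricb_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    communities = file.path(config$out_dir, "ricb_initial_communities.csv"),
    map = file.path(config$out_dir, "ricb_initial_communities.asc"),
    species = file.path(config$out_dir, "parameterization_list.csv"),
    log = file.path(config$out_dir, "run_log.txt"))
  if (!config$overwrite) {
    for (p in paths[1:3]) {
      if (file.exists(p)) {
        ricb_stop("ricb_overwrite_error",
                  "output exists (use overwrite): %s", p)
      }
    }
  }

  raster <- run_stage("read_raster", read_mapcode_raster(config$raster_path))
  tiles <- run_stage("read_tiles", read_tiles(config$tiles_dir))
  aoi <- run_stage("read_aoi", read_aoi(config$aoi_path))

  clipped <- run_stage("clip", clip_to_aoi(raster, aoi))
  if (config$resolution_factor > 1L) {
    clipped <- run_stage("aggregate",
                         mode_aggregate(clipped, config$resolution_factor))
  }
  rm_out <- run_stage("remap", remap_sequential(clipped))

  summaries <- run_stage("abundance",
                         species_abundance(tiles, rm_out$raster, rm_out$remap))
  selected <- run_stage("select",
                        select_species(summaries, config$threshold,
                                       config$include, config$exclude))
  records <- run_stage("cohorts",
                       build_cohorts(tiles, rm_out$raster, rm_out$remap,
                                     selected, config$timestep,
                                     config$leaf_fraction))
  log <- c(attr(tiles, "log"), attr(records, "log"))

  wr <- run_stage("write_csv",
                  suppressWarnings(write_initial_communities(
                    records, paths$communities, overwrite = config$overwrite,
                    round_int = config$round_int)))
  log <- c(log, attr(wr, "log"))
  run_stage("write_map",
            write_map(rm_out$raster, paths$map, overwrite = config$overwrite))
  run_stage("write_species",
            suppressWarnings(write_parameterization_list(
              summaries, selected, paths$species,
              overwrite = config$overwrite)))
  writeLines(log, paths$log)

  invisible(list(paths = paths, log = log, summaries = summaries,
                 selected = selected, records = records))
}
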