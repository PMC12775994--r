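#' Build landis tiles from an augmented tree database
#'
#' Computes per-tree aboveground biomass ([jenkins_biomass()]) and age
#' ([carmean_age()], via the plot's site index and the species group's
#' Carmean coefficients) for every alive tree, then emits one "landis tile"
#' per plot: a table of (species, age, biomass) rows that downstream cohort
#' assembly treats as the community of every pixel imputed to that plot.
#'
#' Dead trees are excluded. Alive trees with `dia_in == 0` (below
#' breast-height measurement) are dropped and counted in the log; alive trees
#' with `ht_ft == 0` are kept with age and biomass 0. An alive tree whose
#' plot lacks a site index, or whose species group lacks Carmean
#' coefficients, is a hard error naming the plot or group.
#'
#' @param trees Tree table: `plot_id`, `species_symbol`, `common_name`,
#'   `e_spgrpcd`, `dia_in`, `ht_ft`, `alive`.
#' @param plots Plot table: `plot_id`, `site_index`.
#' @param species_ref Species reference table mapping `SPECIES_SYMBOL` to
#'   `JENKINS_TOTAL_B1`, `JENKINS_TOTAL_B2` (shape of [read_species_ref()]).
#' @param carmean_table Data frame `e_spgrpcd`, `b1`..`b5` (shape of
#'   [read_carmean_table()]).
#' @param max_age_yr Clamp ceiling passed to [carmean_age()].
#' @return Named list of `landis_tile` data frames keyed by plot id, with a
#'   `log` attribute (character vector of structured events).
#' @export
augment_and_build_tiles <- function(trees, plots, species_ref, carmean_table,
                                    max_age_yr = 300) {
  alive <- trees[trees$alive, , drop = FALSE]
  if (nrow(alive) == 0L) {
    ricb_stop("ricb_argument_error", "no alive trees in input")
  }
  log <- character()

  miss_plot <- setdiff(unique(alive$plot_id), plots$plot_id)
  if (length(miss_plot)) {
    ricb_stop("ricb_linkage_error",
              "alive trees reference plot(s) with no site index: %s",
              paste(miss_plot, collapse = ", "))
  }
  si <- plots$site_index[match(alive$plot_id, plots$plot_id)]
  if (any(si <= 0)) {
    ricb_stop("ricb_linkage_error", "non-positive site index for plot(s): %s",
              paste(unique(alive$plot_id[si <= 0]), collapse = ", "))
  }
  miss_grp <- setdiff(unique(alive$e_spgrpcd), carmean_table$e_spgrpcd)
  if (length(miss_grp)) {
    ricb_stop("ricb_linkage_error",
              "species group(s) without Carmean coefficients: %s",
              paste(miss_grp, collapse = ", "))
  }
  miss_sym <- setdiff(unique(alive$species_symbol), species_ref$SPECIES_SYMBOL)
  if (length(miss_sym)) {
    ricb_stop("ricb_linkage_error",
              "species without Jenkins coefficients: %s",
              paste(miss_sym, collapse = ", "))
  }

  drop0 <- alive$dia_in == 0
  if (any(drop0)) {
    log <- c(log, sprintf("dropped_tree reason=dia0 n=%d", sum(drop0)))
    alive <- alive[!drop0, , drop = FALSE]
    si <- si[!drop0]
  }

  jrow <- match(alive$species_symbol, species_ref$SPECIES_SYMBOL)
  biomass <- jenkins_biomass(alive$dia_in,
                             species_ref$JENKINS_TOTAL_B1[jrow],
                             species_ref$JENKINS_TOTAL_B2[jrow])

  age <- numeric(nrow(alive))
  n_clamped <- 0L
  for (grp in unique(alive$e_spgrpcd)) {
    idx <- which(alive$e_spgrpcd == grp)
    crow <- carmean_table[match(grp, carmean_table$e_spgrpcd), ]
    cf <- carmean_coefficients(crow$b1, crow$b2, crow$b3, crow$b4, crow$b5)
    pos <- alive$ht_ft[idx] > 0
    a <- numeric(length(idx))
    if (any(pos)) {
      a[pos] <- withCallingHandlers(
        carmean_age(alive$ht_ft[idx][pos], si[idx][pos], cf, max_age_yr),
        ricb_clamped_age = function(w) invokeRestart("muffleWarning"))
      asym <- cf["b1"] * si[idx][pos]^cf["b2"]
      n_clamped <- n_clamped + sum(alive$ht_ft[idx][pos] >= asym)
    }
    age[idx] <- a
  }
  # ht_ft == 0: age and biomass both reported as 0 (sapling convention)
  ht0 <- alive$ht_ft == 0
  biomass[ht0] <- 0
  if (n_clamped > 0L) log <- c(log, sprintf("clamped_age n=%d", n_clamped))

  tiles <- lapply(split(seq_len(nrow(alive)), alive$plot_id), function(idx) {
    tile <- data.frame(
      MapCode = rep(NA_integer_, length(idx)),
      SPECIES_SYMBOL = alive$species_symbol[idx],
      COMMON_NAME = alive$common_name[idx],
      E_SPGRPCD = alive$e_spgrpcd[idx],
      age = age[idx],
      biomass = biomass[idx],
      stringsAsFactors = FALSE)
    rownames(tile) <- NULL
    attr(tile, "plot_id") <- alive$plot_id[idx[1]]
    class(tile) <- c("landis_tile", "data.frame")
    tile
  })
  # split() orders keys as character; restore numeric plot-id order
  tiles <- tiles[order(as.numeric(names(tiles)))]
  attr(tiles, "log") <- log
  tiles
}

tile_columns <- c("MapCode", "SPECIES_SYMBOL", "COMMON_NAME", "E_SPGRPCD",
                  "age", "biomass")

#' Write / read a landis tile
#'
#' One CSV per plot, named `<plot_id>.csv`, with exactly the columns
#' `MapCode, SPECIES_SYMBOL, COMMON_NAME, E_SPGRPCD, age, biomass`; the
#' MapCode column is blank on write (it is filled conceptually by the spatial
#' linkage stage). A file missing any of the six columns is a format error
#' naming the first missing column.
#'
#' @param tile A `landis_tile` data frame.
#' @param dir Directory the tile file is written into.
#' @return `write_tile`: the file path, invisibly. `read_tile`: the tile.
#' @export
write_tile <- function(tile, dir) {
  pid <- attr(tile, "plot_id")
  path <- file.path(dir, paste0(pid, ".csv"))
  out <- as.data.frame(tile)[tile_columns]
  write_plain_csv(out, path)
  invisible(path)
}

#' @rdname write_tile
#' @param path Path of a tile CSV; the plot id is taken from the file name.
#' @export
read_tile <- function(path) {
  if (!file.exists(path)) ricb_stop("ricb_io_error", "tile file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(tile_columns, names(df))
  if (length(miss)) {
    ricb_stop("ricb_format_error", "tile file %s missing column '%s'",
              basename(path), miss[1])
  }
  df <- df[tile_columns]
  df$MapCode <- as.integer(df$MapCode)
  attr(df, "plot_id") <- as.integer(tools::file_path_sans_ext(basename(path)))
  class(df) <- c("landis_tile", "data.frame")
  df
}

#' Write / read a tile directory
#'
#' Writes every tile as `<dir>/<plot_id>.csv` plus a `manifest.csv`
#' (`plot_id,filename`); reads a directory back through its manifest.
#'
#' @param tiles Named list of tiles (as from [augment_and_build_tiles()]).
#' @param dir Tile directory (created if absent).
#' @return `write_tiles`: `dir`, invisibly. `read_tiles`: named tile list.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tile in tiles) write_tile(tile, dir)
  manifest <- data.frame(
    plot_id = as.integer(names(tiles)),
    filename = paste0(names(tiles), ".csv"),
    stringsAsFactors = FALSE)
  write_plain_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) {
    ricb_stop("ricb_io_error", "tile manifest not found: %s", mpath)
  }
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  tiles <- lapply(manifest$filename, function(f) read_tile(file.path(dir, f)))
  names(tiles) <- manifest$plot_id
  tiles
}
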