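#' Domain-wide species abundance ranking
#'
#' Computes each species' total aboveground biomass over the clipped domain,
#' pixel-weighted: a plot's per-tree biomass counts once for every raster
#' pixel imputed to that plot. Fractions are normalized by the grand total
#' over all species, and the table is sorted descending by fraction — the
#' ranking the species-selection step presents.
#'
#' @param tiles Named list of tiles keyed by plot id.
#' @param raster A remapped [mapcode_raster()] (values `1..K`).
#' @param remap Remap table from [remap_sequential()].
#' @return Data frame `species_symbol`, `common_name`, `total_biomass_kg`,
#'   `fraction`, sorted descending by fraction.
#' @export
species_abundance <- function(tiles, raster, remap) {
  vals <- raster_values(raster)
  if (!length(vals)) ricb_stop("ricb_empty_clip", "raster is entirely nodata")
  px <- table(vals)
  codes <- as.integer(names(px))
  totals <- list()
  common <- character()
  for (k in seq_along(codes)) {
    orig <- remap$original[match(codes[k], remap$sequential)]
    if (is.na(orig)) {
      ricb_stop("ricb_linkage_error",
                "raster code %d has no entry in the remap table", codes[k])
    }
    tile <- tiles[[as.character(orig)]]
    if (is.null(tile)) {
      ricb_stop("ricb_linkage_error",
                "raster code %d (plot %d) has no landis tile", codes[k], orig)
    }
    per_sp <- tapply(tile$biomass, tile$SPECIES_SYMBOL, sum)
    for (sp in names(per_sp)) {
      totals[[sp]] <- (if (is.null(totals[[sp]])) 0 else totals[[sp]]) +
        per_sp[[sp]] * as.numeric(px[k])
    }
    common[unique(tile$SPECIES_SYMBOL)] <-
      tile$COMMON_NAME[match(unique(tile$SPECIES_SYMBOL), tile$SPECIES_SYMBOL)]
  }
  grand <- sum(unlist(totals))
  if (grand <= 0) {
    ricb_stop("ricb_empty_clip",
              "no alive-tree biomass in the clipped domain")
  }
  df <- data.frame(
    species_symbol = names(totals),
    common_name = unname(common[names(totals)]),
    total_biomass_kg = unname(unlist(totals)),
    stringsAsFactors = FALSE)
  df$fraction <- df$total_biomass_kg / grand
  df <- df[order(-df$fraction, df$species_symbol), ]
  rownames(df) <- NULL
  df
}

#' Select species for the initial-communities file
#'
#' Default selection is every species whose biomass fraction strictly
#' exceeds `threshold` (1% by default). `include` force-adds species (the
#' "niche species under 1%" mechanism) and `exclude` removes them; only the
#' resulting set appears in the final output.
#'
#' @param summaries Abundance table from [species_abundance()].
#' @param threshold Fraction cutoff in `[0, 1]`; strict inequality.
#' @param include,exclude Character vectors of species symbols.
#' @return Sorted character vector of selected symbols.
#' @export
select_species <- function(summaries, threshold = 0.01,
                           include = character(), exclude = character()) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    ricb_stop("ricb_argument_error", "threshold must be in [0, 1]")
  }
  unknown <- setdiff(include, summaries$species_symbol)
  if (length(unknown)) {
    ricb_stop("ricb_argument_error",
              "include names species absent from the domain: %s",
              paste(sort(unknown), collapse = ", "))
  }
  sel <- summaries$species_symbol[summaries$fraction > threshold]
  sort(setdiff(union(sel, include), exclude))
}

#' Bin a tree age into a cohort age class
#'
#' LANDIS-II cohorts carry positive ages that are multiples of the
#' simulation timestep; a tree of age `a` joins the cohort
#' `ceiling(a / timestep) * timestep`, with a minimum of one timestep
#' (age 0 joins the first class). Vectorized over `age_yr`.
#'
#' @param age_yr Non-negative tree age(s) in years (fractional allowed).
#' @param timestep Positive integer age-class width in years.
#' @return Cohort age(s): positive multiples of `timestep`.
#' @export
bin_age <- function(age_yr, timestep) {
  if (!is_count(timestep) || timestep < 1) {
    ricb_stop("ricb_argument_error", "timestep must be a positive integer")
  }
  if (any(!is.finite(age_yr)) || any(age_yr < 0)) {
    ricb_stop("ricb_domain_error", "age_yr must be non-negative")
  }
  pmax(ceiling(age_yr / timestep), 1) * timestep
}

#' Assemble species-age-biomass cohorts per map code
#'
#' For each map code, the rows of its tile restricted to the selected
#' species are binned by [bin_age()] and summed within (species, age class);
#' the summed kilograms are converted to grams per square metre of one pixel
#' (`kg * 1000 / cell_size_m^2`), the unit LANDIS-II requires. The wood/leaf
#' split is `leaf = leaf_fraction * total`, `wood = total - leaf`. Map codes
#' whose tiles contain no selected species yield no records and are logged.
#'
#' @param tiles Named list of tiles keyed by plot id.
#' @param raster A remapped [mapcode_raster()].
#' @param remap Remap table from [remap_sequential()].
#' @param selected Character vector of selected species symbols.
#' @param timestep Positive integer age-class width.
#' @param leaf_fraction Fraction of cohort biomass assigned to leaves
#'   (default 0: all wood).
#' @return Data frame of cohort records sorted by (map_code, species_symbol,
#'   cohort_age_yr), with a `log` attribute.
#' @export
build_cohorts <- function(tiles, raster, remap, selected, timestep,
                          leaf_fraction = 0) {
  if (!is.numeric(leaf_fraction) || leaf_fraction < 0 || leaf_fraction > 1) {
    ricb_stop("ricb_argument_error", "leaf_fraction must be in [0, 1]")
  }
  cell_area <- raster$cell_size_m^2
  codes <- sort(unique(raster_values(raster)))
  log <- character()
  recs <- vector("list", length(codes))
  for (k in seq_along(codes)) {
    orig <- remap$original[match(codes[k], remap$sequential)]
    tile <- tiles[[as.character(orig)]]
    if (is.null(tile)) {
      ricb_stop("ricb_linkage_error",
                "raster code %d (plot %d) has no landis tile", codes[k], orig)
    }
    rows <- tile[tile$SPECIES_SYMBOL %in% selected, , drop = FALSE]
    if (nrow(rows) == 0L) {
      log <- c(log, sprintf("empty_mapcode code=%d plot=%d", codes[k], orig))
      next
    }
    bins <- bin_age(rows$age, timestep)
    agg <- stats::aggregate(rows$biomass,
                            by = list(species_symbol = rows$SPECIES_SYMBOL,
                                      cohort_age_yr = bins),
                            FUN = sum)
    total <- agg$x * 1000 / cell_area
    leaf <- leaf_fraction * total
    recs[[k]] <- data.frame(
      map_code = codes[k],
      species_symbol = agg$species_symbol,
      cohort_age_yr = as.integer(agg$cohort_age_yr),
      cohort_biomass_g_m2 = total,
      wood_biomass_g_m2 = total - leaf,
      leaf_biomass_g_m2 = leaf,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(map_code = integer(), species_symbol = character(),
                      cohort_age_yr = integer(),
                      cohort_biomass_g_m2 = numeric(),
                      wood_biomass_g_m2 = numeric(),
                      leaf_biomass_g_m2 = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$map_code, out$species_symbol, out$cohort_age_yr), ]
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Compare species biomass shares between two abundance rankings
#'
#' Generic side-by-side comparison of two [species_abundance()] tables (two
#' products, two runs, two resolutions): aligns the union of the top-`top_n`
#' species of each, reports both %AGB columns, and counts how many of the
#' top species are shared.
#'
#' @param summaries_a,summaries_b Abundance tables from [species_abundance()].
#' @param top_n Number of leading species to compare (default 10).
#' @return Data frame `species_symbol`, `pct_agb_a`, `pct_agb_b` (percent,
#'   `NA` where absent), sorted by `pct_agb_a` descending, with attribute
#'   `n_shared` (shared species among the two top-`top_n` sets).
#' @export
compare_species_abundance <- function(summaries_a, summaries_b, top_n = 10L) {
  if (!is_count(top_n) || top_n < 1) {
    ricb_stop("ricb_argument_error", "top_n must be a positive integer")
  }
  top_a <- utils::head(summaries_a$species_symbol, top_n)
  top_b <- utils::head(summaries_b$species_symbol, top_n)
  syms <- union(top_a, top_b)
  out <- data.frame(
    species_symbol = syms,
    pct_agb_a = 100 * summaries_a$fraction[match(syms, summaries_a$species_symbol)],
    pct_agb_b = 100 * summaries_b$fraction[match(syms, summaries_b$species_symbol)],
    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$pct_agb_a), -Inf, out$pct_agb_a)), ]
  rownames(out) <- NULL
  attr(out, "n_shared") <- length(intersect(top_a, top_b))
  out
}
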