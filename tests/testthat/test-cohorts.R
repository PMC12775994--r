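simple_tile <- function(plot_id, species, common, biomass, age) {
  tile <- data.frame(MapCode = NA_integer_, SPECIES_SYMBOL = species,
                     COMMON_NAME = common, E_SPGRPCD = 1L,
                     age = age, biomass = biomass, stringsAsFactors = FALSE)
  attr(tile, "plot_id") <- plot_id
  class(tile) <- c("landis_tile", "data.frame")
  tile
}

two_plot_setup <- function() {
  # plot 101 covers 2 pixels (A: 300 kg), plot 102 covers 4 pixels (B: 100 kg)
  grid <- matrix(c(101L, 101L, 102L, 102L, 102L, 102L), 2, 3)
  raster <- mapcode_raster(grid, 0, 0, 30, crs = "EPSG:3857")
  rm_out <- remap_sequential(raster)
  tiles <- list(
    "101" = simple_tile(101L, "AAAA", "species a", 300, 20),
    "102" = simple_tile(102L, "BBBB", "species b", 100, 35))
  list(raster = rm_out$raster, remap = rm_out$remap, tiles = tiles)
}

test_that("species_abundance weights plot biomass by pixel count", {
  s <- two_plot_setup()
  summ <- species_abundance(s$tiles, s$raster, s$remap)
  expect_equal(summ$species_symbol, c("AAAA", "BBBB"))
  expect_equal(summ$fraction, c(0.6, 0.4))  # (300*2)/(300*2+100*4), hand-derived
  expect_equal(summ$total_biomass_kg, c(600, 400))
  expect_equal(sum(summ$fraction), 1, tolerance = 1e-9)
})

test_that("a single species everywhere has fraction one", {
  grid <- matrix(rep(55L, 9), 3, 3)
  rm_out <- remap_sequential(mapcode_raster(grid, 0, 0, 30))
  tiles <- list("55" = simple_tile(55L, "PITA", "loblolly pine", 12.5, 40))
  summ <- species_abundance(tiles, rm_out$raster, rm_out$remap)
  expect_equal(summ$fraction, 1)
})

test_that("abundance fails on unlinked codes or an empty domain", {
  s <- two_plot_setup()
  expect_error(species_abundance(s$tiles["101"], s$raster, s$remap),
               class = "ricb_linkage_error")
  zero <- list("101" = simple_tile(101L, "AAAA", "a", 0, 10),
               "102" = simple_tile(102L, "BBBB", "b", 0, 10))
  expect_error(species_abundance(zero, s$raster, s$remap),
               class = "ricb_empty_clip")
})

test_that("select_species applies the strict threshold with overrides", {
  summ <- data.frame(
    species_symbol = c("AAAA", "BBBB", "CCCC", "DDDD"),
    common_name = letters[1:4],
    total_biomass_kg = c(600, 390, 9, 1),
    fraction = c(0.60, 0.39, 0.009, 0.001),
    stringsAsFactors = FALSE)
  expect_equal(select_species(summ), c("AAAA", "BBBB"))
  expect_equal(select_species(summ, include = "CCCC"),
               c("AAAA", "BBBB", "CCCC"))
  expect_equal(select_species(summ, exclude = "BBBB"), "AAAA")
  # threshold 0: everything with positive biomass
  expect_equal(select_species(summ, threshold = 0),
               c("AAAA", "BBBB", "CCCC", "DDDD"))
  # exactly at the threshold is excluded (strict >)
  at <- summ; at$fraction <- c(0.98, 0.01, 0.005, 0.005)
  expect_equal(select_species(at), "AAAA")
  expect_error(select_species(summ, include = c("ZZZZ", "YYYY")),
               "YYYY, ZZZZ", class = "ricb_argument_error")
})

test_that("raising the threshold never adds species", {
  set.seed(51)
  fr <- runif(12); fr <- fr / sum(fr)
  summ <- data.frame(species_symbol = sprintf("SP%02d", 1:12),
                     common_name = sprintf("species %d", 1:12),
                     total_biomass_kg = fr * 1000, fraction = fr,
                     stringsAsFactors = FALSE)
  prev <- select_species(summ, threshold = 0)
  for (th in c(0.005, 0.01, 0.05, 0.1, 0.3)) {
    cur <- select_species(summ, threshold = th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("bin_age implements ceiling binning with a minimum of one timestep", {
  expect_equal(bin_age(15.0, 5L), 15)
  expect_equal(bin_age(14.97, 5L), 15)
  expect_equal(bin_age(0.3, 5L), 5)
  expect_equal(bin_age(0, 5L), 5)
  expect_equal(bin_age(15.01, 5L), 20)
  expect_equal(bin_age(c(1, 9.99, 10, 10.01), 10L), c(10, 10, 10, 20))
  expect_error(bin_age(-1, 5L), class = "ricb_domain_error")
  expect_error(bin_age(10, 0L), class = "ricb_argument_error")
})

test_that("build_cohorts converts kilograms per pixel to g/m2 and groups by bin", {
  grid <- matrix(7L, 1, 1)
  rm_out <- remap_sequential(mapcode_raster(grid, 0, 0, 30))
  # one 0.9 kg tree on a 30 m cell: 900 g / 900 m2 = 1 g/m2
  tiles <- list("7" = simple_tile(7L, "PITA", "loblolly pine", 0.9, 12))
  rec <- build_cohorts(tiles, rm_out$raster, rm_out$remap, "PITA",
                       timestep = 5L)
  expect_equal(rec$cohort_biomass_g_m2, 1.0)
  expect_equal(rec$cohort_age_yr, 15L)
  expect_equal(rec$wood_biomass_g_m2, 1.0)
  expect_equal(rec$leaf_biomass_g_m2, 0)
  # two same-species trees land in distinct bins with their own biomass
  tiles2 <- list("7" = simple_tile(7L, rep("QUNI", 2), rep("water oak", 2),
                                   c(26.99, 3.89), c(14.97, 8.2)))
  rec2 <- build_cohorts(tiles2, rm_out$raster, rm_out$remap, "QUNI",
                        timestep = 5L)
  expect_equal(rec2$cohort_age_yr, c(10L, 15L))
  expect_equal(rec2$cohort_biomass_g_m2, c(3.89, 26.99) * 1000 / 900)
  # leaf fraction splits without changing the total
  rec3 <- build_cohorts(tiles2, rm_out$raster, rm_out$remap, "QUNI",
                        timestep = 5L, leaf_fraction = 0.25)
  expect_equal(rec3$leaf_biomass_g_m2, 0.25 * rec3$cohort_biomass_g_m2)
  expect_equal(rec3$wood_biomass_g_m2 + rec3$leaf_biomass_g_m2,
               rec3$cohort_biomass_g_m2)
})

test_that("mapcodes with no selected species yield no records but are logged", {
  s <- two_plot_setup()
  rec <- build_cohorts(s$tiles, s$raster, s$remap, "AAAA", timestep = 10L)
  expect_equal(unique(rec$map_code), 1L)
  expect_true(any(grepl("empty_mapcode code=2", attr(rec, "log"))))
})

test_that("binning conserves pixel-weighted biomass at every timestep", {
  land <- generate_landscape(fixture_config(seed = 29, grid_rows = 25,
                                            grid_cols = 25, n_plots = 12))
  tiles <- augment_and_build_tiles(land$trees, land$plots, land$species_ref,
                                   land$carmean)
  clipped <- clip_to_aoi(land$raster, land$aoi)
  rm_out <- remap_sequential(clipped)
  summ <- species_abundance(tiles, rm_out$raster, rm_out$remap)
  selected <- select_species(summ)
  want <- oracle_total_grams(tiles, rm_out$raster, rm_out$remap, selected)
  cell_area <- rm_out$raster$cell_size_m^2
  px <- table(raster_values(rm_out$raster))
  per_ts <- lapply(c(1L, 5L, 10L, 25L), function(ts) {
    rec <- build_cohorts(tiles, rm_out$raster, rm_out$remap, selected, ts)
    got <- sum(rec$cohort_biomass_g_m2 * cell_area *
                 as.numeric(px[as.character(rec$map_code)]))
    expect_equal(got, want, tolerance = 1e-6)
    # per (mapcode, species) totals are invariant under the timestep
    agg <- aggregate(rec$cohort_biomass_g_m2,
                     by = list(rec$map_code, rec$species_symbol), FUN = sum)
    agg <- agg[order(agg[[1]], agg[[2]]), ]
    rownames(agg) <- NULL
    agg
  })
  for (i in 2:4) expect_equal(per_ts[[i]], per_ts[[1]], tolerance = 1e-9)
  # finer timesteps never have fewer cohorts per (mapcode, species)
  n1 <- nrow(build_cohorts(tiles, rm_out$raster, rm_out$remap, selected, 1L))
  n25 <- nrow(build_cohorts(tiles, rm_out$raster, rm_out$remap, selected, 25L))
  expect_gte(n1, n25)
})

test_that("abundance comparison aligns top species and counts the overlap", {
  mk <- function(syms, fr) data.frame(species_symbol = syms,
                                      common_name = syms,
                                      total_biomass_kg = fr * 100,
                                      fraction = fr, stringsAsFactors = FALSE)
  a <- mk(c("QUPR", "QUAL", "ACRU", "PIST"), c(0.4, 0.3, 0.2, 0.1))
  b <- mk(c("QUPR", "ACRU", "BELE", "QUAL"), c(0.35, 0.3, 0.2, 0.15))
  cmp <- compare_species_abundance(a, b, top_n = 3L)
  expect_setequal(cmp$species_symbol, c("QUPR", "QUAL", "ACRU", "BELE"))
  expect_equal(attr(cmp, "n_shared"), 2L)  # QUPR, ACRU in both top-3
  expect_equal(cmp$pct_agb_a[cmp$species_symbol == "QUPR"], 40)
  expect_true(is.na(cmp$pct_agb_a[cmp$species_symbol == "BELE"]))
  # a product compared with itself agrees everywhere
  self <- compare_species_abundance(a, a)
  expect_equal(self$pct_agb_a, self$pct_agb_b)
  expect_equal(attr(self, "n_shared"), 4L)
})
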