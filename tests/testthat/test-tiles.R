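toy_inputs <- function() {
  trees <- data.frame(
    plot_id = c(rep(70001L, 5), rep(70002L, 2)),
    species_symbol = c("QUNI", "QUNI", "PITA", "QUNI", "PITA", "ACRU", "ACRU"),
    common_name = c(rep("water oak", 2), "loblolly pine", "water oak",
                    "loblolly pine", "red maple", "red maple"),
    e_spgrpcd = c(28L, 28L, 2L, 28L, 2L, 22L, 22L),
    dia_in = c(10, 8, 12, 6, 9, 11, 7),
    ht_ft = c(60, 50, 70, 40, 55, 65, 45),
    alive = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  plots <- data.frame(plot_id = c(70001L, 70002L), site_index = c(75, 82))
  species_ref <- data.frame(
    SPECIES_SYMBOL = c("QUNI", "PITA", "ACRU"),
    COMMON_NAME = c("water oak", "loblolly pine", "red maple"),
    E_SPGRPCD = c(28L, 2L, 22L),
    JENKINS_SPGRPCD = c(8L, 4L, 6L),
    JENKINS_TOTAL_B1 = c(-2.0127, -2.5356, -1.9123),
    JENKINS_TOTAL_B2 = c(2.4342, 2.4349, 2.3651),
    stringsAsFactors = FALSE)
  carmean <- default_carmean_pool()
  list(trees = trees, plots = plots, species_ref = species_ref,
       carmean = carmean)
}

test_that("tiles contain only alive trees, one tile per plot with alive trees", {
  inp <- toy_inputs()
  tiles <- augment_and_build_tiles(inp$trees, inp$plots, inp$species_ref,
                                   inp$carmean)
  expect_named(tiles, c("70001", "70002"))
  expect_equal(nrow(tiles[["70001"]]), 3L)  # 5 trees, 2 dead
  expect_equal(nrow(tiles[["70002"]]), 2L)
  # rows keep input order and carry the allometric attributes
  t1 <- tiles[["70001"]]
  expect_equal(t1$SPECIES_SYMBOL, c("QUNI", "QUNI", "PITA"))
  expect_equal(t1$biomass,
               jenkins_biomass(c(10, 8, 12),
                               c(-2.0127, -2.0127, -2.5356),
                               c(2.4342, 2.4342, 2.4349)),
               tolerance = 1e-12)
  cf28 <- with(inp$carmean[inp$carmean$e_spgrpcd == 28, ],
               carmean_coefficients(b1, b2, b3, b4, b5))
  expect_equal(t1$age[1], carmean_age(60, 75, cf28), tolerance = 1e-12)
  expect_true(all(is.na(t1$MapCode)))
})

test_that("tile ages recover the generator's true ages", {
  land <- generate_landscape(fixture_config(seed = 23, grid_rows = 20,
                                            grid_cols = 20, n_plots = 10))
  tiles <- augment_and_build_tiles(land$trees, land$plots, land$species_ref,
                                   land$carmean)
  # union of tile plot ids = plots with at least one alive tree
  alive_plots <- sort(unique(land$trees$plot_id[land$trees$alive]))
  expect_equal(sort(as.integer(names(tiles))), alive_plots)
  truth <- land$truth$true_age_yr[land$trees$alive]
  got <- unlist(lapply(tiles, function(t) t$age), use.names = FALSE)
  # tiles are keyed by plot id (ascending); realign truth the same way
  ord <- order(land$trees$plot_id[land$trees$alive])
  expect_equal(got, truth[ord], tolerance = 1e-6)
})

test_that("missing linkage is a hard error naming the culprit", {
  inp <- toy_inputs()
  expect_error(
    augment_and_build_tiles(inp$trees, inp$plots[-1, ], inp$species_ref,
                            inp$carmean),
    "70001", class = "ricb_linkage_error")
  expect_error(
    augment_and_build_tiles(inp$trees, inp$plots, inp$species_ref,
                            inp$carmean[inp$carmean$e_spgrpcd != 22, ]),
    "22", class = "ricb_linkage_error")
  expect_error(
    augment_and_build_tiles(inp$trees, inp$plots, inp$species_ref[-1, ],
                            inp$carmean),
    "QUNI", class = "ricb_linkage_error")
})

test_that("zero-diameter rows are dropped with a log entry; zero heights zeroed", {
  inp <- toy_inputs()
  inp$trees$dia_in[1] <- 0
  inp$trees$ht_ft[2] <- 0
  tiles <- augment_and_build_tiles(inp$trees, inp$plots, inp$species_ref,
                                   inp$carmean)
  expect_equal(nrow(tiles[["70001"]]), 2L)
  expect_true(any(grepl("dropped_tree reason=dia0 n=1", attr(tiles, "log"))))
  expect_equal(tiles[["70001"]]$age[1], 0)
  expect_equal(tiles[["70001"]]$biomass[1], 0)
})

test_that("tile files carry the six-column layout with blank MapCode and round-trip", {
  inp <- toy_inputs()
  tiles <- augment_and_build_tiles(inp$trees, inp$plots, inp$species_ref,
                                   inp$carmean)
  dir <- withr::local_tempdir()
  path <- write_tile(tiles[["70001"]], dir)
  expect_equal(basename(path), "70001.csv")
  header <- readLines(path, n = 1L)
  expect_identical(header, "MapCode,SPECIES_SYMBOL,COMMON_NAME,E_SPGRPCD,age,biomass")
  # MapCode written blank
  expect_true(all(grepl("^,", readLines(path)[-1])))
  back <- read_tile(path)
  expect_equal(back$biomass, tiles[["70001"]]$biomass, tolerance = 1e-12)
  expect_equal(back$age, tiles[["70001"]]$age, tolerance = 1e-12)
  expect_identical(back$SPECIES_SYMBOL, tiles[["70001"]]$SPECIES_SYMBOL)
  expect_equal(attr(back, "plot_id"), 70001L)
})

test_that("a tile file missing a column is a format error naming it", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "123.csv")
  writeLines(c("MapCode,SPECIES_SYMBOL,COMMON_NAME,E_SPGRPCD,age",
               ",QUNI,water oak,28,14.97"), path)
  expect_error(read_tile(path), "biomass", class = "ricb_format_error")
})

test_that("a tile directory round-trips through its manifest", {
  inp <- toy_inputs()
  tiles <- augment_and_build_tiles(inp$trees, inp$plots, inp$species_ref,
                                   inp$carmean)
  dir <- withr::local_tempdir()
  write_tiles(tiles, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_tiles(dir)
  expect_named(back, names(tiles))
  expect_equal(back[["70002"]]$biomass, tiles[["70002"]]$biomass,
               tolerance = 1e-12)
})
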