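test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_species = 40, seed = 123)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$occurrences, s2$occurrences)
  expect_identical(s1$species, s2$species)
  expect_identical(s1$truth, s2$truth)
})

test_that("group apportionment matches the requested weights exactly", {
  cfg <- simulation_config(n_species = 1311, seed = 1)
  sim <- simulate_dataset(cfg)
  tab <- table(sim$species$group_label)
  expect_equal(sum(tab), 1311)
  expect_equal(as.integer(tab[c("Coffea", "Legumes", "Myrcia", "MadPalms",
                                "OrchidsNG")]),
               c(105, 837, 97, 176, 96))
})

test_that("noise-free labels follow the EOO bands of the true extent", {
  cfg <- simulation_config(n_species = 60, label_noise = 0,
                           extent_range_km2 = c(1, 90), seed = 21)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$species$reference_category == "CR"))
  cfg2 <- simulation_config(n_species = 60, label_noise = 0,
                            extent_range_km2 = c(30000, 1e6), seed = 22)
  sim2 <- simulate_dataset(cfg2)
  expect_true(all(sim2$species$reference_category == "LC"))
})

test_that("missing-coordinate blanking keeps the locality code", {
  cfg <- simulation_config(n_species = 80, missing_coordinate_rate = 0.3,
                           cultivated_rate = 0, outside_range_rate = 0,
                           duplicate_rate = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  blank <- is.na(sim$occurrences$longitude)
  expect_gt(mean(blank), 0.2); expect_lt(mean(blank), 0.4)
  expect_true(all(!is.na(sim$occurrences$locality_code[blank])))
})

test_that("contamination and duplicates are injected and removed by cleaning", {
  cfg <- simulation_config(n_species = 100, cultivated_rate = 0.1,
                           outside_range_rate = 0.1, duplicate_rate = 0.1,
                           seed = 41)
  sim <- simulate_dataset(cfg)
  expect_gt(sum(sim$occurrences$is_cultivated), 0)
  expect_gt(sum(sim$occurrences$is_outside_native_range), 0)
  cleaned <- clean_occurrences(sim$occurrences)
  expect_false(any(cleaned$is_cultivated | cleaned$is_outside_native_range))
  expect_lt(nrow(cleaned), nrow(sim$occurrences))
})

test_that("threatened species cite criteria with range-driven labels citing B", {
  cfg <- simulation_config(n_species = 300, label_noise = 0, seed = 51)
  sim <- simulate_dataset(cfg)
  threatened <- sim$species$reference_category %in% c("CR", "EN", "VU")
  expect_true(all(grepl("B", sim$species$criteria_cited[threatened])))
  expect_true(all(sim$species$criteria_cited[!threatened] == ""))
})

test_that("the lattice admin layer tiles the window and matches index arithmetic", {
  cfg <- simulation_config(n_species = 5, admin_grid = c(10, 10), seed = 61)
  layer <- make_admin_layer(cfg)
  expect_length(layer$units, 100)
  set.seed(62)
  lon <- runif(40, -19.9, 19.9); lat <- runif(40, -19.9, 19.9)
  # index-arithmetic oracle: unit from integer division of the offsets
  ix <- floor((lon + 20) / 40 * 10) + 1
  iy <- floor((lat + 20) / 40 * 10) + 1
  want <- sprintf("adm_%02d_%02d", ix, iy)
  rec <- data.frame(species_id = "x", longitude = lon, latitude = lat,
                    collection_year = 2000L, locality_code = NA_character_,
                    locality_text = NA_character_, is_cultivated = FALSE,
                    is_outside_native_range = FALSE, stringsAsFactors = FALSE)
  got <- assign_localities(rec, layer)$locality_code
  expect_identical(got, want)
  # interior points belong to exactly one unit (no overlap between tiles)
  for (i in 1:10) {
    hits <- sum(vapply(layer$units, function(u) {
      oracle_point_in_ring(lon[i], lat[i], u$ring)
    }, logical(1)))
    expect_equal(hits, 1)
  }
  # 1x1 grid: everything lands in the single unit
  cfg1 <- simulation_config(n_species = 5, admin_grid = c(1, 1), seed = 63)
  l1 <- make_admin_layer(cfg1)
  expect_equal(assign_localities(rec, l1)$locality_code, rep("adm_01_01", 40))
})

test_that("the antimeridian scenario produces genuine spanners", {
  cfg <- simulation_config(n_species = 120, antimeridian = TRUE, seed = 71)
  sim <- simulate_dataset(cfg)
  res <- exclude_antimeridian_spanners(clean_occurrences(sim$occurrences))
  expect_gt(length(res$excluded_species), 0)
  expect_lt(length(res$excluded_species), 120)
  # kept species have no longitude on both flanks of the meridian
  for (s in utils::head(unique(res$kept$species_id), 20)) {
    lon <- res$kept$longitude[res$kept$species_id == s]
    lon <- lon[!is.na(lon)]
    expect_false(any(lon > 150) && any(lon < -150))
  }
})

test_that("computed EOO recovers the target extent for well-sampled species", {
  cfg <- simulation_config(n_species = 150, label_noise = 0,
                           missing_coordinate_rate = 0, seed = 81)
  sim <- simulate_dataset(cfg)
  m <- summarize_ranges(clean_occurrences(sim$occurrences))
  tr <- merge(m, sim$truth, by = "species_id")
  big <- tr[tr$n_georeferenced >= 30, ]
  expect_gt(nrow(big), 5)
  expect_true(all(abs(big$eoo_km2 / big$target_eoo_km2 - 1) <= 0.25))
})

test_that("written CSV files round-trip through the occurrence reader", {
  cfg <- simulation_config(n_species = 30, seed = 91)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  occ <- read_occurrences(paths[["occurrences"]])
  expect_equal(nrow(occ), nrow(sim$occurrences))
  expect_equal(sort(unique(occ$species_id)), sort(unique(sim$occurrences$species_id)))
  expect_equal(sum(is.na(occ$longitude)), sum(is.na(sim$occurrences$longitude)))
  labs <- utils::read.csv(paths[["labels"]], stringsAsFactors = FALSE)
  expect_setequal(labs$species_id, sim$species$species_id)
})
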