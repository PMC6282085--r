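write_csv_fixture <- function(text) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(text, path)
  path
}

test_that("reading preserves rows and turns bad values into missingness", {
  path <- write_csv_fixture(c(
    "species,lon,lat,year,locality",
    "sp1,10.5,20.1,1999,L1",
    "sp1,11.0,,2001,L2",
    "sp2,12.2,21.0,2005,"))
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 3)
  expect_equal(sum(is.na(occ$latitude)), 1)
  expect_equal(occ$species_id, c("sp1", "sp1", "sp2"))
  expect_true(is.na(occ$locality_code[3]))

  # out-of-bounds longitude invalidates the coordinate pair, with a warning
  path2 <- write_csv_fixture(c("species,lon,lat,year,locality",
                               "sp1,181.0,10,1999,L1"))
  expect_warning(occ2 <- read_occurrences(path2), "bounds")
  expect_true(is.na(occ2$longitude) && is.na(occ2$latitude))

  # implausible year
  path3 <- write_csv_fixture(c("species,lon,lat,year,locality",
                               "sp1,10,10,1432,L1"))
  expect_warning(occ3 <- read_occurrences(path3), "year")
  expect_true(is.na(occ3$collection_year))
})

test_that("the Darwin Core dialect remaps column names", {
  path <- write_csv_fixture(c(
    "scientificName,decimalLongitude,decimalLatitude,year,stateProvince",
    "Coffea test,35.2,-6.1,1987,Morogoro"))
  occ <- read_occurrences(path, occurrence_dialect("dwc"))
  expect_equal(occ$longitude, 35.2)
  expect_equal(occ$locality_code, "Morogoro")
  expect_equal(occ$species_id, "Coffea test")
})

test_that("a missing species column is a hard error; an empty file is empty", {
  path <- write_csv_fixture(c("lon,lat", "1,2"))
  expect_error(read_occurrences(path), "species")
  path2 <- write_csv_fixture("species,lon,lat,year,locality")
  expect_equal(nrow(read_occurrences(path2)), 0)
})

make_records <- function(lon, lat, year = 2000L, sp = "sp1",
                         cult = FALSE, outside = FALSE, loc = NA_character_) {
  n <- max(length(lon), length(lat), length(year), length(cult), length(outside))
  data.frame(species_id = rep(sp, n)[1:n], longitude = rep(lon, length.out = n),
             latitude = rep(lat, length.out = n),
             collection_year = rep(as.integer(year), length.out = n),
             locality_code = rep(loc, length.out = n),
             locality_text = NA_character_,
             is_cultivated = rep(cult, length.out = n),
             is_outside_native_range = rep(outside, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("cleaning removes flagged records and exact duplicates, idempotently", {
  rec <- rbind(
    make_records(10, 10, 1990),
    make_records(10, 10, 1990),                # duplicate of row 1
    make_records(10, 10, 1991),                # same place, other year: kept
    make_records(11, 11, 1990, outside = TRUE),
    make_records(12, 12, 1990, cult = TRUE))
  out <- clean_occurrences(rec)
  expect_equal(nrow(out), 2)
  expect_false(any(out$is_cultivated | out$is_outside_native_range))
  expect_identical(clean_occurrences(out), out)       # idempotent
  expect_lte(nrow(clean_occurrences(rec)), nrow(rec)) # never grows
  # no flags, no duplicates: identity
  rec2 <- make_records(c(1, 2), c(1, 2))
  expect_equal(nrow(clean_occurrences(rec2)), 2)
  # duplicate key is rounded to 4 dp: 1e-5 degree apart collapses
  rec3 <- make_records(c(1, 1 + 1e-5), c(1, 1))
  expect_equal(nrow(clean_occurrences(rec3)), 1)
  expect_equal(nrow(clean_occurrences(rec2[0, ])), 0)
})

test_that("species spanning the 180th meridian are excluded, one-sided ones kept", {
  occ <- rbind(make_records(c(179.5, -179.5), c(0, 0), sp = "spanner"),
               make_records(c(10, 20), c(0, 0), sp = "narrow"),
               make_records(-180, 0, sp = "edge"))
  res <- exclude_antimeridian_spanners(occ)
  expect_equal(res$excluded_species, "spanner")
  expect_setequal(unique(res$kept$species_id), c("narrow", "edge"))
})

test_that("locality assignment matches the brute-force point-in-polygon oracle", {
  layer <- admin_layer(list(
    list(unit_id = "A", ring = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
    list(unit_id = "B", ring = cbind(c(1, 2, 2, 1), c(0, 0, 1, 1))),
    list(unit_id = "C", ring = cbind(c(0, 1, 1, 0), c(1, 1, 2, 2))),
    list(unit_id = "D", ring = cbind(c(1, 2, 2, 1), c(1, 1, 2, 2)))))
  # centroid containment
  rec <- make_records(0.5, 0.5)
  expect_equal(assign_localities(rec, layer)$locality_code, "A")
  # non-georeferenced record keeps its pre-set code
  rec2 <- make_records(NA_real_, NA_real_, loc = "B")
  expect_equal(assign_localities(rec2, layer)$locality_code, "B")
  # scattered points agree with the winding-number oracle
  set.seed(3)
  pts <- make_records(runif(25, -0.2, 2.2), runif(25, -0.2, 2.2))
  got <- suppressWarnings(assign_localities(pts, layer))$locality_code
  want <- vapply(seq_len(25), function(i) {
    oracle_locality(pts$longitude[i], pts$latitude[i], layer)
  }, character(1))
  expect_identical(got, want)
  # a point in no unit warns and gets NA
  expect_warning(out <- assign_localities(make_records(5, 5), layer), "outside")
  expect_true(is.na(out$locality_code))
})

test_that("invalid admin polygons are rejected at load time", {
  expect_error(admin_layer(list(list(unit_id = "X", ring = cbind(c(0, 1), c(0, 1))))),
               "3 distinct")
  expect_error(admin_layer(list(
    list(unit_id = "X", ring = cbind(c(0, 1, 1), c(0, 0, 1))),
    list(unit_id = "X", ring = cbind(c(2, 3, 3), c(0, 0, 1))))), "unique")
  expect_error(admin_layer(list(list(unit_id = "X",
                                     ring = cbind(c(0, 200, 1), c(0, 0, 1))))),
               "bounds")
  expect_error(admin_layer(list()), "at least one")
})

test_that("admin layers round-trip through GeoJSON", {
  layer <- admin_layer(list(
    list(unit_id = "u1", ring = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
    list(unit_id = "u2", ring = cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)))))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_admin_geojson(layer, path)
  back <- read_admin_geojson(path)
  expect_equal(vapply(back$units, `[[`, "", "unit_id"), c("u1", "u2"))
  rec <- make_records(c(0.5, 1.5), c(0.5, 0.5))
  expect_equal(assign_localities(rec, back)$locality_code, c("u1", "u2"))
})
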