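mk_metrics <- function(eoo = 0, aoo = 0, locations = 0, n_geo = 1,
                       n_spec = 10, id = "x") {
  data.frame(species_id = id, n_specimens = n_spec, n_georeferenced = n_geo,
             n_localities = 1, eoo_km2 = eoo, n_occupied_cells = aoo / 4,
             aoo_km2 = aoo, n_locations = locations, stringsAsFactors = FALSE)
}

test_that("EOO banding follows the criterion-B bands with strict upper bounds", {
  cases <- list(list(25000, "LC", "not_threatened"),
                list(50, "CR", "threatened"),
                list(20000, "LC", "not_threatened"),  # boundary: strict '<',
                list(19999.9, "VU", "threatened"),     # falls less-threatened
                list(5000, "VU", "threatened"),
                list(100, "EN", "threatened"),
                list(4999.9, "EN", "threatened"))
  for (cs in cases) {
    p <- classify_rcat(mk_metrics(eoo = cs[[1]]))
    expect_equal(p$category, cs[[2]])
    expect_equal(p$binary, cs[[3]])
  }
  # degenerate hull with a georeferenced point: point-like range = CR
  expect_equal(classify_rcat(mk_metrics(eoo = 0, n_geo = 1))$category, "CR")
  # no coordinates at all: not assessable by an EOO method
  expect_true(is.na(classify_rcat(mk_metrics(eoo = 0, n_geo = 0))$category))
})

test_that("lowering EOO never moves the EOO banding toward lower threat", {
  set.seed(8)
  ranks <- match(c("CR", "EN", "VU", "NT", "LC"), c("CR", "EN", "VU", "NT", "LC"))
  for (i in 1:50) {
    e1 <- 10^runif(1, 0, 6); e2 <- e1 * runif(1, 0, 1)  # e2 <= e1
    r1 <- match(classify_rcat(mk_metrics(eoo = e1))$category, c("CR", "EN", "VU", "NT", "LC"))
    r2 <- match(classify_rcat(mk_metrics(eoo = e2))$category, c("CR", "EN", "VU", "NT", "LC"))
    expect_lte(r2, r1)
  }
})

test_that("the criterion-B approximation combines range and location conditions", {
  expect_equal(classify_conr(mk_metrics(eoo = 50, locations = 1))$category, "CR")
  # range qualifies for VU but locations disqualify every threatened band
  expect_equal(classify_conr(mk_metrics(eoo = 15000, locations = 30))$category, "NT")
  # EN via the AOO branch despite a huge EOO
  expect_equal(classify_conr(mk_metrics(eoo = 1e6, aoo = 8, locations = 2))$category, "EN")
  # beyond both VU range thresholds: LC regardless of locations
  expect_equal(classify_conr(mk_metrics(eoo = 1e6, aoo = 4000, locations = 1))$category, "LC")
  expect_true(is.na(classify_conr(mk_metrics(eoo = 0, n_geo = 0))$category))
})

test_that("the criterion-B approximation never assigns a threatened band to wide ranges", {
  m <- random_metrics(200, seed = 31)
  p <- classify_conr(m)
  wide <- m$eoo_km2 >= 20000 & m$aoo_km2 >= 2000
  expect_false(any(p$category[wide] %in% c("CR", "EN", "VU")))
})

test_that("the specimen-triage tree exits at the documented steps", {
  old <- data.frame(species_id = "a", longitude = 1, latitude = 1,
                    collection_year = 1890L, locality_code = "u1",
                    locality_text = NA_character_, is_cultivated = FALSE,
                    is_outside_native_range = FALSE, stringsAsFactors = FALSE)
  p <- classify_us_method(old)
  expect_equal(p$category, "PotentiallyExtinct")
  expect_equal(p$pathway, "no_recent_collections")
  expect_equal(p$binary, "threatened")

  few <- do.call(rbind, replicate(3, old, simplify = FALSE))
  few$collection_year <- 2010L
  expect_equal(classify_us_method(few)$pathway, "few_specimens")

  # 20 recent specimens in 8 distinct units -> NotThreatened
  wide <- do.call(rbind, replicate(20, old, simplify = FALSE))
  wide$collection_year <- 2000L
  wide$locality_code <- rep(sprintf("u%d", 1:8), length.out = 20)
  pw <- classify_us_method(wide)
  expect_equal(pw$category, "NotThreatened")
  expect_equal(pw$binary, "not_threatened")

  # 20 recent specimens in 2 units -> few_localities
  two <- wide; two$locality_code <- rep(c("u1", "u2"), 10)
  expect_equal(classify_us_method(two)$pathway, "few_localities")

  # records with no usable year fail the recency check
  nodate <- wide; nodate$collection_year <- NA_integer_
  expect_equal(classify_us_method(nodate)$category, "PotentiallyExtinct")

  expect_error(classify_us_method(old[0, ]), "no records")
})

test_that("the check order of the triage tree is switchable", {
  rec <- data.frame(species_id = "a", longitude = 1, latitude = 1,
                    collection_year = 1890L, locality_code = "u1",
                    locality_text = NA_character_, is_cultivated = FALSE,
                    is_outside_native_range = FALSE, stringsAsFactors = FALSE)
  # old AND few specimens: exit step depends on ordering
  expect_equal(classify_us_method(rec)$pathway, "no_recent_collections")
  expect_equal(classify_us_method(rec, extinct_check_first = FALSE)$pathway,
               "few_specimens")
})

test_that("pathway proportions cover every species and sum to one", {
  sim <- simulate_dataset(simulation_config(n_species = 50, seed = 4))
  occ <- clean_occurrences(sim$occurrences)
  p <- classify_us_method(occ)
  tab <- us_pathway_proportions(p)
  expect_equal(sum(tab$n), nrow(p))
  expect_equal(sum(tab$proportion), 1)
})

test_that("the specimen-count rule uses a strict threshold", {
  expect_equal(classify_specimen_count(mk_metrics(n_spec = 9), 10)$binary, "threatened")
  expect_equal(classify_specimen_count(mk_metrics(n_spec = 10), 10)$binary, "not_threatened")
  m <- random_metrics(50, seed = 2)
  expect_true(all(classify_specimen_count(m, 1)$binary == "not_threatened"))
})

test_that("threshold selection maximizes accuracy and matches the exhaustive oracle", {
  # perfectly separable at 7 specimens
  n <- c(1:6, 8:20)
  lab <- n < 7
  sel <- select_count_threshold(n, lab, 1:50)
  expect_equal(sel$accuracy, 1.0)
  expect_equal(sel$threshold, 7)
  # all species threatened: accuracy 1 reached once the threshold clears
  # every count (smallest such threshold wins the tie)
  n2 <- sample(1:20)
  sel2 <- select_count_threshold(n2, rep(TRUE, 20), 1:50)
  expect_equal(sel2$accuracy, 1.0)
  expect_gt(sel2$threshold, max(n2))
  # random fixtures agree with the exhaustive sweep oracle
  for (seed in 1:3) {
    set.seed(seed)
    n3 <- rnbinom(200, mu = 15, size = 2) + 1
    lab3 <- runif(200) < 1 / (1 + exp((n3 - 12) / 4))
    sel3 <- select_count_threshold(n3, lab3, 1:100)
    orc <- oracle_count_threshold(n3, lab3, 1:100)
    expect_equal(sel3$threshold, orc$threshold)
    expect_equal(sel3$accuracy, orc$accuracy)
    # returned accuracy dominates the whole curve
    expect_true(all(sel3$accuracy >= sel3$curve$accuracy))
  }
  expect_error(select_count_threshold(integer(0), logical(0)), "no labelled")
})
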