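#' Configuration for the synthetic herbarium-data generator
#'
#' Describes a simulated multi-group herbarium dataset with known ground
#' truth. The defaults emulate the structure of a large multi-herbarium
#' validation set: 1311 species in five study groups of very unequal size,
#' per-species range extents log-uniform over 1 to 1e6 km^2 (straddling all
#' criterion-B thresholds), specimen counts that grow with range size
#' (negative binomial), collection years spanning 1880-2015, a fraction of
#' records lacking coordinates but keeping a locality code, and low rates
#' of cultivated/outside-native-range contamination and exact duplicates.
#'
#' Reference categories are assigned from the *true* range extent through
#' the EOO bands of [category_thresholds()], then, with probability
#' `label_noise`, replaced by a random category — the stand-in for species
#' whose real-world assessments rest on criteria other than geographic
#' range. Species whose label is range-driven cite criterion B; flipped
#' labels cite other criteria.
#'
#' @param n_species Total species (default 1311).
#' @param group_weights Named numeric vector of group weights; species are
#'   apportioned proportionally (largest-remainder rounding, so the
#'   realised per-group counts always sum to `n_species`).
#' @param extent_range_km2 Range of true extents, log-uniform (km^2).
#' @param specimen_mu_intercept,specimen_mu_coef,specimen_mu_exponent
#'   Expected specimen count for a species of extent A is
#'   `intercept + coef * A^exponent`; the positive link is the entire
#'   signal available to the specimen-count classifier.
#' @param specimen_dispersion Negative-binomial size parameter.
#' @param year_range Collection-year window (default 1880-2015).
#' @param missing_coordinate_rate Fraction of records whose coordinates are
#'   blanked (locality code retained).
#' @param cultivated_rate,outside_range_rate Expected flagged contamination
#'   records per genuine record.
#' @param duplicate_rate Expected exact-duplicate records per genuine
#'   record.
#' @param admin_grid Integer c(nx, ny): synthetic admin-unit lattice.
#' @param label_noise Probability a species' category is replaced by a
#'   random category.
#' @param window Numeric c(lon_min, lon_max, lat_min, lat_max), degrees; a
#'   40 x 40 degree window away from poles and antimeridian by default.
#' @param antimeridian Shift the window to straddle the 180th meridian
#'   (exercises the spanner-exclusion logic; default FALSE).
#' @param thresholds [category_thresholds()] used for truth labelling.
#' @param seed Integer seed (mandatory source of all randomness).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 1311,
                              group_weights = c(Coffea = 105, Legumes = 837,
                                                Myrcia = 97, MadPalms = 176,
                                                OrchidsNG = 96),
                              extent_range_km2 = c(1, 1e6),
                              specimen_mu_intercept = 2.5,
                              specimen_mu_coef = 2,
                              specimen_mu_exponent = 0.20,
                              specimen_dispersion = 8,
                              year_range = c(1880, 2015),
                              missing_coordinate_rate = 0.1,
                              cultivated_rate = 0.02,
                              outside_range_rate = 0.02,
                              duplicate_rate = 0.05,
                              admin_grid = c(8, 8),
                              label_noise = 0.2,
                              window = c(-20, 20, -20, 20),
                              antimeridian = FALSE,
                              thresholds = category_thresholds(),
                              seed = 1) {
  stopifnot(n_species >= 1, length(group_weights) >= 1,
            all(group_weights > 0), length(extent_range_km2) == 2,
            extent_range_km2[1] > 0, extent_range_km2[2] > extent_range_km2[1],
            missing_coordinate_rate >= 0, missing_coordinate_rate <= 1,
            cultivated_rate >= 0, outside_range_rate >= 0, duplicate_rate >= 0,
            label_noise >= 0, label_noise <= 1,
            length(admin_grid) == 2, all(admin_grid >= 1),
            length(window) == 4, window[2] > window[1], window[4] > window[3],
            specimen_dispersion > 0, is.numeric(seed))
  structure(as.list(environment()), class = "simulation_config")
}

# Apportion n among weights by largest remainder; guarantees sum == n.
.apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Synthetic rectangular admin-unit lattice
#'
#' Builds an [admin_layer()] of `nx * ny` rectangular units tiling the
#' simulation window — the synthetic stand-in for a first-level
#' administrative subdivision. Units are ordered column-major with stable
#' ids `adm_<ix>_<iy>`; the lattice tiles the window without overlap.
#'
#' @param config A [simulation_config()] (its `admin_grid` and `window`
#'   are used).
#' @return An [admin_layer()].
#' @export
make_admin_layer <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nx <- config$admin_grid[1]; ny <- config$admin_grid[2]
  w <- config$window
  xs <- seq(w[1], w[2], length.out = nx + 1)
  ys <- seq(w[3], w[4], length.out = ny + 1)
  units <- list()
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      ring <- cbind(c(xs[ix], xs[ix + 1], xs[ix + 1], xs[ix], xs[ix]),
                    c(ys[iy], ys[iy], ys[iy + 1], ys[iy + 1], ys[iy]))
      units[[length(units) + 1]] <- list(
        unit_id = sprintf("adm_%02d_%02d", ix, iy), ring = ring)
    }
  }
  admin_layer(units, level_label = sprintf("synthetic %dx%d lattice", nx, ny))
}

# Fast lattice lookup (index arithmetic); agrees with polygon containment
# for all interior points (boundary points have probability zero under the
# continuous generator).
.lattice_code <- function(lon, lat, config) {
  w <- config$window
  nx <- config$admin_grid[1]; ny <- config$admin_grid[2]
  ix <- floor((lon - w[1]) / (w[2] - w[1]) * nx) + 1
  iy <- floor((lat - w[3]) / (w[4] - w[3]) * ny) + 1
  out <- rep(NA_character_, length(lon))
  ok <- !is.na(lon) & !is.na(lat) & ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  out[ok] <- sprintf("adm_%02d_%02d", ix[ok], iy[ok])
  out
}

#' Simulate a herbarium occurrence dataset with known ground truth
#'
#' Per species: a true range extent is drawn (log-uniform), a disc of that
#' area is placed in the window, and specimen points are drawn inside it —
#' up to eight "anchor" points near the range rim (herbarium collections
#' accumulated over a century span a species' range limits; without rim
#' points the convex hull of a handful of specimens would badly
#' under-represent the range the label is based on) and the remainder
#' uniform over the disc, all with a small coordinate jitter. Collection
#' years, locality codes (from the synthetic admin lattice),
#' missing-coordinate blanking, flagged contamination records, exact
#' duplicate records, the reference category and cited criteria are then
#' generated as described in [simulation_config()].
#'
#' @param config A [simulation_config()].
#' @return A `herb_sim` list: `occurrences` (canonical record table,
#'   contamination and duplicates included — i.e. *uncleaned*), `species`
#'   (species_id, group_label, reference_category, criteria_cited, and the
#'   per-species predictor columns for the random-forest stage), `truth`
#'   (species_id, target_eoo_km2, centre, radius, n_genuine_records), and
#'   the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  counts <- .apportion(config$n_species, config$group_weights)
  group <- rep(names(counts), counts)
  n_sp <- config$n_species
  ids <- sprintf("sp%04d", seq_len(n_sp))
  w <- config$window
  th <- config$thresholds

  extent <- 10^stats::runif(n_sp, log10(config$extent_range_km2[1]),
                            log10(config$extent_range_km2[2]))
  radius <- sqrt(extent / pi)

  occ_list <- vector("list", n_sp)
  sp_rows <- vector("list", n_sp)
  truth_rows <- vector("list", n_sp)

  for (i in seq_len(n_sp)) {
    R <- radius[i]
    mlat <- min(R / 110.574, (w[4] - w[3]) / 4)
    lat_c <- stats::runif(1, w[3] + mlat, w[4] - mlat)
    mlon <- min(R / (111.320 * cos(lat_c * pi / 180)), (w[2] - w[1]) / 4)
    lon_c <- stats::runif(1, w[1] + mlon, w[2] - mlon)

    mu <- config$specimen_mu_intercept +
      config$specimen_mu_coef * extent[i]^config$specimen_mu_exponent
    n_rec <- max(1L, stats::rnbinom(1, size = config$specimen_dispersion, mu = mu))

    # anchors near the rim, then uniform interior points
    k <- min(n_rec, 8L)
    ang <- 2 * pi * (seq_len(k) - 1) / k +
      stats::runif(k, -0.2, 0.2) * 2 * pi / k
    rad <- R * (0.95 + 0.05 * stats::runif(k))
    if (n_rec > k) {
      ang <- c(ang, stats::runif(n_rec - k, 0, 2 * pi))
      rad <- c(rad, R * sqrt(stats::runif(n_rec - k)))
    }
    x <- rad * cos(ang) + stats::rnorm(n_rec, 0, 0.25)
    y <- rad * sin(ang) + stats::rnorm(n_rec, 0, 0.25)
    lat_p <- lat_c + y / 110.574
    lon_p <- lon_c + x / (111.320 * cos(lat_c * pi / 180))

    yr_end <- config$year_range[2] - round(stats::rexp(1, 1 / 25))
    yr_end <- max(yr_end, config$year_range[1] + 5)
    yr_start <- max(config$year_range[1], yr_end - round(stats::runif(1, 5, 80)))
    years <- sample(seq(yr_start, yr_end), n_rec, replace = TRUE)

    rec <- data.frame(
      species_id = ids[i], longitude = lon_p, latitude = lat_p,
      collection_year = as.integer(years),
      locality_code = NA_character_, locality_text = NA_character_,
      is_cultivated = FALSE, is_outside_native_range = FALSE,
      stringsAsFactors = FALSE)
    rec$locality_code <- .lattice_code(rec$longitude, rec$latitude, config)

    # blank coordinates (locality kept): the non-georeferenced fraction
    blank <- stats::runif(n_rec) < config$missing_coordinate_rate
    rec$longitude[blank] <- NA_real_
    rec$latitude[blank] <- NA_real_

    # contamination: cultivated records anywhere, escapes well outside range
    n_cult <- stats::rbinom(1, n_rec, config$cultivated_rate)
    if (n_cult > 0) {
      cl_lon <- stats::runif(n_cult, w[1], w[2])
      cl_lat <- stats::runif(n_cult, w[3], w[4])
      rec <- rbind(rec, data.frame(
        species_id = ids[i], longitude = cl_lon, latitude = cl_lat,
        collection_year = as.integer(sample(seq(yr_start, yr_end), n_cult, replace = TRUE)),
        locality_code = .lattice_code(cl_lon, cl_lat, config),
        locality_text = NA_character_,
        is_cultivated = TRUE, is_outside_native_range = FALSE,
        stringsAsFactors = FALSE))
    }
    n_out <- stats::rbinom(1, n_rec, config$outside_range_rate)
    if (n_out > 0) {
      ang_o <- stats::runif(n_out, 0, 2 * pi)
      d_o <- R * stats::runif(n_out, 3, 6) + 50
      o_lat <- lat_c + d_o * sin(ang_o) / 110.574
      o_lon <- lon_c + d_o * cos(ang_o) / (111.320 * cos(lat_c * pi / 180))
      rec <- rbind(rec, data.frame(
        species_id = ids[i], longitude = o_lon, latitude = o_lat,
        collection_year = as.integer(sample(seq(yr_start, yr_end), n_out, replace = TRUE)),
        locality_code = .lattice_code(o_lon, o_lat, config),
        locality_text = NA_character_,
        is_cultivated = FALSE, is_outside_native_range = TRUE,
        stringsAsFactors = FALSE))
    }
    # herbarium duplicates: exact copies of existing records
    n_dup <- stats::rbinom(1, n_rec, config$duplicate_rate)
    if (n_dup > 0) {
      rec <- rbind(rec, rec[sample(seq_len(n_rec), n_dup, replace = TRUE), ])
    }
    occ_list[[i]] <- rec

    # reference label: EOO band of the true extent, noise-flipped
    band <- .metric_band(extent[i], th$eoo_km2)
    if (is.na(band)) band <- "LC"
    flipped <- stats::runif(1) < config$label_noise
    if (flipped) band <- sample(.iucn_levels, 1)
    threatened <- band %in% c("CR", "EN", "VU")
    crit <- character(0)
    if (threatened) {
      if (!flipped) {
        crit <- c("B",
                  if (stats::runif(1) < 0.30) "D",
                  if (stats::runif(1) < 0.06) "A",
                  if (stats::runif(1) < 0.06) "C")
      } else {
        crit <- c(if (stats::runif(1) < 0.60) "D",
                  if (stats::runif(1) < 0.30) "A",
                  if (stats::runif(1) < 0.30) "C",
                  if (stats::runif(1) < 0.10) "B")
        if (length(crit) == 0) crit <- "D"
      }
    }

    ord <- sample(sprintf("order%d", 1:6), 1)
    fam <- paste0(ord, "_fam", sample(1:3, 1))
    gen <- paste0(fam, "_gen", sample(1:4, 1))
    sp_rows[[i]] <- data.frame(
      species_id = ids[i], group_label = group[i],
      reference_category = band,
      criteria_cited = paste(sort(crit), collapse = ";"),
      elevation_min = round(stats::runif(1, 0, 1500)),
      elevation_max = NA_real_,  # filled below
      latitude_centroid = lat_c,
      n_habitats = 1L + stats::rpois(1, 0.5 + log10(extent[i] + 1) / 2),
      realm_value = paste0("realm", 1 + (lon_c > 0) + 2 * (lat_c > 0)),
      av_temp = 25 - 0.4 * abs(lat_c) + stats::rnorm(1, 0, 2),
      season_temp = abs(lat_c) / 2 + stats::rnorm(1, 0, 1.5),
      av_precip = 1600 - 15 * abs(lat_c) + stats::rnorm(1, 0, 250),
      season_precip = stats::runif(1, 10, 90),
      eti = stats::rnorm(1, 0, 1),
      mean_gdp = stats::rlnorm(1, 8, 1),
      mean_hpd = stats::rlnorm(1, 4, 1),
      min_hpd = stats::rlnorm(1, 1.5 + (!threatened), 1),
      mean_hfi = stats::runif(1, 0, 50),
      genus = gen, family = fam, order = ord,
      stringsAsFactors = FALSE)
    sp_rows[[i]]$elevation_max <- sp_rows[[i]]$elevation_min +
      round(stats::runif(1, 100, 2000))

    truth_rows[[i]] <- data.frame(
      species_id = ids[i], target_eoo_km2 = extent[i],
      centre_lon = lon_c, centre_lat = lat_c, radius_km = R,
      n_genuine_records = n_rec, stringsAsFactors = FALSE)
  }

  occurrences <- do.call(rbind, occ_list)
  rownames(occurrences) <- NULL
  if (isTRUE(config$antimeridian)) {
    # shift the whole window eastward so part of it wraps across 180 deg;
    # species whose ranges cross the wrap become antimeridian spanners
    occurrences$longitude <- ((occurrences$longitude + 170 + 180) %% 360) - 180
  }
  out <- list(occurrences = occurrences,
              species = do.call(rbind, sp_rows),
              truth = do.call(rbind, truth_rows),
              config = config)
  class(out) <- "herb_sim"
  out
}

#' @export
print.herb_sim <- function(x, ...) {
  cat("<herb_sim> synthetic herbarium dataset\n")
  cat("  species:", nrow(x$species), " records:", nrow(x$occurrences), "\n")
  tab <- table(x$species$group_label)
  for (g in names(tab)) {
    n_rec <- sum(x$occurrences$species_id %in%
                   x$species$species_id[x$species$group_label == g])
    cat(sprintf("    %-10s %5d species (%d records)\n", g, tab[[g]], n_rec))
  }
  cat("  reference categories:",
      paste(sprintf("%s=%d", names(table(x$species$reference_category)),
                    table(x$species$reference_category)), collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated dataset to CSV files
#'
#' Emits the occurrence table in the `"plain"` dialect that
#' [read_occurrences()] reads, plus a labels table (species_id, group,
#' category, criteria cited), the per-species predictor table, and the
#' ground-truth table.
#'
#' @param sim A `herb_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "herb_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  occ <- sim$occurrences
  names(occ) <- c("species", "lon", "lat", "year", "locality",
                  "locality_text", "cultivated", "outside_range")
  paths <- c(occurrences = file.path(dir, "occurrences.csv"),
             labels = file.path(dir, "labels.csv"),
             predictors = file.path(dir, "predictors.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(occ, paths[["occurrences"]], row.names = FALSE, na = "")
  utils::write.csv(sim$species[, c("species_id", "group_label",
                                   "reference_category", "criteria_cited")],
                   paths[["labels"]], row.names = FALSE, na = "")
  pred_cols <- setdiff(names(sim$species),
                       c("group_label", "reference_category", "criteria_cited"))
  utils::write.csv(sim$species[, pred_cols], paths[["predictors"]],
                   row.names = FALSE, na = "")
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE, na = "")
  invisible(paths)
}
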