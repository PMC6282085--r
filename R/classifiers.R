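#' EOO-band categorisation (rCAT-style preliminary assessment)
#'
#' Places each species in the smallest threatened band whose EOO upper
#' bound exceeds its extent of occurrence — CR below 100 km^2, EN below
#' 5000 km^2, VU below 20000 km^2, LC otherwise — mirroring how
#' EOO-calculator tools are used for preliminary assessments where species
#' beyond the VU bound are tagged as not at risk. NT is never emitted:
#' an EOO-only banding has no evidence to separate NT from LC.
#'
#' A species with at least one georeferenced record but a degenerate
#' (zero-area) hull is placed in the CR band: its recorded range is
#' point-like. Species with no georeferenced records at all get an `NA`
#' category — an EOO method simply cannot assess them, and the evaluation
#' layer excludes them from this method's denominators.
#'
#' @param metrics Data.frame from [summarize_ranges()].
#' @param thresholds A [category_thresholds()] object.
#' @param use_aoo Also band on AOO and take the more threatened of the two
#'   bands (off by default; EOO-only is the standard preliminary mode).
#' @return A prediction data.frame: `species_id`, `approach`, `category`,
#'   `binary`.
#' @export
classify_rcat <- function(metrics, thresholds = category_thresholds(),
                          use_aoo = FALSE) {
  stopifnot(inherits(thresholds, "category_thresholds"))
  band <- .metric_band(metrics$eoo_km2, thresholds$eoo_km2)
  band[is.na(band)] <- "LC"
  if (use_aoo) {
    aband <- .metric_band(metrics$aoo_km2, thresholds$aoo_km2)
    aband[is.na(aband)] <- "LC"
    band <- .iucn_levels[pmin(match(band, .iucn_levels), match(aband, .iucn_levels))]
  }
  band[metrics$n_georeferenced == 0] <- NA_character_
  .prediction(metrics$species_id, "rcat", band)
}

#' Criterion-B approximation with assumed continuing decline (ConR-style)
#'
#' Approximates a Red List criterion-B assessment from range metrics alone,
#' under the working assumption of continuing decline in habitat quality
#' (the assumption that lets range thresholds plus location counts imply a
#' category). A species qualifies for threatened band X when its EOO or its
#' AOO falls below X's range threshold *and* its location count does not
#' exceed X's location threshold; the most threatened qualifying band wins.
#' Species whose range qualifies for VU but whose location count exceeds
#' the VU location threshold are returned as NT; species beyond both VU
#' range thresholds are LC.
#'
#' @inheritParams classify_rcat
#' @return A prediction data.frame (`approach = "conr"`).
#' @export
classify_conr <- function(metrics, thresholds = category_thresholds()) {
  stopifnot(inherits(thresholds, "category_thresholds"))
  n <- nrow(metrics)
  cat_out <- rep("LC", n)
  range_qualifies_vu <- metrics$eoo_km2 < thresholds$eoo_km2[["VU"]] |
    metrics$aoo_km2 < thresholds$aoo_km2[["VU"]]
  cat_out[range_qualifies_vu] <- "NT"  # provisional: range alone, too many locations
  for (band in c("VU", "EN", "CR")) {
    ok <- (metrics$eoo_km2 < thresholds$eoo_km2[[band]] |
             metrics$aoo_km2 < thresholds$aoo_km2[[band]]) &
      metrics$n_locations <= thresholds$locations[[band]]
    cat_out[ok] <- band
  }
  cat_out[metrics$n_georeferenced == 0] <- NA_character_
  .prediction(metrics$species_id, "conr", cat_out)
}

#' Parameters of the specimen-triage decision tree
#'
#' Thresholds for [classify_us_method()]: the minimum specimen count and
#' locality breadth of a species considered safe, and the recency window
#' within which a species must have been collected to be considered extant.
#' The published calibration of this triage tree is not restated here; the
#' defaults are conventional round values and every one of them is meant to
#' be tuned to the flora at hand.
#'
#' @param min_specimens Species with fewer specimens are potentially
#'   threatened (default 5).
#' @param min_localities Species known from fewer distinct localities are
#'   potentially threatened (default 3).
#' @param recent_year_cutoff Years before `reference_year` within which a
#'   collection counts as recent (default 50).
#' @param reference_year The "now" of the assessment (default 2015).
#' @return A named list of class `us_method_params`.
#' @export
us_method_params <- function(min_specimens = 5, min_localities = 3,
                             recent_year_cutoff = 50, reference_year = 2015) {
  stopifnot(min_specimens > 0, min_localities > 0,
            recent_year_cutoff > 0, reference_year > 0)
  structure(list(min_specimens = min_specimens, min_localities = min_localities,
                 recent_year_cutoff = recent_year_cutoff,
                 reference_year = reference_year),
            class = "us_method_params")
}

#' Specimen-triage decision tree ("US Method")
#'
#' A three-step first-pass triage over raw specimen evidence, requiring no
#' coordinates at all — only counts, locality codes and collection years:
#'
#' 1. no collection within the recency window -> `PotentiallyExtinct`;
#' 2. fewer than `min_specimens` specimens -> `PotentiallyThreatened`;
#' 3. fewer than `min_localities` distinct locality codes ->
#'    `PotentiallyThreatened`;
#' 4. otherwise `NotThreatened`.
#'
#' The step at which each species exits is recorded in `pathway`, so the
#' flow of a whole flora through the tree can be tabulated with
#' [us_pathway_proportions()]. Species whose records carry no collection
#' year at all fail the recency check (no evidence of recent collection).
#' The extinct-check-first ordering follows the tree's published
#' description; set `extinct_check_first = FALSE` to run the specimen-count
#' check first.
#'
#' @param occurrences Cleaned canonical occurrence data.frame (one or more
#'   species, each with at least one record).
#' @param params A [us_method_params()] object.
#' @param extinct_check_first Run the recency check before the count check
#'   (default `TRUE`).
#' @return A prediction data.frame (`approach = "us_method"`) with a
#'   `pathway` column naming the exit step.
#' @export
classify_us_method <- function(occurrences, params = us_method_params(),
                               extinct_check_first = TRUE) {
  stopifnot(inherits(params, "us_method_params"))
  if (nrow(occurrences) == 0) stop("no records to classify")
  sp <- unique(occurrences$species_id)
  cutoff <- params$reference_year - params$recent_year_cutoff
  rows <- lapply(sp, function(s) {
    rec <- occurrences[occurrences$species_id == s, , drop = FALSE]
    yrs <- rec$collection_year[!is.na(rec$collection_year)]
    recent <- length(yrs) > 0 && max(yrs) >= cutoff
    n_spec <- nrow(rec)
    n_loc <- length(unique(rec$locality_code[!is.na(rec$locality_code)]))
    steps <- list(
      extinct = function() if (!recent) c("PotentiallyExtinct", "no_recent_collections") else NULL,
      count = function() if (n_spec < params$min_specimens) c("PotentiallyThreatened", "few_specimens") else NULL,
      locality = function() if (n_loc < params$min_localities) c("PotentiallyThreatened", "few_localities") else NULL
    )
    order <- if (extinct_check_first) c("extinct", "count", "locality") else c("count", "extinct", "locality")
    out <- c("NotThreatened", "widespread_and_recent")
    for (nm in order) {
      hit <- steps[[nm]]()
      if (!is.null(hit)) { out <- hit; break }
    }
    data.frame(species_id = s, category = out[1], pathway = out[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  pred <- .prediction(res$species_id, "us_method", res$category)
  pred$pathway <- res$pathway
  pred
}

#' Pathway proportions through the specimen-triage tree
#'
#' Tabulates the fraction of species exiting the [classify_us_method()]
#' tree at each step; proportions sum to 1 over the terminal outcomes.
#'
#' @param predictions Output of [classify_us_method()].
#' @return Data.frame with `pathway`, `category`, `n`, `proportion`.
#' @export
us_pathway_proportions <- function(predictions) {
  stopifnot("pathway" %in% names(predictions))
  tab <- stats::aggregate(list(n = predictions$species_id),
                          by = list(pathway = predictions$pathway,
                                    category = predictions$category),
                          FUN = length)
  tab$proportion <- tab$n / sum(tab$n)
  tab[order(-tab$n), ]
}

#' Specimen-count threshold rule
#'
#' The naive baseline: a species is potentially threatened when it is known
#' from fewer than `threshold` specimens (strict `<`; a species with
#' exactly `threshold` specimens is not threatened).
#'
#' @param metrics Data.frame with `species_id` and `n_specimens` (e.g. from
#'   [summarize_ranges()]).
#' @param threshold Positive integer count threshold.
#' @return A prediction data.frame (`approach = "specimen_count"`).
#' @export
classify_specimen_count <- function(metrics, threshold) {
  stopifnot(threshold >= 1)
  cat_out <- ifelse(metrics$n_specimens < threshold,
                    "PotentiallyThreatened", "NotThreatened")
  .prediction(metrics$species_id, "specimen_count", cat_out)
}

#' Choose the specimen-count threshold that maximizes whole-dataset accuracy
#'
#' Sweeps every candidate threshold over the labelled species and returns
#' the one with the highest classification accuracy (threatened iff
#' specimen count below threshold), ties broken in favour of the smallest
#' threshold. The full accuracy-vs-threshold curve is returned so the
#' choice can be inspected.
#'
#' @param n_specimens Integer vector of per-species specimen counts.
#' @param threatened Logical vector: reference binary status (TRUE =
#'   threatened).
#' @param candidates Candidate thresholds (default `1:500`).
#' @return A list with `threshold`, `accuracy`, and `curve` (data.frame
#'   `threshold`, `accuracy`).
#' @export
select_count_threshold <- function(n_specimens, threatened, candidates = 1:500) {
  stopifnot(length(n_specimens) == length(threatened))
  if (length(n_specimens) == 0) stop("no labelled species supplied")
  if (length(candidates) == 0) stop("no candidate thresholds supplied")
  acc <- vapply(candidates, function(t) {
    mean((n_specimens < t) == threatened)
  }, numeric(1))
  best <- which.max(acc)  # which.max takes the first (smallest) maximiser
  list(threshold = candidates[best], accuracy = acc[best],
       curve = data.frame(threshold = candidates, accuracy = acc))
}

# Assemble a prediction data.frame and derive the binary status from the
# category (threatened iff CR/EN/VU/PotentiallyExtinct/PotentiallyThreatened).
.prediction <- function(species_id, approach, category, score = NA_real_) {
  binary <- rep(NA_character_, length(category))
  binary[category %in% .threatened_levels] <- "threatened"
  binary[category %in% .not_threatened_levels] <- "not_threatened"
  data.frame(species_id = species_id, approach = approach,
             category = category, binary = binary, score = score,
             stringsAsFactors = FALSE)
}
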