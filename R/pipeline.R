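#' Run the full assessment-comparison workflow
#'
#' Orchestrates the whole study on a synthetic dataset: simulate ->
#' clean (flag removal, dedup, antimeridian exclusion, locality
#' back-computation) -> range metrics -> all requested classifiers ->
#' evaluation against the reference labels -> Bayesian comparisons. All
#' intermediate tables and reports are written as CSV under `out_dir`, and
#' a JSON manifest records the configuration, seeds, per-stage record
#' counts and every file written, so each reported number can be
#' recomputed from the intermediates.
#'
#' Approach-specific conventions follow the comparison protocol: the
#' rule-based approaches (rcat, conr, us_method, specimen_count) are
#' applied to every species; the specimen-count threshold is chosen to
#' maximize accuracy on the whole dataset; the random forest is trained on
#' a stratified 75% split, tuned by repeated cross-validation on ROC area,
#' and evaluated on the held-out 25% only.
#'
#' @param config A [simulation_config()]; its `seed` drives every stage.
#' @param out_dir Output directory.
#' @param methods Character subset of
#'   `c("rcat", "conr", "us_method", "specimen_count", "random_forest")`.
#' @param range_cfg [range_config()] for the metric stage.
#' @param us_params [us_method_params()] for the triage tree.
#' @param count_candidates Candidate specimen-count thresholds.
#' @param rf_cv_folds,rf_cv_repeats,rf_grid,rf_ntree Random-forest protocol
#'   settings (see [tune_and_fit()]).
#' @param draws Posterior draws for every Bayesian comparison.
#' @return A `pipeline_result` list: `manifest`, `report` (eval_report with
#'   significance stars), `comparisons`, `predictions`, `metrics`,
#'   `pathways`, `by_category`, `by_criterion`, `count_threshold`,
#'   `rf` (fit + tuning + importance, when run), `sim`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         out_dir = tempfile("herbassess_run_"),
                         methods = c("rcat", "conr", "us_method",
                                     "specimen_count", "random_forest"),
                         range_cfg = range_config(),
                         us_params = us_method_params(),
                         count_candidates = 1:500,
                         rf_cv_folds = 10, rf_cv_repeats = 5,
                         rf_grid = rf_default_grid(), rf_ntree = 500,
                         draws = 10000) {
  methods <- match.arg(methods, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  counts_log <- list()

  # --- simulate -------------------------------------------------------
  sim <- simulate_dataset(config)
  sim_paths <- write_simulation(sim, out_dir)
  counts_log$simulated_records <- nrow(sim$occurrences)
  counts_log$simulated_species <- nrow(sim$species)

  # --- clean ----------------------------------------------------------
  occ <- clean_occurrences(sim$occurrences)
  counts_log$after_cleaning <- nrow(occ)
  am <- exclude_antimeridian_spanners(occ)
  occ <- am$kept
  counts_log$excluded_antimeridian_species <- length(am$excluded_species)
  layer <- make_admin_layer(config)
  occ <- assign_localities(occ, layer)
  utils::write.csv(occ, file.path(out_dir, "occurrences_clean.csv"),
                   row.names = FALSE, na = "")

  refs <- sim$species[!sim$species$species_id %in% am$excluded_species, ,
                      drop = FALSE]

  # --- range metrics --------------------------------------------------
  metrics <- summarize_ranges(occ, range_cfg)
  utils::write.csv(metrics, file.path(out_dir, "range_metrics.csv"),
                   row.names = FALSE, na = "")

  # --- classifiers ----------------------------------------------------
  ref_binary <- binarize_category(refs$reference_category)
  names(ref_binary) <- refs$species_id
  preds <- list()
  count_sel <- NULL
  rf_out <- NULL

  if ("rcat" %in% methods) {
    preds$rcat <- classify_rcat(metrics, config$thresholds)
  }
  if ("conr" %in% methods) {
    preds$conr <- classify_conr(metrics, config$thresholds)
  }
  if ("us_method" %in% methods) {
    preds$us_method <- classify_us_method(occ, us_params)
  }
  if ("specimen_count" %in% methods) {
    m <- metrics[metrics$species_id %in% refs$species_id, , drop = FALSE]
    count_sel <- select_count_threshold(
      m$n_specimens,
      ref_binary[m$species_id] == "threatened",
      candidates = count_candidates)
    utils::write.csv(count_sel$curve,
                     file.path(out_dir, "count_threshold_curve.csv"),
                     row.names = FALSE)
    preds$specimen_count <- classify_specimen_count(metrics, count_sel$threshold)
  }
  if ("random_forest" %in% methods) {
    ptab <- .predictor_table(refs, metrics)
    split <- split_train_test(ptab, train_fraction = 0.75, seed = seed)
    tuned <- tune_and_fit(split$train, cv_folds = rf_cv_folds,
                          cv_repeats = rf_cv_repeats, grid = rf_grid,
                          ntree = rf_ntree, seed = seed)
    prob <- predict_rf(tuned$fit, split$test, type = "prob")
    cls <- predict_rf(tuned$fit, split$test, type = "class")
    rf_pred <- .prediction(split$test$species_id, "random_forest",
                           rep(NA_character_, nrow(split$test)))
    rf_pred$binary <- cls
    rf_pred$score <- prob
    preds$random_forest <- rf_pred
    imp <- permutation_importance(tuned$fit, seed = seed)
    utils::write.csv(imp, file.path(out_dir, "rf_importance.csv"),
                     row.names = FALSE)
    utils::write.csv(tuned$tuning, file.path(out_dir, "rf_tuning.csv"),
                     row.names = FALSE)
    rf_out <- list(fit = tuned$fit, best = tuned$best, tuning = tuned$tuning,
                   importance = imp, test_auc = rf_test_auc(tuned$fit, split$test),
                   n_train = nrow(split$train), n_test = nrow(split$test))
  }
  preds <- lapply(preds, function(p) {
    if (!"pathway" %in% names(p)) p$pathway <- NA_character_
    p[, c("species_id", "approach", "category", "binary", "score", "pathway")]
  })
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE, na = "")

  # --- evaluation -----------------------------------------------------
  report <- score_predictions(predictions, refs, strata = "group_label")
  by_cat <- accuracy_by_category(predictions, refs)
  by_crit <- correct_classification_by_criterion(predictions, refs)
  pathways <- if ("us_method" %in% methods) {
    us_pathway_proportions(preds$us_method)
  } else NULL

  # --- Bayesian comparisons ------------------------------------------
  set.seed(seed + 1L)
  comparisons <- .compare_all(report, ref_binary, predictions, draws)
  report$significant_vs_default <- vapply(seq_len(nrow(report)), function(i) {
    hit <- comparisons$quantity == "accuracy" &
      comparisons$label_a == report$approach[i] &
      comparisons$label_b == "default" &
      comparisons$stratum == report$stratum[i]
    if (any(hit)) comparisons$significant[hit][1] else NA
  }, logical(1))

  utils::write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(by_cat, file.path(out_dir, "accuracy_by_category.csv"),
                   row.names = FALSE)
  utils::write.csv(by_crit, file.path(out_dir, "accuracy_by_criterion.csv"),
                   row.names = FALSE)
  if (!is.null(pathways)) {
    utils::write.csv(pathways, file.path(out_dir, "us_pathways.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    tool = "herbassess",
    version = as.character(utils::packageVersion("herbassess")),
    seed = seed,
    methods = methods,
    draws = draws,
    config = config[setdiff(names(config), "thresholds")],
    counts = counts_log,
    count_threshold = if (!is.null(count_sel)) count_sel$threshold else NULL,
    outputs = c(as.list(sim_paths), list(
      occurrences_clean = file.path(out_dir, "occurrences_clean.csv"),
      range_metrics = file.path(out_dir, "range_metrics.csv"),
      predictions = file.path(out_dir, "predictions.csv"),
      report = file.path(out_dir, "report.csv"),
      comparisons = file.path(out_dir, "comparisons.csv"),
      accuracy_by_category = file.path(out_dir, "accuracy_by_category.csv"),
      accuracy_by_criterion = file.path(out_dir, "accuracy_by_criterion.csv"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(manifest = manifest, report = report,
                 comparisons = comparisons, predictions = predictions,
                 metrics = metrics, pathways = pathways,
                 by_category = by_cat, by_criterion = by_crit,
                 count_threshold = if (!is.null(count_sel)) count_sel$threshold else NA,
                 rf = rf_out, sim = sim, out_dir = out_dir),
            class = "pipeline_result")
}

# Assemble the per-species predictor table for the random-forest stage:
# computed EOO joined to the simulated per-species predictors, plus the
# binary label.
.predictor_table <- function(refs, metrics) {
  pred_cols <- c("elevation_min", "elevation_max", "latitude_centroid",
                 "n_habitats", "realm_value", "av_temp", "season_temp",
                 "av_precip", "season_precip", "eti", "mean_gdp", "mean_hpd",
                 "min_hpd", "mean_hfi", "genus", "family", "order")
  tab <- merge(refs[, c("species_id", "reference_category", pred_cols)],
               metrics[, c("species_id", "eoo_km2")], by = "species_id")
  names(tab)[names(tab) == "eoo_km2"] <- "range_eoo"
  tab$label <- binarize_category(tab$reference_category)
  tab$reference_category <- NULL
  tab
}

# Every approach vs the default baseline (accuracy), overall and per
# stratum, plus pairwise accuracy/sensitivity/specificity comparisons on
# the overall stratum.
.compare_all <- function(report, ref_binary, predictions, draws) {
  rows <- list()
  add <- function(cmp, stratum) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = cmp$quantity, label_a = cmp$label_a, label_b = cmp$label_b,
      stratum = stratum, estimate = cmp$estimate,
      ci_low = cmp$ci_low, ci_high = cmp$ci_high,
      significant = cmp$significant, stringsAsFactors = FALSE)
  }
  for (i in which(report$stratum == "all")) {
    app <- report$approach[i]
    sp <- predictions$species_id[predictions$approach == app &
                                   !is.na(predictions$binary)]
    sp <- intersect(sp, names(ref_binary))
    correct <- report$tp[i] + report$tn[i]
    add(compare_to_default(correct, report$n[i], ref_binary[sp],
                           label = app, draws = draws), "all")
  }
  overall <- report[report$stratum == "all", , drop = FALSE]
  apps <- overall$approach
  if (length(apps) > 1) {
    for (i in seq_len(length(apps) - 1)) {
      for (j in seq((i + 1), length(apps))) {
        a <- overall[i, ]; b <- overall[j, ]
        add(compare_performance("accuracy",
                                list(correct = a$tp + a$tn, n = a$n),
                                list(correct = b$tp + b$tn, n = b$n),
                                a$approach, b$approach, draws), "all")
        for (q in c("sensitivity", "specificity")) {
          add(compare_performance(q,
                                  c(tp = a$tp, fn = a$fn, tn = a$tn, fp = a$fp),
                                  c(tp = b$tp, fn = b$fn, tn = b$tn, fp = b$fp),
                                  a$approach, b$approach, draws), "all")
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("herbassess pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("outputs in: ", x$out_dir, "\n\n", sep = "")
  print(x$report[x$report$stratum == "all", ])
  if (!is.na(x$count_threshold)) {
    cat("\nselected specimen-count threshold:", x$count_threshold, "\n")
  }
  if (!is.null(x$rf)) {
    cat("random-forest held-out AUC:", round(x$rf$test_auc, 3),
        "| top predictor:", x$rf$importance$predictor[1], "\n")
  }
  invisible(x)
}
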