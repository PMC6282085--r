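#' Collapse a five-level Red List category to binary threat status
#'
#' CR, EN and VU are "threatened"; NT and LC are "not threatened". Any
#' other input — EX, EW, DD, NE, or an unknown code — is a hard error:
#' extinct, data-deficient and not-evaluated species are excluded from
#' evaluation datasets before scoring, so meeting one here indicates an
#' upstream filtering bug rather than a value to guess at.
#'
#' @param category Character vector of categories in `{CR, EN, VU, NT, LC}`.
#' @return Character vector, `"threatened"` or `"not_threatened"`.
#' @examples
#' binarize_category(c("CR", "NT", "VU"))
#' @export
binarize_category <- function(category) {
  bad <- !category %in% .iucn_levels
  if (any(bad)) {
    stop("cannot binarize category(ies): ",
         paste(unique(category[bad]), collapse = ", "),
         " (only CR/EN/VU/NT/LC are evaluable)")
  }
  ifelse(category %in% c("CR", "EN", "VU"), "threatened", "not_threatened")
}

# Confusion counts with threatened as the positive class.
# pred, ref: character vectors "threatened"/"not_threatened".
.confusion <- function(pred, ref) {
  c(tp = sum(pred == "threatened" & ref == "threatened"),
    fn = sum(pred == "not_threatened" & ref == "threatened"),
    tn = sum(pred == "not_threatened" & ref == "not_threatened"),
    fp = sum(pred == "threatened" & ref == "not_threatened"))
}

.metrics_row <- function(cc) {
  n <- sum(cc)
  pos <- cc[["tp"]] + cc[["fn"]]
  neg <- cc[["tn"]] + cc[["fp"]]
  data.frame(
    n = n,
    tp = cc[["tp"]], fn = cc[["fn"]], tn = cc[["tn"]], fp = cc[["fp"]],
    accuracy = (cc[["tp"]] + cc[["tn"]]) / n,
    sensitivity = if (pos > 0) cc[["tp"]] / pos else NA_real_,
    specificity = if (neg > 0) cc[["tn"]] / neg else NA_real_,
    default_accuracy = max(pos, neg) / n
  )
}

#' Score predictions against reference Red List categories
#'
#' Joins predictions to the reference table on `species_id` and computes,
#' for each approach — overall and within each stratum (by default the
#' study group) — the confusion counts and the headline metrics: accuracy,
#' sensitivity (threatened species correctly predicted threatened),
#' specificity (not-threatened species correctly predicted not threatened)
#' and the default accuracy, i.e. the accuracy of always predicting the
#' stratum's majority status. Approaches are scored on the species they
#' actually produced predictions for: different approaches have different
#' data requirements, so their denominators legitimately differ, and
#' species with an `NA` prediction are excluded from that approach only.
#' Unmatched species ids are reported via a message, never silently
#' dropped.
#'
#' @param predictions Prediction data.frame (rows from one or more
#'   approaches; columns `species_id`, `approach`, `binary`).
#' @param references Reference data.frame: `species_id`,
#'   `reference_category` (five-level) and any stratum columns.
#' @param strata Character vector of reference columns to stratify by
#'   (default `"group_label"`; use `character(0)` for overall only).
#' @return An `eval_report` data.frame: one row per (approach, stratum)
#'   plus an `"all"` row per approach.
#' @export
score_predictions <- function(predictions, references, strata = "group_label") {
  stopifnot(all(c("species_id", "approach", "binary") %in% names(predictions)),
            all(c("species_id", "reference_category") %in% names(references)))
  strata <- intersect(strata, names(references))
  references$ref_binary <- binarize_category(references$reference_category)
  joined <- merge(predictions, references, by = "species_id")
  unmatched <- setdiff(predictions$species_id, references$species_id)
  if (length(unmatched)) {
    message(length(unmatched),
            " predicted species absent from the reference table: ",
            paste(utils::head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "")
  }
  joined <- joined[!is.na(joined$binary), , drop = FALSE]
  if (nrow(joined) == 0) stop("no species joined between predictions and references")
  one_stratum <- function(d, approach, stratum) {
    cbind(data.frame(approach = approach, stratum = stratum,
                     stringsAsFactors = FALSE),
          .metrics_row(.confusion(d$binary, d$ref_binary)))
  }
  out <- list()
  for (app in unique(joined$approach)) {
    d <- joined[joined$approach == app, , drop = FALSE]
    out[[length(out) + 1]] <- one_stratum(d, app, "all")
    for (sc in strata) {
      for (g in sort(unique(d[[sc]]))) {
        out[[length(out) + 1]] <- one_stratum(d[d[[sc]] == g, , drop = FALSE], app, g)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("eval_report", class(res))
  res
}

#' @export
print.eval_report <- function(x, ...) {
  d <- as.data.frame(x)
  d$accuracy <- round(100 * d$accuracy)          # whole-percent accuracy
  d$default_accuracy <- round(100 * d$default_accuracy)
  d$sensitivity <- round(d$sensitivity, 2)       # 2 dp, report style
  d$specificity <- round(d$specificity, 2)
  print(d[, c("approach", "stratum", "n", "accuracy", "default_accuracy",
              "sensitivity", "specificity")])
  invisible(x)
}

#' Per-category accuracy of binary threat predictions
#'
#' For each reference category CR/EN/VU/NT/LC, the fraction of species
#' whose binary prediction matches the category's binarized status. Note
#' the weighted mean of these per-category accuracies, weighted by
#' category counts, is exactly the overall accuracy.
#'
#' @inheritParams score_predictions
#' @return Data.frame: `approach`, `category`, `n`, `accuracy`.
#' @export
accuracy_by_category <- function(predictions, references) {
  references$ref_binary <- binarize_category(references$reference_category)
  joined <- merge(predictions, references, by = "species_id")
  joined <- joined[!is.na(joined$binary), , drop = FALSE]
  out <- list()
  for (app in unique(joined$approach)) {
    d <- joined[joined$approach == app, , drop = FALSE]
    for (cat in .iucn_levels) {
      dc <- d[d$reference_category == cat, , drop = FALSE]
      if (nrow(dc) == 0) next
      out[[length(out) + 1]] <- data.frame(
        approach = app, category = cat, n = nrow(dc),
        accuracy = mean(dc$binary == dc$ref_binary),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Probability of correct classification by cited Red List criterion
#'
#' Among species whose reference assessment is threatened, compares the
#' proportion correctly predicted threatened between species citing a given
#' criterion (A, B, C or D) and species not citing it. Criteria overlap — a
#' species citing B and D counts in both B's and D's "citing" groups. The
#' returned counts feed [compare_performance()] for a credible-interval
#' judgement of the difference.
#'
#' @inheritParams score_predictions
#' @param references Must carry a `criteria_cited` column: per species a
#'   string of cited criteria, e.g. `"B"`, `"B;D"` (any non-letter
#'   separator).
#' @return Data.frame with one row per (approach, criterion, citing group):
#'   `approach`, `criterion`, `cites`, `n`, `n_correct`,
#'   `proportion_correct`.
#' @export
correct_classification_by_criterion <- function(predictions, references) {
  stopifnot("criteria_cited" %in% names(references))
  references$ref_binary <- binarize_category(references$reference_category)
  joined <- merge(predictions, references, by = "species_id")
  joined <- joined[!is.na(joined$binary) & joined$ref_binary == "threatened", ,
                   drop = FALSE]
  out <- list()
  for (app in unique(joined$approach)) {
    d <- joined[joined$approach == app, , drop = FALSE]
    for (cr in c("A", "B", "C", "D")) {
      cites <- grepl(cr, d$criteria_cited, fixed = TRUE)
      for (grp in c(TRUE, FALSE)) {
        dg <- d[cites == grp, , drop = FALSE]
        if (nrow(dg) == 0) next
        out[[length(out) + 1]] <- data.frame(
          approach = app, criterion = cr, cites = grp, n = nrow(dg),
          n_correct = sum(dg$binary == "threatened"),
          proportion_correct = mean(dg$binary == "threatened"),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
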