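#' Posterior draws for a classification accuracy
#'
#' Conjugate Bayesian estimation of a binomial proportion: with `correct`
#' successes in `n` species and a flat Beta(1, 1) prior, the posterior is
#' Beta(correct + 1, n - correct + 1), sampled exactly (no MCMC needed).
#'
#' @param correct Number of correctly classified species (0..n).
#' @param n Number of species evaluated (>= 1).
#' @param draws Number of posterior draws (default 10000).
#' @return Numeric vector of `draws` posterior accuracy samples.
#' @export
posterior_accuracy <- function(correct, n, draws = 10000) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(correct >= 0, correct <= n, draws >= 1)
  stats::rbeta(draws, correct + 1, n - correct + 1)
}

#' Posterior draws for sensitivity and specificity
#'
#' Conjugate Bayesian estimation of the four confusion-matrix cell
#' probabilities under a multinomial likelihood with a flat
#' Dirichlet(1,1,1,1) prior. Each posterior draw of the cell probabilities
#' (via normalized Gamma variates) is transformed to sensitivity
#' `p_tp / (p_tp + p_fn)` and specificity `p_tn / (p_tn + p_fp)`. Empty
#' cells are handled by the prior's smoothing — no special-casing.
#'
#' @param confusion Named numeric vector or list with elements `tp`, `fn`,
#'   `tn`, `fp`.
#' @param draws Number of posterior draws (default 10000).
#' @return Data.frame with columns `sensitivity` and `specificity`, one row
#'   per draw.
#' @export
posterior_sens_spec <- function(confusion, draws = 10000) {
  cc <- unlist(confusion)[c("tp", "fn", "tn", "fp")]
  if (any(is.na(cc)) || any(cc < 0)) stop("confusion must supply non-negative tp, fn, tn, fp")
  if (sum(cc) < 1) stop("confusion counts sum to zero")
  g <- matrix(stats::rgamma(4 * draws, shape = rep(cc + 1, each = draws)),
              nrow = draws)
  colnames(g) <- c("tp", "fn", "tn", "fp")
  data.frame(sensitivity = g[, "tp"] / (g[, "tp"] + g[, "fn"]),
             specificity = g[, "tn"] / (g[, "tn"] + g[, "fp"]))
}

#' Credible-interval comparison of two classifiers
#'
#' Draws independent posterior samples of a performance quantity for two
#' approaches, pairs them by draw index, and summarizes the difference
#' `a - b` by its central 95% credible interval. The difference is declared
#' significant when zero lies outside that interval. For `quantity =
#' "accuracy"` supply `list(correct =, n =)` per side (binomial
#' likelihood); for `"sensitivity"` or `"specificity"` supply confusion
#' counts `c(tp =, fn =, tn =, fp =)` per side (multinomial likelihood).
#'
#' The two approaches are modelled as independent even when evaluated on
#' overlapping species sets, matching the stated likelihoods; no multiple-
#' comparison correction is applied anywhere in this package, so users
#' running many comparisons should read the intervals accordingly.
#'
#' @param quantity One of `"accuracy"`, `"sensitivity"`, `"specificity"`.
#' @param counts_a,counts_b Counts for each side (see Details).
#' @param label_a,label_b Approach labels carried into the result.
#' @param draws Number of posterior draws (default 10000).
#' @param ci_level Credible level (default 0.95).
#' @return A `comparison_result` list: `quantity`, `label_a`, `label_b`,
#'   `samples` (the difference draws), `estimate` (posterior mean
#'   difference), `ci_low`, `ci_high`, `significant`.
#' @examples
#' set.seed(1)
#' compare_performance("accuracy", list(correct = 99, n = 100),
#'                     list(correct = 50, n = 100), "good", "bad")
#' @export
compare_performance <- function(quantity = c("accuracy", "sensitivity", "specificity"),
                                counts_a, counts_b,
                                label_a = "a", label_b = "b",
                                draws = 10000, ci_level = 0.95) {
  quantity <- match.arg(quantity)
  draw_side <- function(counts) {
    if (quantity == "accuracy") {
      posterior_accuracy(counts$correct, counts$n, draws)
    } else {
      posterior_sens_spec(counts, draws)[[quantity]]
    }
  }
  diff <- draw_side(counts_a) - draw_side(counts_b)
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(diff, c(alpha, 1 - alpha)))
  structure(list(quantity = quantity, label_a = label_a, label_b = label_b,
                 samples = diff, estimate = mean(diff),
                 ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s - %s = %.3f [%.3f, %.3f] %s\n",
              x$quantity, x$label_a, x$label_b, x$estimate,
              x$ci_low, x$ci_high,
              if (x$significant) "(significant)" else "(not significant)"))
  invisible(x)
}

#' Compare an approach's accuracy to the default baseline
#'
#' The default baseline is the majority-class classifier: on the same
#' species set, it scores one correct for every species belonging to the
#' most common reference status. Its correctness counts are given exactly
#' the same conjugate posterior treatment as a real approach and compared
#' with [compare_performance()]; a significant positive difference is the
#' minimum bar any assessment method must clear.
#'
#' @param correct Number of species the approach classified correctly.
#' @param n Number of species the approach was evaluated on.
#' @param reference_binary Character vector of the reference statuses
#'   (`"threatened"` / `"not_threatened"`) of those same `n` species.
#' @param label Approach label for the result.
#' @param draws Number of posterior draws (default 10000).
#' @return A `comparison_result` with `label_b = "default"`.
#' @export
compare_to_default <- function(correct, n, reference_binary, label = "approach",
                               draws = 10000) {
  if (length(reference_binary) != n) {
    stop("reference_binary must have length n")
  }
  default_correct <- max(table(factor(reference_binary,
                                      levels = c("threatened", "not_threatened"))))
  compare_performance("accuracy",
                      list(correct = correct, n = n),
                      list(correct = default_correct, n = n),
                      label_a = label, label_b = "default", draws = draws)
}
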