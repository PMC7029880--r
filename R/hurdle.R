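#' Eligibility rule for the binary co-occurrence analysis
#'
#' The binomial-logit model on binarized co-occurrence is only fitted in
#' matrices where more than five species pairs never co-occur, i.e. where
#' the zero-pair count `n0 >= 6`; with fewer zeros the binary outcome is too
#' unbalanced to be informative.
#'
#' @param pairs a `pair_table` from [pairwise_jaccard()].
#' @return `TRUE` when `n0 >= 6`.
#' @export
check_binary_eligibility <- function(pairs) {
  zero_pair_count(pairs) >= 6L
}

# One-row ModelResult record. statistic is Wald z (binary) or t (strength);
# withheld records carry NA estimates and a human-readable reason.
model_result <- function(scale_label, matrix_name, trait_set, analysis_type,
                         estimate = NA_real_, std_error = NA_real_,
                         statistic = NA_real_, p_value = NA_real_,
                         n_obs = NA_integer_, n_zero = NA_integer_,
                         eligible = TRUE, converged = NA, reason = "") {
  data.frame(scale_label = scale_label, matrix_name = matrix_name,
             trait_set = trait_set, analysis_type = analysis_type,
             estimate = estimate, std_error = std_error,
             statistic = statistic, p_value = p_value,
             n_obs = as.integer(n_obs), n_zero = as.integer(n_zero),
             eligible = eligible, converged = converged, reason = reason,
             mechanism = NA_character_, stringsAsFactors = FALSE)
}

# Align dissimilarity values with the rows of a pair table.
match_dissim <- function(pairs, dissim, trait_set) {
  if (!trait_set %in% names(dissim)) {
    abort_lookup(sprintf("trait set '%s' not in dissimilarity table", trait_set))
  }
  keys <- pair_key(pairs$species_a, pairs$species_b)
  pos <- match(keys, pair_key(dissim$species_a, dissim$species_b))
  if (anyNA(pos)) {
    miss <- which(is.na(pos))[1]
    abort_config(sprintf("no dissimilarity for pair (%s, %s)",
                         pairs$species_a[miss], pairs$species_b[miss]))
  }
  dissim[[trait_set]][pos]
}

#' Binary co-occurrence analysis (step 1 of the hurdle)
#'
#' Logistic regression (binomial family, logit link) of the binarized
#' co-occurrence indicator (`1` when the pair shares at least one sampling
#' unit) on the trait-set dissimilarity, with intercept. The slope's Wald z
#' statistic and two-sided p-value are reported. Ineligible matrices
#' (fewer than six zero pairs, see [check_binary_eligibility()]) yield a
#' withheld record rather than a fit; perfect separation or IRLS
#' non-convergence yields a record flagged `converged = FALSE` rather than
#' an error, so a planner sweep can complete.
#'
#' @param pairs a `pair_table` from [pairwise_jaccard()].
#' @param dissim a `dissimilarity_table` from [pair_dissimilarities()]
#'   covering every pair in `pairs`.
#' @param trait_set one of [trait_sets()].
#' @return A one-row ModelResult data frame.
#' @export
fit_binary <- function(pairs, dissim, trait_set) {
  n_zero <- zero_pair_count(pairs)
  base <- function(...) {
    model_result(attr(pairs, "scale_label"), attr(pairs, "matrix_name"),
                 trait_set, "binary", n_obs = nrow(pairs), n_zero = n_zero, ...)
  }
  if (!check_binary_eligibility(pairs)) {
    return(base(eligible = FALSE, reason = "fewer than six zero pairs"))
  }
  d <- match_dissim(pairs, dissim, trait_set)
  if (stats::sd(d) == 0) {
    abort_computation(sprintf("dissimilarity '%s' is constant over pairs", trait_set))
  }
  y <- pairs$cooccurs
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  converged <- fit$converged && !separation
  base(estimate = co["d", "Estimate"], std_error = co["d", "Std. Error"],
       statistic = co["d", "z value"], p_value = co["d", "Pr(>|z|)"],
       converged = converged,
       reason = if (converged) "" else "possible separation or non-convergence")
}

#' Co-occurrence strength analysis (step 2 of the hurdle)
#'
#' Ordinary least squares of the log-transformed Jaccard index (natural log)
#' on the trait-set dissimilarity, restricted to pairs that co-occur at
#' least once (`ji > 0`; the log is undefined at zero, and those pairs are
#' the binary step's business). The slope's t statistic is tested two-sided
#' on `n - 2` degrees of freedom. With fewer than three positive pairs the
#' result is withheld with a reason instead of fitted.
#'
#' @inheritParams fit_binary
#' @return A one-row ModelResult data frame.
#' @export
fit_strength <- function(pairs, dissim, trait_set) {
  n_zero <- zero_pair_count(pairs)
  pos <- pairs$ji > 0
  base <- function(...) {
    model_result(attr(pairs, "scale_label"), attr(pairs, "matrix_name"),
                 trait_set, "strength", n_obs = sum(pos), n_zero = n_zero, ...)
  }
  if (sum(pos) < 3) {
    return(base(reason = "insufficient positive pairs"))
  }
  d <- match_dissim(pairs, dissim, trait_set)[pos]
  if (stats::sd(d) == 0) {
    abort_computation(sprintf("dissimilarity '%s' is constant over positive pairs",
                              trait_set))
  }
  fit <- stats::lm(log(pairs$ji[pos]) ~ d)
  co <- summary(fit)$coefficients
  base(estimate = co["d", "Estimate"], std_error = co["d", "Std. Error"],
       statistic = co["d", "t value"], p_value = co["d", "Pr(>|t|)"],
       converged = TRUE)
}
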