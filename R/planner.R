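#' Enumerate the analysis grid over matrices, trait sets and analysis types
#'
#' For every matrix, nine co-occurrence strength analyses (one per trait set)
#' are always planned; the nine binary co-occurrence analyses are planned
#' only where the matrix has at least six zero pairs
#' ([check_binary_eligibility()]). With one continental matrix this yields
#' 18 analyses; with five eligible regional matrices, 90.
#'
#' @param pair_tables list of `pair_table` objects ([pairwise_jaccard()]),
#'   one per matrix; names are taken from each table's `matrix_name`.
#' @param schema a [trait_schema()] defining the trait sets.
#' @return An `analysis_plan`: a data frame of entries (`matrix_name`,
#'   `scale_label`, `trait_set`, `analysis_type`, `eligible`, `n_zero`) with
#'   per-scale/type counts as the `counts` attribute.
#' @export
build_plan <- function(pair_tables, schema = ant_trait_schema()) {
  if (!length(pair_tables)) abort_validation("need at least one pair table")
  if (inherits(pair_tables, "pair_table")) pair_tables <- list(pair_tables)
  sets <- trait_sets(schema)
  entries <- do.call(rbind, lapply(pair_tables, function(pt) {
    if (!inherits(pt, "pair_table")) abort_validation("all inputs must be pair_table objects")
    eligible <- check_binary_eligibility(pt)
    types <- if (eligible) c("binary", "strength") else "strength"
    grid <- expand.grid(trait_set = sets, analysis_type = types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(matrix_name = attr(pt, "matrix_name"),
               scale_label = attr(pt, "scale_label"),
               trait_set = grid$trait_set, analysis_type = grid$analysis_type,
               eligible = eligible, n_zero = attr(pt, "n_zero"),
               stringsAsFactors = FALSE)
  }))
  entries <- entries[order(entries$scale_label, entries$matrix_name,
                           match(entries$trait_set, sets), entries$analysis_type), ]
  rownames(entries) <- NULL
  counts <- as.data.frame(table(scale_label = entries$scale_label,
                                analysis_type = entries$analysis_type),
                          responseName = "n_analyses")
  counts <- counts[counts$n_analyses > 0, ]
  structure(entries, counts = counts, class = c("analysis_plan", "data.frame"))
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat(sprintf("Analysis plan: %d analyses over %d matrices\n",
              nrow(x), length(unique(x$matrix_name))))
  print.data.frame(attr(x, "counts"), row.names = FALSE)
  invisible(x)
}

#' Execute an analysis plan
#'
#' Runs [fit_binary()] / [fit_strength()] for every plan entry against the
#' pool-level dissimilarity table and classifies each fitted slope with
#' [classify_mechanism()]. Computation failures on individual entries
#' (e.g. a constant predictor) are recorded as withheld results so the sweep
#' always completes. Results are ordered by (scale, matrix, trait set,
#' analysis type) for reproducible diffs.
#'
#' @param plan an [build_plan()] result.
#' @param pair_tables the same list of pair tables the plan was built from.
#' @param dissim a `dissimilarity_table` ([pair_dissimilarities()]) covering
#'   every species pair present in any matrix.
#' @param alpha significance level for the mechanism call (default 0.05).
#' @return A data frame of ModelResult rows with a `mechanism` column.
#' @export
run_plan <- function(plan, pair_tables, dissim, alpha = 0.05) {
  if (inherits(pair_tables, "pair_table")) pair_tables <- list(pair_tables)
  tab_names <- vapply(pair_tables, attr, "", "matrix_name")
  results <- lapply(seq_len(nrow(plan)), function(k) {
    entry <- plan[k, ]
    pt <- pair_tables[[match(entry$matrix_name, tab_names)]]
    if (is.null(pt)) abort_config(sprintf("no pair table for matrix '%s'",
                                          entry$matrix_name))
    fitter <- if (entry$analysis_type == "binary") fit_binary else fit_strength
    tryCatch(
      fitter(pt, dissim, entry$trait_set),
      tc_computation_error = function(e) {
        model_result(entry$scale_label, entry$matrix_name, entry$trait_set,
                     entry$analysis_type, n_obs = nrow(pt),
                     n_zero = attr(pt, "n_zero"), eligible = entry$eligible,
                     converged = FALSE, reason = conditionMessage(e))
      }
    )
  })
  out <- do.call(rbind, results)
  out$mechanism <- as.character(classify_mechanism(out, alpha = alpha))
  out <- out[order(out$scale_label, out$matrix_name,
                   match(out$trait_set, trait_sets()), out$analysis_type), ]
  rownames(out) <- NULL
  out
}

#' Classify fitted slopes into assembly mechanisms
#'
#' A significant negative dissimilarity slope (p below `alpha`) indicates
#' environmental filtering (co-occurring species are functionally similar);
#' a significant positive slope indicates competitive exclusion; anything
#' else — non-significant, withheld, or non-converged — is classified as
#' neutral. Withheld/non-converged records are annotated distinctly via the
#' `annotation` attribute, since they carry no slope evidence at all.
#'
#' @param results one or more ModelResult rows ([fit_binary()],
#'   [fit_strength()], [run_plan()]).
#' @param alpha significance level (default 0.05).
#' @return Factor with levels `environmental_filtering`, `competition`,
#'   `neutral`, of one call per row; attribute `annotation` distinguishes
#'   `"not_estimated"` rows from genuinely non-significant (`"tested"`) ones.
#' @export
#' @examples
#' res <- rbind(
#'   data.frame(estimate = -0.85, p_value = 1e-5, converged = TRUE),
#'   data.frame(estimate = 0.53, p_value = 0.001, converged = TRUE),
#'   data.frame(estimate = 0.15, p_value = 0.147, converged = TRUE))
#' classify_mechanism(res)
classify_mechanism <- function(results, alpha = 0.05) {
  est <- results$estimate
  p <- results$p_value
  converged <- if ("converged" %in% names(results)) results$converged else TRUE
  estimated <- !is.na(est) & !is.na(p) & (is.na(converged) | converged)
  call <- rep("neutral", NROW(results))
  call[estimated & p < alpha & est < 0] <- "environmental_filtering"
  call[estimated & p < alpha & est > 0] <- "competition"
  out <- factor(call, levels = c("environmental_filtering", "competition", "neutral"))
  attr(out, "annotation") <- ifelse(estimated, "tested", "not_estimated")
  out
}

#' End-to-end analysis of a set of occurrence matrices
#'
#' Convenience wrapper: computes pair tables for every matrix, builds the
#' pool dissimilarity context and table from the trait data, enumerates the
#' plan and runs it.
#'
#' @param matrices list of [occurrence_matrix()] objects.
#' @param traits pool [trait_table()].
#' @param alpha significance level (default 0.05).
#' @return List with elements `pairs` (list of pair tables), `plan`,
#'   `results`.
#' @export
analyze_assembly <- function(matrices, traits, alpha = 0.05) {
  if (inherits(matrices, "occurrence_matrix")) matrices <- list(matrices)
  schema <- attr(traits, "schema")
  pairs <- lapply(matrices, pairwise_jaccard)
  ctx <- gower_context(traits, schema)
  all_sp <- sort(unique(unlist(lapply(matrices, function(m) colnames(m$incidence)))))
  missing_sp <- setdiff(all_sp, traits$species)
  if (length(missing_sp)) {
    abort_config(sprintf("species without trait data: %s",
                         paste(missing_sp, collapse = ", ")))
  }
  dissim <- pair_dissimilarities(ctx, traits, species = all_sp)
  plan <- build_plan(pairs, schema)
  list(pairs = pairs, plan = plan,
       results = run_plan(plan, pairs, dissim, alpha = alpha))
}
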