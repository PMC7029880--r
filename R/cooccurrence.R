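#' Pairwise Jaccard co-occurrence for all species pairs in a matrix
#'
#' For each unordered species pair (a, b) counts the sampling units holding
#' only a (A), only b (B) and both (AB), and computes the Jaccard
#' co-occurrence index
#' \deqn{JI_{ab} = AB / (A + B + AB).}
#' Units where neither species occurs do not enter the index. `ji = 0` means
#' the pair never co-occurs; `ji = 1` means the two species have identical
#' occupancy.
#'
#' @param mat an [occurrence_matrix()] with at least two species.
#' @return A `pair_table`: a data frame with one row per unordered pair
#'   (`species_a < species_b` lexicographically) and columns `species_a`,
#'   `species_b`, `A`, `B`, `AB`, `ji`, `cooccurs`, carrying attributes
#'   `matrix_name`, `scale_label`, `n_pairs` and `n_zero` (the number of
#'   pairs with `ji = 0`).
#' @export
#' @examples
#' m <- occurrence_matrix(
#'   matrix(c(1, 1, 1, 0, 0, 1, 1, 1), 4, 2,
#'          dimnames = list(paste0("u", 1:4), c("a", "b"))),
#'   scale_label = "local", name = "demo")
#' pairwise_jaccard(m)  # A = 1, B = 1, AB = 2, ji = 0.5
pairwise_jaccard <- function(mat) {
  if (!inherits(mat, "occurrence_matrix")) {
    abort_validation("mat must be an occurrence_matrix")
  }
  x <- mat$incidence
  if (ncol(x) < 2) {
    abort_computation(sprintf(
      "co-occurrence needs >=2 species; matrix '%s' has %d", mat$name, ncol(x)))
  }
  # deterministic output: canonicalize species order, pairs in lexicographic
  # order with species_a < species_b
  x <- x[, order(colnames(x)), drop = FALSE]
  shared <- crossprod(x)                 # unit counts shared by each pair
  occ <- diag(shared)                    # per-species occupancy
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  ab <- shared[idx]
  a_only <- occ[idx[, 1]] - ab
  b_only <- occ[idx[, 2]] - ab
  ji <- ab / (a_only + b_only + ab)
  out <- data.frame(
    species_a = colnames(x)[idx[, 1]],
    species_b = colnames(x)[idx[, 2]],
    A = as.integer(a_only), B = as.integer(b_only), AB = as.integer(ab),
    ji = ji, cooccurs = as.integer(ab >= 1),
    stringsAsFactors = FALSE
  )
  structure(out,
            matrix_name = mat$name, scale_label = mat$scale_label,
            n_pairs = nrow(out), n_zero = sum(out$ji == 0),
            class = c("pair_table", "data.frame"))
}

#' Number of never-co-occurring pairs in a pair table
#'
#' Counts the species pairs with Jaccard co-occurrence exactly zero (`n0`).
#' This margin drives eligibility for the binary co-occurrence analysis
#' ([check_binary_eligibility()]).
#'
#' @param pairs a `pair_table` from [pairwise_jaccard()].
#' @return Integer count.
#' @export
zero_pair_count <- function(pairs) {
  if (!inherits(pairs, "pair_table")) abort_validation("pairs must be a pair_table")
  as.integer(attr(pairs, "n_zero"))
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("Pair table '%s' (%s scale): %d pairs, %d with zero co-occurrence\n",
              attr(x, "matrix_name"), attr(x, "scale_label"),
              attr(x, "n_pairs"), attr(x, "n_zero")))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more pairs\n", nrow(x) - 6))
  invisible(x)
}
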