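#' The nine trait sets
#'
#' Dissimilarities are computed for nine trait sets: all six traits together,
#' the two ecological groups (`tolerance`, `niche`), and each single trait.
#' The composite values are unweighted means of their single-trait
#' components, so `all_traits` equals the mean of the six single-trait
#' dissimilarities and each group equals the mean of its three.
#'
#' @param schema a [trait_schema()].
#' @return Character vector of trait-set names.
#' @export
trait_sets <- function(schema = ant_trait_schema()) {
  c("all_traits", "tolerance", "niche", schema$trait)
}

#' Build a Gower dissimilarity context from the full species pool
#'
#' Gower components for quantitative traits are normalized by the trait's
#' range. Because ranges depend on the species set, they are fixed once here
#' over the complete pool (the largest scale, where the species count is
#' highest) and reused unchanged for every regional or local subset, so a
#' pair's dissimilarity is identical at every scale.
#'
#' @param traits a [trait_table()] covering the full pool.
#' @param schema a [trait_schema()]; defaults to the table's own schema.
#' @return An object of class `gower_context` holding the schema, the pooled
#'   quantitative ranges and the pool species set.
#' @export
gower_context <- function(traits, schema = attr(traits, "schema")) {
  if (!inherits(traits, "trait_table")) abort_validation("traits must be a trait_table")
  if (is.null(schema)) abort_validation("no trait schema available")
  quant <- schema$trait[schema$kind == "quantitative"]
  ranges <- lapply(quant, function(tr) {
    rng <- range(traits[[tr]])
    if (diff(rng) <= 0) {
      abort_computation(sprintf(
        "quantitative trait '%s' is constant over the pool (range would be zero)", tr))
    }
    rng
  })
  names(ranges) <- quant
  structure(list(schema = schema, ranges = ranges,
                 pool_species = sort(traits$species)),
            class = "gower_context")
}

#' @export
print.gower_context <- function(x, ...) {
  cat(sprintf("Gower context: %d pool species, ranges fixed for %s\n",
              length(x$pool_species),
              paste(sprintf("%s [%.3g, %.3g]", names(x$ranges),
                            vapply(x$ranges, `[`, 0, 1),
                            vapply(x$ranges, `[`, 0, 2)), collapse = "; ")))
  invisible(x)
}

# Vectorized single-trait Gower component between index vectors i and j of
# the trait table. Quantitative: |xi - xj| / pooled range; categorical: simple
# matching (0 same level, 1 different); fuzzy: half Manhattan distance over
# component proportions (in [0, 1] since each row sums to 1).
single_trait_dissim <- function(ctx, traits, trait, i, j) {
  k <- match(trait, ctx$schema$trait)
  if (is.na(k)) abort_lookup(sprintf("unknown trait '%s'", trait))
  kind <- ctx$schema$kind[k]
  if (kind == "quantitative") {
    rng <- ctx$ranges[[trait]]
    pmin(abs(traits[[trait]][i] - traits[[trait]][j]) / diff(rng), 1)
  } else if (kind == "categorical") {
    as.numeric(traits[[trait]][i] != traits[[trait]][j])
  } else {
    cc <- fuzzy_columns(ctx$schema, trait)
    m <- as.matrix(traits[cc])
    0.5 * rowSums(abs(m[i, , drop = FALSE] - m[j, , drop = FALSE]))
  }
}

set_members <- function(ctx, trait_set) {
  schema <- ctx$schema
  switch(trait_set,
         all_traits = schema$trait,
         tolerance = schema$trait[schema$group == "tolerance"],
         niche = schema$trait[schema$group == "niche"],
         {
           if (!trait_set %in% schema$trait) {
             abort_lookup(sprintf("unknown trait set '%s'", trait_set))
           }
           trait_set
         })
}

#' Gower dissimilarity between two species for one trait set
#'
#' The value is the unweighted mean of the single-trait Gower components in
#' the set (quantitative components range-normalized with the pooled ranges
#' in `ctx`; categorical by simple matching; fuzzy by half Manhattan distance
#' over proportions). All values lie in [0, 1].
#'
#' @param a,b species identifiers.
#' @param trait_set one of [trait_sets()].
#' @param ctx a [gower_context()].
#' @param traits the [trait_table()] holding both species.
#' @return A single dissimilarity in [0, 1].
#' @export
#' @examples
#' pool <- generate_pool(scenario_config(n_species = 10, seed = 1))
#' ctx <- gower_context(pool)
#' pair_dissimilarity("sp001", "sp002", "all_traits", ctx, pool)
pair_dissimilarity <- function(a, b, trait_set, ctx, traits) {
  i <- match(a, traits$species)
  j <- match(b, traits$species)
  if (is.na(i)) abort_lookup(sprintf("species '%s' not in trait table", a))
  if (is.na(j)) abort_lookup(sprintf("species '%s' not in trait table", b))
  members <- set_members(ctx, trait_set)
  mean(vapply(members, single_trait_dissim, 0,
              ctx = ctx, traits = traits, i = i, j = j))
}

#' Dissimilarity table: all species pairs by all nine trait sets
#'
#' @param ctx a [gower_context()].
#' @param traits the pool [trait_table()].
#' @param species optional subset of species (default: all in `traits`).
#' @return A `dissimilarity_table`: a data frame with `species_a`,
#'   `species_b` (a < b) and one column per trait set in [trait_sets()].
#' @export
pair_dissimilarities <- function(ctx, traits, species = NULL) {
  if (is.null(species)) species <- traits$species
  species <- sort(species)
  missing_sp <- setdiff(species, traits$species)
  if (length(missing_sp)) {
    abort_lookup(sprintf("species not in trait table: %s",
                         paste(missing_sp, collapse = ", ")))
  }
  if (length(species) < 2) abort_computation("need >=2 species for pair dissimilarities")
  idx <- match(species, traits$species)
  pair_idx <- which(upper.tri(diag(length(species))), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  i <- idx[pair_idx[, 1]]
  j <- idx[pair_idx[, 2]]
  singles <- vapply(ctx$schema$trait, single_trait_dissim, numeric(length(i)),
                    ctx = ctx, traits = traits, i = i, j = j)
  singles <- matrix(singles, nrow = length(i),
                    dimnames = list(NULL, ctx$schema$trait))
  out <- data.frame(
    species_a = species[pair_idx[, 1]],
    species_b = species[pair_idx[, 2]],
    all_traits = rowMeans(singles),
    tolerance = rowMeans(singles[, ctx$schema$trait[ctx$schema$group == "tolerance"],
                                 drop = FALSE]),
    niche = rowMeans(singles[, ctx$schema$trait[ctx$schema$group == "niche"],
                             drop = FALSE]),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(singles))
  rownames(out) <- NULL
  structure(out, class = c("dissimilarity_table", "data.frame"))
}

#' Square dissimilarity matrix for one trait set
#'
#' Convenience wrapper used by the simulator's limiting-similarity rule and
#' for inspection; symmetric with a zero diagonal.
#'
#' @inheritParams pair_dissimilarities
#' @param trait_set one of [trait_sets()].
#' @return A symmetric species-by-species matrix.
#' @export
dissimilarity_matrix <- function(ctx, traits, trait_set, species = NULL) {
  if (is.null(species)) species <- traits$species
  species <- sort(species)
  n <- length(species)
  idx <- match(species, traits$species)
  if (anyNA(idx)) abort_lookup("species not in trait table")
  members <- set_members(ctx, trait_set)
  pair_idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- idx[pair_idx[, 1]]
  j <- idx[pair_idx[, 2]]
  vals <- rowMeans(vapply(members, single_trait_dissim, numeric(length(i)),
                          ctx = ctx, traits = traits, i = i, j = j))
  m <- matrix(0, n, n, dimnames = list(species, species))
  m[pair_idx] <- vals
  m[pair_idx[, c(2, 1), drop = FALSE]] <- vals
  m
}

#' Pairwise Pearson correlation screen among trait columns
#'
#' Checks for strongly redundant traits before dissimilarity analysis.
#' Traits are encoded numerically: quantitative columns as stored (i.e.
#' post-transform), two-level categorical traits as 0/1, the three-level
#' queen-number trait ordinally (monogynous 0, both 0.5, polygynous 1 when
#' those levels are present, otherwise integer level codes), and fuzzy
#' components as separate columns. Pairs with `|r|` at or above the
#' threshold are flagged; zero-variance columns yield `NA` correlations,
#' reported rather than dropped.
#'
#' @param traits a [trait_table()].
#' @param threshold flag limit on `|r|` (default 0.7).
#' @return Data frame with `trait_i`, `trait_j`, `r`, `p_value`, `flagged`.
#' @export
trait_correlation_screen <- function(traits, threshold = 0.7) {
  if (nrow(traits) < 3) abort_computation("correlation screen needs >=3 species")
  schema <- attr(traits, "schema")
  enc <- list()
  for (k in seq_len(nrow(schema))) {
    tr <- schema$trait[k]
    if (schema$kind[k] == "quantitative") {
      enc[[tr]] <- traits[[tr]]
    } else if (schema$kind[k] == "fuzzy") {
      for (cc in fuzzy_columns(schema, tr)) enc[[cc]] <- traits[[cc]]
    } else {
      lev <- sort(unique(traits[[tr]]))
      if (setequal(lev, c("monogynous", "polygynous")) ||
          setequal(lev, c("both", "monogynous", "polygynous"))) {
        enc[[tr]] <- c(monogynous = 0, both = 0.5, polygynous = 1)[traits[[tr]]]
      } else {
        enc[[tr]] <- as.numeric(factor(traits[[tr]], levels = lev)) - 1
      }
    }
  }
  enc <- as.data.frame(enc)
  cols <- names(enc)
  combos <- utils::combn(length(cols), 2)
  res <- apply(combos, 2, function(ij) {
    x <- enc[[ij[1]]]
    y <- enc[[ij[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(x, y, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  })
  data.frame(
    trait_i = cols[combos[1, ]],
    trait_j = cols[combos[2, ]],
    r = res[1, ],
    p_value = res[2, ],
    flagged = !is.na(res[1, ]) & abs(res[1, ]) >= threshold,
    stringsAsFactors = FALSE
  )
}
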