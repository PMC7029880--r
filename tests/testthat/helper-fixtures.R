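# Fixture builders; everything is generated in code at test time.

# A raw (untransformed) six-trait table for n species; read through
# trait_table() the colony sizes come back as logs.
random_trait_df <- function(n, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(n * 3, shape = c(0.8, 2, 1.2)), n, 3, byrow = TRUE)
  diet <- g / rowSums(g)
  data.frame(
    species = sprintf("sp%03d", seq_len(n)),
    n_queens = sample(c("monogynous", "polygynous", "both"), n, TRUE,
                      prob = c(0.5, 0.35, 0.15)),
    colony_size = exp(runif(n, 3, 11.5)),
    brood_cycle = sample(c("seasonal", "year_round"), n, TRUE),
    diet_seed = diet[, 1], diet_insect = diet[, 2], diet_liquid = diet[, 3],
    diurnality = sample(c("diurnal", "non_diurnal"), n, TRUE),
    worker_size = runif(n, 1, 15),
    stringsAsFactors = FALSE
  )
}

random_trait_pool <- function(n, seed = 1) {
  trait_table(random_trait_df(n, seed), ant_trait_schema())
}

# Incidence matrix from a named list of occupancy unit-id vectors.
occupancy_matrix <- function(occ, units, scale_label = "local", name = "fix",
                             warn = FALSE) {
  m <- matrix(0L, length(units), length(occ),
              dimnames = list(units, names(occ)))
  for (sp in names(occ)) m[occ[[sp]], sp] <- 1L
  occurrence_matrix(m, scale_label = scale_label, name = name, warn = warn)
}

random_incidence <- function(n_units, n_species, p = 0.4, seed = 1,
                             scale_label = "local", name = "rand") {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_units * n_species, 1, p), n_units, n_species,
                dimnames = list(sprintf("u%03d", seq_len(n_units)),
                                sprintf("sp%03d", seq_len(n_species))))
    if (all(colSums(m) > 0)) break   # keep every species so pair counts are fixed
  }
  occurrence_matrix(m, scale_label = scale_label, name = name, warn = FALSE)
}

# Hand-built pair table (bypasses pairwise_jaccard) for model-fitting tests
# where ji values are chosen analytically.
manual_pair_table <- function(ji, name = "manual", scale_label = "local",
                              species_a = NULL, species_b = NULL) {
  n <- length(ji)
  if (is.null(species_a)) {
    sp <- sprintf("sp%03d", seq_len(ceiling((1 + sqrt(1 + 8 * n)) / 2)))
    idx <- which(upper.tri(diag(length(sp))), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][seq_len(n), , drop = FALSE]
    species_a <- sp[idx[, 1]]
    species_b <- sp[idx[, 2]]
  }
  structure(
    data.frame(species_a = species_a, species_b = species_b,
               A = NA_integer_, B = NA_integer_, AB = NA_integer_,
               ji = ji, cooccurs = as.integer(ji > 0), stringsAsFactors = FALSE),
    matrix_name = name, scale_label = scale_label,
    n_pairs = n, n_zero = sum(ji == 0),
    class = c("pair_table", "data.frame"))
}

# Matching hand-built dissimilarity table carrying one trait set.
manual_dissim <- function(pairs, values, trait_set = "all_traits") {
  out <- data.frame(species_a = pairs$species_a, species_b = pairs$species_b,
                    stringsAsFactors = FALSE)
  out[[trait_set]] <- values
  structure(out, class = c("dissimilarity_table", "data.frame"))
}
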