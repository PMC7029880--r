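# A small fully pinned pool: worker sizes 2 and 10 fix the pooled range so
# single-trait components are exact fractions.
pinned_pool <- function() {
  trait_table(data.frame(
    species = c("lo", "hi", "p1", "p2"),
    n_queens = c("monogynous", "monogynous", "monogynous", "polygynous"),
    colony_size = exp(c(4, 8, 5, 7)),
    brood_cycle = c("seasonal", "seasonal", "seasonal", "seasonal"),
    diet_seed = c(1, 1, 1, 0.5), diet_insect = c(0, 0, 0, 0.5),
    diet_liquid = c(0, 0, 0, 0),
    diurnality = c("diurnal", "diurnal", "diurnal", "non_diurnal"),
    worker_size = c(2, 10, 4, 6),
    stringsAsFactors = FALSE), ant_trait_schema())
}

test_that("pooled quantitative ranges are recorded once and reused", {
  pool <- pinned_pool()
  ctx <- gower_context(pool)
  expect_equal(ctx$ranges$worker_size, c(2, 10))
  expect_equal(ctx$ranges$colony_size, c(4, 8))
})

test_that("a constant quantitative trait is rejected (zero range)", {
  df <- random_trait_df(6, seed = 2)
  df$worker_size <- 5
  pool <- trait_table(df, ant_trait_schema())
  expect_error(gower_context(pool), class = "tc_computation_error")
})

test_that("single components follow the stated rules and sets average them", {
  pool <- pinned_pool()
  ctx <- gower_context(pool)
  # worker size 4 vs 6 over pooled range (2, 10)
  expect_equal(pair_dissimilarity("p1", "p2", "worker_size", ctx, pool), 0.25)
  # categorical mismatch is a full step
  expect_equal(pair_dissimilarity("p1", "p2", "diurnality", ctx, pool), 1)
  # fuzzy diet: half Manhattan distance over proportions
  expect_equal(pair_dissimilarity("p1", "p2", "diet", ctx, pool), 0.5)
  # niche group: unweighted mean of its three singles
  expect_equal(pair_dissimilarity("p1", "p2", "niche", ctx, pool),
               mean(c(0.25, 1, 0.5)))
  # range endpoints give the maximal quantitative component
  expect_equal(pair_dissimilarity("lo", "hi", "worker_size", ctx, pool), 1)
  # identical trait vectors give zero everywhere
  for (ts in trait_sets()) {
    expect_equal(pair_dissimilarity("lo", "lo", ts, ctx, pool), 0)
  }
})

test_that("all nine trait sets match the independently coded oracle", {
  for (seed in 1:6) {
    pool <- random_trait_pool(12, seed = seed)
    ctx <- gower_context(pool)
    tab <- pair_dissimilarities(ctx, pool)
    pick <- sample(nrow(tab), 20)
    for (k in pick) {
      want <- oracle_gower_pair(pool, tab$species_a[k], tab$species_b[k])
      got <- unlist(tab[k, names(want)])
      expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("values are symmetric, bounded, and decompose into single-trait means", {
  pool <- random_trait_pool(15, seed = 9)
  ctx <- gower_context(pool)
  tab <- pair_dissimilarities(ctx, pool)
  sets <- trait_sets()
  expect_true(all(as.matrix(tab[sets]) >= 0 & as.matrix(tab[sets]) <= 1))
  schema <- ant_trait_schema()
  expect_equal(tab$all_traits, unname(rowMeans(tab[schema$trait])),
               tolerance = 1e-12)
  expect_equal(tab$tolerance,
               unname(rowMeans(tab[schema$trait[schema$group == "tolerance"]])),
               tolerance = 1e-12)
  expect_equal(tab$niche,
               unname(rowMeans(tab[schema$trait[schema$group == "niche"]])),
               tolerance = 1e-12)
  # symmetry via the scalar interface
  expect_equal(pair_dissimilarity("sp003", "sp011", "all_traits", ctx, pool),
               pair_dissimilarity("sp011", "sp003", "all_traits", ctx, pool))
})

test_that("a pool-built context yields identical values on any species subset", {
  pool <- random_trait_pool(30, seed = 4)
  ctx <- gower_context(pool)
  full <- pair_dissimilarities(ctx, pool)
  sub_species <- sort(pool$species[c(2, 5, 9, 14, 22, 27)])
  sub <- pair_dissimilarities(ctx, pool, species = sub_species)
  key_full <- paste(full$species_a, full$species_b)
  key_sub <- paste(sub$species_a, sub$species_b)
  for (ts in trait_sets()) {
    expect_equal(sub[[ts]], full[[ts]][match(key_sub, key_full)], tolerance = 1e-12)
  }
  # and the context itself is untouched by subset scoring
  expect_identical(ctx$ranges, gower_context(pool)$ranges)
})

test_that("unknown species or trait sets raise lookup errors", {
  pool <- random_trait_pool(5, seed = 1)
  ctx <- gower_context(pool)
  expect_error(pair_dissimilarity("ghost", "sp001", "niche", ctx, pool),
               class = "tc_lookup_error")
  expect_error(pair_dissimilarity("sp001", "sp002", "charisma", ctx, pool),
               class = "tc_lookup_error")
})

test_that("the correlation screen flags duplicates and handles degenerate columns", {
  # duplicated quantitative trait: r = 1, flagged
  schema <- trait_schema(c("t1", "t2"), rep("quantitative", 2),
                         c("tolerance", "niche"))
  set.seed(1)
  v <- rnorm(20)
  tt <- trait_table(data.frame(species = sprintf("s%02d", 1:20), t1 = v, t2 = v),
                    schema)
  scr <- trait_correlation_screen(tt)
  expect_equal(scr$r, 1)
  expect_true(scr$flagged)

  # orthogonal +-1 contrasts: r = 0, unflagged
  tt2 <- trait_table(data.frame(species = sprintf("s%d", 1:4),
                                t1 = c(-1, -1, 1, 1), t2 = c(-1, 1, -1, 1)),
                     schema)
  scr2 <- trait_correlation_screen(tt2)
  expect_equal(scr2$r, 0)
  expect_false(scr2$flagged)

  # zero-variance column: correlation undefined, reported as NA not dropped
  tt3 <- trait_table(data.frame(species = sprintf("s%d", 1:5),
                                t1 = 1:5, t2 = rep(2, 5)), schema)
  scr3 <- trait_correlation_screen(tt3)
  expect_true(is.na(scr3$r))
  expect_false(scr3$flagged)

  expect_error(trait_correlation_screen(tt3[1:2, ]), class = "tc_computation_error")
})

test_that("independently generated trait columns rarely reach the 0.7 flag threshold", {
  flags <- vapply(1:10, function(seed) {
    pool <- random_trait_pool(155, seed = 100 + seed)
    sum(trait_correlation_screen(pool)$flagged, na.rm = TRUE)
  }, 0)
  # diet components are negatively coupled by the unit-sum constraint but
  # below 0.7 in absolute value for these concentrations; everything else is
  # independent, so flags should be rare overall
  expect_lt(mean(flags), 1)
  expect_equal(median(flags), 0)
})
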