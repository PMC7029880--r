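# Independent oracles, deliberately coded against the definitions rather
# than the package internals: explicit set operations for co-occurrence,
# elementwise loops for Gower, Newton-Raphson IRLS for the logistic slope,
# textbook closed forms for OLS.

# Jaccard counts per pair from occupancy sets.
oracle_jaccard <- function(x) {
  sp <- sort(colnames(x))
  out <- NULL
  for (a in seq_along(sp)) {
    for (b in seq_along(sp)) {
      if (b <= a) next
      units_a <- rownames(x)[x[, sp[a]] == 1]
      units_b <- rownames(x)[x[, sp[b]] == 1]
      ab <- length(intersect(units_a, units_b))
      a_only <- length(setdiff(units_a, units_b))
      b_only <- length(setdiff(units_b, units_a))
      out <- rbind(out, data.frame(
        species_a = sp[a], species_b = sp[b],
        A = a_only, B = b_only, AB = ab,
        ji = ab / (a_only + b_only + ab),
        stringsAsFactors = FALSE))
    }
  }
  out
}

# Nine Gower values for one species pair of a six-trait ant table whose
# colony_size column already holds log values. Ranges are taken over the
# full table (the pool).
oracle_gower_pair <- function(tab, a, b) {
  ra <- tab[tab$species == a, ]
  rb <- tab[tab$species == b, ]
  rng_cs <- range(tab$colony_size)
  rng_ws <- range(tab$worker_size)
  d <- c(
    n_queens = as.numeric(ra$n_queens != rb$n_queens),
    colony_size = abs(ra$colony_size - rb$colony_size) / diff(rng_cs),
    brood_cycle = as.numeric(ra$brood_cycle != rb$brood_cycle),
    diet = 0.5 * (abs(ra$diet_seed - rb$diet_seed) +
                    abs(ra$diet_insect - rb$diet_insect) +
                    abs(ra$diet_liquid - rb$diet_liquid)),
    diurnality = as.numeric(ra$diurnality != rb$diurnality),
    worker_size = abs(ra$worker_size - rb$worker_size) / diff(rng_ws)
  )
  c(all_traits = mean(d),
    tolerance = mean(d[c("n_queens", "colony_size", "brood_cycle")]),
    niche = mean(d[c("diet", "diurnality", "worker_size")]),
    d)
}

# Logistic regression slope by Newton-Raphson on the score equations.
oracle_irls_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  se <- sqrt(diag(solve(crossprod(X * (mu * (1 - mu)), X))))
  list(coef = unname(beta), se = unname(se), z = unname(beta / se))
}

# Textbook OLS slope and its t statistic.
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (sum(x * y) - n * mean(x) * mean(y)) / (sum(x^2) - n * mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  list(slope = slope, intercept = intercept, se = se, t = slope / se,
       p = 2 * stats::pt(abs(slope / se), n - 2, lower.tail = FALSE))
}
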