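# Independent oracles used across the suite. These are deliberately
# written from first principles (loops, grids, direct formula
# translations) and never call the package code paths they check.

# Exhaustive Marginal Value Theorem solution: accumulate volumes one
# reward at a time and maximise the average rate including travel time.
oracle_policy <- function(cod, initial = 150, factor = 0.8, iri = 4,
                          n_max = 100) {
  vol <- initial
  total <- 0
  rates <- numeric(n_max)
  for (n in seq_len(n_max)) {
    total <- total + vol
    rates[n] <- total / (cod + iri * (n - 1))
    vol <- vol * factor
  }
  n_star <- which(rates == max(rates))[1]
  list(n_star = n_star,
       rejection = initial * factor^n_star,
       rates = rates)
}

# Closed-form rejection volume of a deterministic threshold agent: the
# first (largest) scheduled volume strictly below the leave threshold.
oracle_rejection <- function(threshold, initial = 150, factor = 0.8) {
  vol <- initial
  repeat {
    if (vol < threshold) return(vol)
    vol <- vol * factor
  }
}

# Direct transcription of the published z-procedure for two dependent
# overlapping correlations (Fisher transforms, mean squared correlation,
# capped heteroscedasticity factor), kept textually independent of the
# package implementation.
oracle_meng_z <- function(ry1, ry2, rx, n) {
  zf <- function(r) 0.5 * log((1 + r) / (1 - r))
  r2bar <- mean(c(ry1^2, ry2^2))
  f <- (1 - rx) / (2 * (1 - r2bar))
  if (f > 1) f <- 1
  h <- (1 - f * r2bar) / (1 - r2bar)
  (zf(ry1) - zf(ry2)) * sqrt((n - 3) / (2 * (1 - rx) * h))
}

# Brute-force discount-rate estimate: log-spaced grid search of the
# anchored-hyperbola residual sum of squares.
oracle_grid_k <- function(b, A, delays, points, grid = NULL) {
  if (is.null(grid)) grid <- exp(seq(log(1e-4), log(10), length.out = 20000))
  rss <- vapply(grid, function(k)
    sum((points - b * A / (1 + k * delays))^2), numeric(1))
  grid[which.min(rss)]
}

# Convenience: a deterministic hyperbolic-discounter rat.
det_hyperbolic_rat <- function(id = "r1", sex = "male", k = 0.02, b = 0.7,
                               weight = 0.4) {
  rat_record(id, sex, weight,
             agent_policy("hyperbolic_discounter", k = k, b = b))
}
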