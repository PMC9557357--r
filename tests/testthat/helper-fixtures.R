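# Shared fixtures and independent oracles used across the suite.

small_sim <- function(seed = 11, n = 400, ...) {
  simulate_sage(sim_config(n_households = n, seed = seed, ...))
}

fast_settings <- function(seed = 1) {
  cause_settings(num_trees = 100, seed = seed)
}

# A generator configuration with no covariate effects on costs: the only
# systematic cost contrast is the planted NCD-vs-CD offset.
flat_cost_config <- function(n_households, seed, ncd_cost_ratio = 1.6, ...) {
  sim_config(
    n_households = n_households, seed = seed, ncd_cost_ratio = ncd_cost_ratio,
    cause_covariate_strength = 0, cause_concentration = 0,
    cost_params = list(beta_age = 0, beta_urban = 0, beta_educ = 0,
                       beta_female = 0, beta_wealth = 0,
                       sdlog = c(outpatient = 1.0, inpatient = 1.0)),
    ...)
}

# Brute-force subsistence-line oracle: explicit loop over the sorted
# households, including each whole household whose weight interval overlaps
# the percentile band.
oracle_food_line <- function(food, size, w, beta, band = c(0.45, 0.55)) {
  v <- food / size^beta
  o <- order(v)
  v <- v[o]; w <- w[o]
  total <- sum(w)
  acc <- 0
  num <- 0; den <- 0
  for (i in seq_along(v)) {
    lo_i <- acc / total
    acc <- acc + w[i]
    hi_i <- acc / total
    if (hi_i > band[1] && lo_i < band[2]) {
      num <- num + v[i] * w[i]
      den <- den + w[i]
    }
  }
  num / den
}

# Exhaustive minimum-cardinality crossing-subset oracle (<= 20 visits).
oracle_min_visits <- function(costs, threshold) {
  n <- length(costs)
  stopifnot(n <= 20)
  best <- Inf
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) >= best) next
    if (sum(costs[members]) > threshold) best <- length(members)
  }
  best
}

# Direct re-statement of the attribution rule for share vectors.
oracle_attribution <- function(shares, cutoff = 0.75) {
  if (sum(shares) == 0) return("UNALLOCABLE")
  shares <- shares / sum(shares)
  cats <- c("NCD", "CD", "INJURY")
  hit <- which(shares > cutoff)
  if (length(hit) == 1) cats[hit] else "UNALLOCABLE"
}

# Hand-rolled one-way cluster sandwich (Stata-style adjustment).
oracle_cluster_vcov <- function(X, y, cluster) {
  fit <- lm.fit(X, y)
  e <- y - X %*% fit$coefficients
  G <- length(unique(cluster))
  N <- nrow(X); K <- ncol(X)
  meat <- matrix(0, K, K)
  for (g in unique(cluster)) {
    Xg <- X[cluster == g, , drop = FALSE]
    s <- t(Xg) %*% e[cluster == g]
    meat <- meat + s %*% t(s)
  }
  bread <- solve(t(X) %*% X)
  (G / (G - 1)) * ((N - 1) / (N - K)) * bread %*% meat %*% bread
}
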