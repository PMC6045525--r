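# Brute-force oracles and small builders shared across the suite.

# Direct evaluation of the mixture probability of one pattern by explicit
# loops over classes and observed items (no logs, no matrix algebra).
brute_pattern_prob <- function(gamma, rho, pattern) {
  total <- 0
  for (c in seq_along(gamma)) {
    term <- gamma[c]
    for (j in seq_along(pattern)) {
      if (is.na(pattern[j])) next
      term <- term * if (pattern[j] == 1) rho[c, j] else 1 - rho[c, j]
    }
    total <- total + term
  }
  as.numeric(total)
}

brute_loglik <- function(gamma, rho, items) {
  ll <- 0
  for (i in seq_len(nrow(items))) {
    if (all(is.na(items[i, ]))) next
    ll <- ll + log(brute_pattern_prob(gamma, rho, items[i, ]))
  }
  ll
}

brute_posterior <- function(gamma, rho, pattern) {
  num <- vapply(seq_along(gamma), function(c) {
    term <- gamma[c]
    for (j in seq_along(pattern)) {
      if (is.na(pattern[j])) next
      term <- term * if (pattern[j] == 1) rho[c, j] else 1 - rho[c, j]
    }
    term
  }, numeric(1))
  num / sum(num)
}

# All 2^J complete patterns, items varying as in pattern_table().
all_patterns <- function(J) {
  as.matrix(expand.grid(rep(list(c(0L, 1L)), J))[, J:1, drop = FALSE])
}

# Random valid parameter set (interior rho) under a seed.
random_params <- function(C, J, seed) {
  set.seed(seed)
  g <- rexp(C)
  lca_params(g / sum(g), matrix(runif(C * J, 0.05, 0.95), C, J))
}

# Random response matrix with optional missingness.
random_data <- function(n, J, seed, miss = 0) {
  set.seed(seed)
  items <- matrix(rbinom(n * J, 1L, 0.5), n, J)
  if (miss > 0) items[matrix(runif(n * J) < miss, n, J)] <- NA_integer_
  response_matrix(items)
}

# The two-class worked example used across likelihood/posterior tests:
# gamma = (0.4, 0.6), rho rows (0.9, 0.1) and (0.2, 0.8).
example_c2 <- function() {
  lca_params(c(0.4, 0.6), rbind(c(0.9, 0.1), c(0.2, 0.8)))
}
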