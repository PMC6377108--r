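# Independent oracles and fixture builders used across the suite.

# unit-scale Frechet CDF used by oracles (independent of the package's
# kernel implementation)
oracle_frechet_cdf <- function(d_prime, eta) {
  ifelse(d_prime > 0, exp(-d_prime^(-eta)), 0)
}

# brute-force inclusion-exclusion over all non-empty pathway subsets, with
# the joint sufficiency probability of a subset equal to the product of its
# marginals (independence)
oracle_union_response <- function(d_prime, eta) {
  I <- length(d_prime)
  marg <- oracle_frechet_cdf(d_prime, eta)
  total <- 0
  for (size in seq_len(I)) {
    subsets <- utils::combn(I, size, simplify = FALSE)
    for (s in subsets) {
      total <- total + (-1)^(size + 1) * prod(marg[s])
    }
  }
  total
}

# exhaustive grid-search maximizer of the binomial log-likelihood (with
# the same adjusted counts the deviance uses), for small 2-parameter
# Frechet instances
oracle_grid_ml <- function(data, xi_grid, eta_grid, adjust = TRUE) {
  n <- if (adjust) adjust_counts(data$n, data$N) else data$n
  N <- data$N
  d <- data[[stressor_names(data)[1]]]
  best <- list(ll = -Inf, xi = NA, eta = NA)
  for (xi in xi_grid) {
    for (eta in eta_grid) {
      p <- pmin(pmax(oracle_frechet_cdf(d / xi, eta), 1e-12), 1 - 1e-12)
      ll <- sum(n * log(p) + (N - n) * log(1 - p))
      if (ll > best$ll) best <- list(ll = ll, xi = xi, eta = eta)
    }
  }
  best
}

# quantal fixture from a known single-stressor Frechet truth
make_frechet_fixture <- function(seed, N = 500,
                                 doses = c(0.3, 0.5, 0.7, 0.9, 1.2, 1.6, 2.2, 3.0),
                                 xi = 1, eta = 2) {
  simulate_quantal(frechet_drf(xi = xi, eta = eta), doses, N = N, seed = seed)
}

# Table-style published parameter sets used in closed-form checks
tbl_chloroform_cmb <- list(d_b = 0.7886, xi = 1.1711, eta = 5.3731)
tbl_benzene_toluene_cm <- list(xi = c(benzene = 3, toluene = 30),
                               xi_int = c("1_2" = -0.095), eta = 1, d0 = 4.2)
tbl_benzene_toluene_dm <- list(xi = c(benzene = 6, toluene = 30),
                               eta = c(1, 1), d0 = c(10, 125))
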