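# Independent oracles and tiny fixture builders used across test files.

# Cliff's delta straight from its definition via the full pairwise sign matrix.
cliffs_delta_outer <- function(x1, x2) mean(sign(outer(x1, x2, "-")))

# Gaussian twin-pair log-likelihood summed pair by pair with solve(),
# independent of the package's chol-based paths.
loglik_oracle <- function(data, A, C, E, mu) {
  mu2 <- c(mu, mu)
  ll <- 0
  for (z in c("MZ", "DZ")) {
    x <- if (z == "MZ") data$mz else data$dz
    S <- implied_covariance(A, C, E, z)
    Si <- solve(S)
    ld <- determinant(S, logarithm = TRUE)$modulus
    for (r in seq_len(nrow(x))) {
      d <- x[r, ] - mu2
      ll <- ll - 0.5 * (length(mu2) * log(2 * pi) + ld + drop(d %*% Si %*% d))
    }
  }
  as.numeric(ll)
}

# 3-pair cohort used by the reader/validator tests.
tiny_cohort <- function() {
  cohort(subject_id = paste0("S", 1:6),
         pair_id = rep(c("MZ1", "MZ2", "DZ1"), each = 2),
         zygosity = rep(c("MZ", "MZ", "DZ"), each = 2),
         age = rep(c(25, 30, 28), each = 2),
         sex = c("F", "F", "M", "F", "M", "M"))
}

# Small edge table with reproducible random values.
tiny_edges <- function(cohort, n_edges = 12, seed = 1, session = "REST1") {
  set.seed(seed)
  v <- matrix(rnorm(nrow(cohort) * n_edges), nrow(cohort), n_edges)
  rownames(v) <- cohort$subject_id
  edge_table(v, twinconn:::edge_node_pairs_for(n_edges), session = session)
}

# Simulate, add sessions, and return the pieces most tests need.
twin_scenario <- function(n_mz, n_dz, n_edges, a2, c2, noise_sd = 0.3, seed = 1,
                          beta_age = 0, beta_sex = 0) {
  coh <- generate_cohort(n_mz, n_dz, seed = seed)
  truth <- ace_truth(n_edges, a2 = a2, c2 = c2,
                     beta_age = beta_age, beta_sex = beta_sex)
  stable <- simulate_edge_phenotypes(coh, truth, seed = seed + 1)
  ses <- simulate_sessions(stable, noise_sd, seed = seed + 2)
  list(cohort = coh, truth = truth, stable = stable,
       rest1 = ses$rest1, rest2 = ses$rest2)
}
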