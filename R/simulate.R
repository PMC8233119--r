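#' Per-edge ACE ground truth
#'
#' Specifies, per edge, the standardized variance fractions of the additive
#' genetic (a2), shared environment (c2) and unique (e2) components, the
#' total phenotypic variance, linear age and sex effects, and the intercept.
#' Scalars are recycled across edges; fractions must be non-negative and sum
#' to 1 per edge.
#'
#' @param n_edges Number of edges.
#' @param a2,c2 Additive-genetic and shared-environment fractions.
#' @param e2 Unique fraction; defaults to `1 - a2 - c2`.
#' @param total_var Phenotypic variance (> 0).
#' @param beta_age Slope per year of age.
#' @param beta_sex Offset for male relative to female subjects.
#' @param mu0 Intercept.
#' @return An `ace_truth` data.frame with one row per edge.
#' @export
ace_truth <- function(n_edges, a2 = 0.3, c2 = 0.2, e2 = NULL, total_var = 1,
                      beta_age = 0, beta_sex = 0, mu0 = 0) {
  if (is.null(e2)) e2 <- 1 - a2 - c2
  x <- data.frame(a2 = rep_len(a2, n_edges), c2 = rep_len(c2, n_edges),
                  e2 = rep_len(e2, n_edges),
                  total_var = rep_len(total_var, n_edges),
                  beta_age = rep_len(beta_age, n_edges),
                  beta_sex = rep_len(beta_sex, n_edges),
                  mu0 = rep_len(mu0, n_edges))
  if (any(x$a2 < 0 | x$c2 < 0 | x$e2 < 0 | x$a2 > 1 | x$c2 > 1 | x$e2 > 1))
    stop("variance fractions must lie in [0, 1]")
  if (any(abs(x$a2 + x$c2 + x$e2 - 1) > 1e-12))
    stop("a2 + c2 + e2 must equal 1 per edge")
  if (any(x$total_var <= 0)) stop("total_var must be positive")
  class(x) <- c("ace_truth", "data.frame")
  x
}

#' Generate a synthetic twin cohort
#'
#' Twins share `pair_id`, zygosity and age; ages are drawn uniformly over
#' `age_range` per pair and sex is an independent fair coin per subject.
#' Deterministic under a fixed seed.
#'
#' @param n_mz_pairs,n_dz_pairs Pair counts (>= 1).
#' @param age_range Length-2 numeric, years.
#' @param seed Optional integer seed.
#' @return A `twin_cohort` with `2 * (n_mz_pairs + n_dz_pairs)` subjects.
#' @examples
#' coh <- generate_cohort(123, 67, seed = 1)
#' nrow(coh)  # 380
#' @export
generate_cohort <- function(n_mz_pairs, n_dz_pairs, age_range = c(22, 36),
                            seed = NULL) {
  if (n_mz_pairs < 1 || n_dz_pairs < 1) stop("need at least 1 pair of each zygosity")
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- n_mz_pairs + n_dz_pairs
  zyg <- rep(c("MZ", "DZ"), c(n_mz_pairs, n_dz_pairs))
  pair_ids <- sprintf("%s%04d", zyg, c(seq_len(n_mz_pairs), seq_len(n_dz_pairs)))
  ages <- stats::runif(n_pairs, age_range[1], age_range[2])
  n_subj <- 2L * n_pairs
  cohort(subject_id = sprintf("S%04d", seq_len(n_subj)),
         pair_id = rep(pair_ids, each = 2),
         zygosity = rep(zyg, each = 2),
         age = rep(ages, each = 2),
         sex = sample(c("F", "M"), n_subj, replace = TRUE))
}

#' Simulate edge phenotypes with known ACE structure
#'
#' For each pair and edge, an additive genetic factor G is identical within
#' MZ pairs; within DZ pairs each twin's G is `sqrt(1/2)` pair-common plus
#' `sqrt(1/2)` twin-unique, giving genetic correlation exactly 1/2 by
#' construction. The shared-environment factor C is identical within every
#' pair and the unique factor E is independent per subject. The phenotype is
#' `mu0 + beta_age * age + beta_sex * [sex == M] + sqrt(a2 v) G +
#' sqrt(c2 v) C + sqrt(e2 v) E`, so after covariate removal the within-pair
#' correlation converges to `a2 + c2` (MZ) and `a2/2 + c2` (DZ).
#'
#' @param cohort A `twin_cohort`.
#' @param truth An [ace_truth()] table, one row per edge.
#' @param seed Optional integer seed.
#' @return An `edge_table` of stable subject-level phenotypes (session tag
#'   `"stable"`); edges take the first `n_edges` canonical node pairs.
#' @export
simulate_edge_phenotypes <- function(cohort, truth, seed = NULL) {
  cohort <- validate_cohort(cohort)
  if (!inherits(truth, "ace_truth")) stop("`truth` must be an ace_truth table")
  if (!is.null(seed)) set.seed(seed)
  E <- nrow(truth)
  n <- nrow(cohort)
  pair_of <- match(cohort$pair_id, unique(cohort$pair_id))
  n_pairs <- max(pair_of)
  is_mz <- cohort$zygosity == "MZ"

  g_pair <- matrix(stats::rnorm(n_pairs * E), n_pairs, E)
  c_pair <- matrix(stats::rnorm(n_pairs * E), n_pairs, E)
  g_unique <- matrix(stats::rnorm(n * E), n, E)
  e_subj <- matrix(stats::rnorm(n * E), n, E)

  g <- g_pair[pair_of, , drop = FALSE]
  g[!is_mz, ] <- sqrt(0.5) * g[!is_mz, , drop = FALSE] +
    sqrt(0.5) * g_unique[!is_mz, , drop = FALSE]
  cc <- c_pair[pair_of, , drop = FALSE]

  sa <- sqrt(truth$a2 * truth$total_var)
  sc <- sqrt(truth$c2 * truth$total_var)
  se <- sqrt(truth$e2 * truth$total_var)
  y <- g * rep(sa, each = n) + cc * rep(sc, each = n) + e_subj * rep(se, each = n)
  y <- y + rep(truth$mu0, each = n) +
    outer(cohort$age, truth$beta_age) +
    outer(as.numeric(cohort$sex == "M"), truth$beta_sex)

  rownames(y) <- cohort$subject_id
  edge_table(y, edge_node_pairs_for(E), session = "stable")
}

# smallest node count whose lower triangle holds E edges; first E pairs
edge_node_pairs_for <- function(E) {
  n <- ceiling((1 + sqrt(1 + 8 * E)) / 2)
  utils::head(edge_node_pairs(n), E)
}

#' Simulate two noisy sessions around stable phenotypes
#'
#' Each session equals the stable subject-level value plus independent
#' zero-mean Gaussian noise of standard deviation `session_noise_sd`
#' (`0` gives identical sessions), emulating a two-day REST1/REST2 design.
#'
#' @param stable An `edge_table` of stable phenotypes.
#' @param session_noise_sd Noise SD (>= 0), in phenotype units.
#' @param seed Optional integer seed.
#' @return A list with `edge_table`s `rest1` and `rest2`.
#' @export
simulate_sessions <- function(stable, session_noise_sd, seed = NULL) {
  validate_edge_table(stable)
  if (session_noise_sd < 0) stop("session_noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(stable$values)
  r1 <- stable$values + matrix(stats::rnorm(prod(d), sd = session_noise_sd), d[1], d[2])
  r2 <- stable$values + matrix(stats::rnorm(prod(d), sd = session_noise_sd), d[1], d[2])
  list(rest1 = edge_table(r1, stable$edges, session = "REST1"),
       rest2 = edge_table(r2, stable$edges, session = "REST2"))
}

#' Simulate ROI time series with a target correlation structure
#'
#' Draws iid Gaussian time points and colours them with the symmetric square
#' root of the target correlation matrix, so the sample correlation of the
#' output converges to the target as the number of time points grows.
#'
#' @param target_corr Positive semidefinite correlation matrix (eigenvalues
#'   `>= -1e-8`).
#' @param n_timepoints Number of time points.
#' @param seed Optional integer seed.
#' @return Numeric matrix, time points x nodes.
#' @export
simulate_roi_timeseries <- function(target_corr, n_timepoints, seed = NULL) {
  target_corr <- validate_connectivity(target_corr)
  ev <- eigen(target_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop(sprintf("target correlation is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev$values)))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(target_corr)
  L <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(stats::rnorm(n_timepoints * p), n_timepoints, p)
  ts <- z %*% L
  colnames(ts) <- colnames(target_corr)
  ts
}

#' Build a synthetic parcellation from network sizes
#'
#' @param network_sizes Named integer vector: nodes per network, in node
#'   order (a `"unassigned"` name is allowed).
#' @return A `parcellation` with `sum(network_sizes)` nodes labelled
#'   `N001, N002, ...`.
#' @export
generate_parcellation <- function(network_sizes) {
  if (is.null(names(network_sizes)) || any(!nzchar(names(network_sizes))))
    stop("network_sizes must be a named vector")
  n <- sum(network_sizes)
  parcellation(node_id = sprintf("N%03d", seq_len(n)),
               network = rep(names(network_sizes), network_sizes))
}

#' Per-edge truth with network-specific heritability
#'
#' Assigns each within-network edge its network's variance fractions and
#' every remaining edge (between networks or touching unassigned nodes) the
#' `between` fractions, so network-wise heritability differences can be
#' emulated.
#'
#' @param parc A `parcellation`.
#' @param a2_by_network,c2_by_network Named numeric vectors keyed by network.
#' @param between Length-2 numeric `c(a2, c2)` for all other edges.
#' @param ... Passed to [ace_truth()] (`total_var`, `beta_age`, ...).
#' @return An `ace_truth` table over all `n(n-1)/2` canonical edges.
#' @export
ace_truth_by_network <- function(parc, a2_by_network, c2_by_network,
                                 between = c(a2 = 0.2, c2 = 0.1), ...) {
  parc <- validate_parcellation(parc)
  n <- n_nodes(parc)
  a2 <- rep(between[[1]], n_edges(n))
  c2 <- rep(between[[2]], n_edges(n))
  for (net in names(a2_by_network)) {
    pos <- network_edges(parc, net)
    a2[pos] <- a2_by_network[[net]]
    c2[pos] <- if (net %in% names(c2_by_network)) c2_by_network[[net]] else between[[2]]
  }
  ace_truth(n_edges(n), a2 = a2, c2 = c2, ...)
}
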