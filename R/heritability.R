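#' Default bootstrap iteration count
#'
#' The smallest multiple of 1,000 (with a floor of 1,000) such that
#' `iterations * subset_size >= 2 * n_edges`, i.e. every edge is expected to
#' be drawn at least twice: 8,000 for 35,778 edges, 12,000 for 55,278,
#' 1,000 for small networks.
#'
#' @param n_edges Number of edges available.
#' @param subset_size Edges per iteration.
#' @return Integer iteration count.
#' @export
default_iterations <- function(n_edges, subset_size = 10) {
  if (n_edges < 1 || subset_size < 1) stop("inputs must be positive")
  max(1000L, as.integer(ceiling(2 * n_edges / subset_size / 1000) * 1000))
}

#' Bootstrapped multivariate ACE heritability
#'
#' At each iteration, draws `subset_size` distinct edges uniformly at random
#' (draws are independent across iterations, so edges recur), fits the
#' multivariate ACE model to the twin pairs with those edges as phenotypes,
#' and records the mean of each component's standardized diagonal. With
#' `shuffle_zygosity = TRUE` the MZ/DZ labels are permuted across pairs
#' (pairs stay intact, group sizes preserved) before every fit, yielding the
#' zygosity-shuffled null distribution. Non-converged fits are redrawn and
#' logged; more than `max_redraw_frac` of failures aborts.
#'
#' @param edges A residualized, session-averaged `edge_table`.
#' @param cohort A `twin_cohort`.
#' @param subset_size Edges per iteration (default 10).
#' @param n_iterations Number of iterations; default [default_iterations()].
#' @param seed Optional integer seed.
#' @param shuffle_zygosity Permute zygosity labels each iteration (null).
#' @param max_redraw_frac Abort when redraws exceed this fraction of
#'   `n_iterations`.
#' @return A `boot_dist`: data.frame of per-iteration `h2`, `c2`, `e2`
#'   means, with attributes `type` (`"estimate"`/`"null"`), `subset_size`,
#'   `n_iterations`, `seed`, `n_redraws`.
#' @export
bootstrap_heritability <- function(edges, cohort, subset_size = 10,
                                   n_iterations = NULL, seed = NULL,
                                   shuffle_zygosity = FALSE,
                                   max_redraw_frac = 0.1) {
  validate_edge_table(edges); cohort <- validate_cohort(cohort)
  E <- ncol(edges$values)
  if (E < subset_size)
    stop(sprintf("only %d edges available for subset_size %d", E, subset_size))
  if (is.null(n_iterations)) n_iterations <- default_iterations(E, subset_size)
  if (!is.null(seed)) set.seed(seed)

  pidx <- pair_structure(cohort)
  v <- edges$values[match(cohort$subject_id, rownames(edges$values)), , drop = FALSE]
  two_p_all <- cbind(v[pidx$twin1, , drop = FALSE], v[pidx$twin2, , drop = FALSE])
  zyg0 <- pidx$zygosity

  h2 <- c2 <- e2 <- numeric(n_iterations)
  n_redraws <- 0L
  max_redraws <- ceiling(max_redraw_frac * n_iterations)
  it <- 1L
  while (it <= n_iterations) {
    sel <- sample.int(E, subset_size)
    zyg <- if (shuffle_zygosity) sample(zyg0) else zyg0
    dat <- paired_phenotypes(
      two_p_all[zyg == "MZ", c(sel, E + sel), drop = FALSE],
      two_p_all[zyg == "DZ", c(sel, E + sel), drop = FALSE])
    fit <- fit_ace(dat)
    if (!fit$converged) {
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws)
        stop(sprintf("more than %d%% of ACE fits failed to converge (%d redraws)",
                     round(100 * max_redraw_frac), n_redraws))
      message(sprintf("iteration %d: non-converged fit, redrawing edges", it))
      next
    }
    s <- standardize(fit)
    h2[it] <- mean(s$h2); c2[it] <- mean(s$c2); e2[it] <- mean(s$e2)
    it <- it + 1L
  }
  structure(data.frame(iteration = seq_len(n_iterations), h2 = h2, c2 = c2, e2 = e2),
            type = if (shuffle_zygosity) "null" else "estimate",
            subset_size = subset_size, n_iterations = n_iterations,
            seed = seed, n_redraws = n_redraws,
            class = c("boot_dist", "data.frame"))
}

#' @rdname bootstrap_heritability
#' @param ... Passed to [bootstrap_heritability()].
#' @export
null_distribution <- function(edges, cohort, ...) {
  bootstrap_heritability(edges, cohort, ..., shuffle_zygosity = TRUE)
}

#' Welch test of an estimate distribution against its null
#'
#' Unequal-variance two-sample t test of the per-iteration mean h2 values,
#' estimate vs null. Bootstrap iterations are not independent samples; the
#' test mirrors the field's usage and should be read as descriptive.
#'
#' @param estimate,null `boot_dist` objects (or data.frames with an `h2`
#'   column) of length >= 2 each.
#' @param component Which standardized component to compare.
#' @return List with `t`, `p_value`, `mean_estimate`, `mean_null`.
#' @export
compare_to_null <- function(estimate, null, component = "h2") {
  x <- estimate[[component]]; y <- null[[component]]
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 iterations per half")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p_value = 1,
                                        mean_estimate = mean(x), mean_null = mean(y)))
    stop("degenerate zero-variance distributions with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_estimate = mean(x), mean_null = mean(y))
}

#' Per-network bootstrapped heritability pipeline
#'
#' Chains the full analysis: average the two sessions, residualize age and
#' sex, subset each network's edges (both endpoints inside; `"whole-brain"`
#' uses every edge), and run the bootstrap estimate plus zygosity-shuffled
#' null with [default_iterations()] unless `n_iterations` is given.
#'
#' @param rest1,rest2 Session `edge_table`s over the full cohort.
#' @param cohort A `twin_cohort`.
#' @param parc A `parcellation` matching the edge tables' node indices.
#' @param networks Character vector of network names and/or `"whole-brain"`.
#' @param subset_size Edges per iteration.
#' @param n_iterations Optional fixed iteration count for all networks.
#' @param seed Integer master seed; each network consumes derived seeds.
#' @return A list with `distributions` (per network: `estimate`, `null`)
#'   and a `summary` data.frame (mean components, 2.5/97.5 bootstrap
#'   percentiles of h2, Welch t and p against the null).
#' @export
network_heritability <- function(rest1, rest2, cohort, parc, networks,
                                 subset_size = 10, n_iterations = NULL,
                                 seed = 1) {
  parc <- validate_parcellation(parc)
  unknown <- setdiff(networks, c(network_names(parc), "whole-brain"))
  if (length(unknown))
    stop("unknown network(s): ", paste(unknown, collapse = ", "))
  mean_edges <- residualize(average_sessions(rest1, rest2), cohort)
  dists <- list(); rows <- list()
  for (i in seq_along(networks)) {
    net <- networks[i]
    pos <- if (net == "whole-brain") seq_len(ncol(mean_edges$values))
           else network_edges(parc, net)
    sub <- subset_edges(mean_edges, pos)
    iters <- if (is.null(n_iterations)) default_iterations(length(pos), subset_size)
             else n_iterations
    est <- bootstrap_heritability(sub, cohort, subset_size, iters,
                                  seed = seed + 2L * i)
    nul <- null_distribution(sub, cohort, subset_size = subset_size,
                             n_iterations = iters, seed = seed + 2L * i + 1L)
    cmp <- compare_to_null(est, nul)
    ci <- stats::quantile(est$h2, c(0.025, 0.975), names = FALSE)
    dists[[net]] <- list(estimate = est, null = nul)
    rows[[i]] <- data.frame(network = net, n_edges = length(pos),
                            n_iterations = iters,
                            mean_h2 = mean(est$h2), h2_lo = ci[1], h2_hi = ci[2],
                            mean_c2 = mean(est$c2), mean_e2 = mean(est$e2),
                            null_mean_h2 = mean(nul$h2),
                            t = cmp$t, p_value = cmp$p_value)
  }
  list(distributions = dists, summary = do.call(rbind, rows))
}

#' Plot estimate and null heritability distributions
#'
#' Kernel-density display of the per-iteration mean h2 for the bootstrap
#' estimate (solid) and the zygosity-shuffled null (dashed).
#'
#' @param estimate,null `boot_dist` objects.
#' @param main Plot title.
#' @return Invisibly, `NULL`; draws on the current device.
#' @export
plot_heritability_distributions <- function(estimate, null, main = "Network heritability") {
  de <- stats::density(estimate$h2); dn <- stats::density(null$h2)
  graphics::plot(de, main = main, xlab = expression(mean~h^2),
                 xlim = range(de$x, dn$x), ylim = range(0, de$y, dn$y))
  graphics::lines(dn, lty = 2)
  graphics::legend("topright", legend = c("estimate", "null"), lty = c(1, 2), bty = "n")
  invisible(NULL)
}
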