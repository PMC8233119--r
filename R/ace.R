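#' Paired twin phenotypes
#'
#' Holds, per zygosity group, one row per twin pair: the first p columns are
#' twin 1's phenotype values and the last p columns twin 2's. This is the
#' input to the multivariate ACE fit. A rough identifiability advisory is
#' issued (not an error) when the pair count is small relative to the
#' 3 p(p+1)/2 + p free parameters.
#'
#' @param mz,dz Numeric matrices, pairs x 2p, for the MZ and DZ groups.
#' @return A `paired_phenotypes` object (`mz`, `dz`, `p`).
#' @export
paired_phenotypes <- function(mz, dz) {
  mz <- as.matrix(mz); dz <- as.matrix(dz)
  if (ncol(mz) != ncol(dz)) stop("MZ and DZ matrices must have the same width")
  if (ncol(mz) %% 2 != 0) stop("columns must be twin1 values followed by twin2 values (2p)")
  if (nrow(mz) == 0 || nrow(dz) == 0) stop("both zygosity groups must be non-empty")
  p <- ncol(mz) / 2
  n_par <- 3 * p * (p + 1) / 2 + p
  if ((nrow(mz) + nrow(dz)) * 2 * p < 2 * n_par)
    warning(sprintf("only %d pairs for %d free parameters; estimates may be unstable",
                    nrow(mz) + nrow(dz), n_par))
  structure(list(mz = mz, dz = dz, p = as.integer(p)), class = "paired_phenotypes")
}

#' Assemble paired phenotypes from an edge table
#'
#' Orders each pair's two subjects by their appearance in the cohort and
#' stacks the selected edges as twin1 values followed by twin2 values.
#'
#' @param edges An `edge_table` covering all cohort subjects.
#' @param cohort A `twin_cohort`.
#' @param positions Edge positions to use as phenotypes (default all).
#' @param zygosity Optional per-pair zygosity override (in cohort pair
#'   order), used by the zygosity-shuffled null.
#' @return A `paired_phenotypes` object.
#' @export
pair_edges <- function(edges, cohort, positions = NULL, zygosity = NULL) {
  validate_edge_table(edges); cohort <- validate_cohort(cohort)
  if (is.null(positions)) positions <- seq_len(ncol(edges$values))
  ids <- rownames(edges$values)
  if (!setequal(ids, cohort$subject_id))
    stop("edge table and cohort cover different subjects")
  pidx <- pair_structure(cohort)
  if (is.null(zygosity)) zygosity <- pidx$zygosity
  v <- edges$values[match(cohort$subject_id, ids), positions, drop = FALSE]
  two_p <- cbind(v[pidx$twin1, , drop = FALSE], v[pidx$twin2, , drop = FALSE])
  paired_phenotypes(two_p[zygosity == "MZ", , drop = FALSE],
                    two_p[zygosity == "DZ", , drop = FALSE])
}

# row indices of each pair's two twins (cohort order) and per-pair zygosity
pair_structure <- function(cohort) {
  ord <- order(match(cohort$pair_id, unique(cohort$pair_id)))
  rows <- matrix(ord, ncol = 2, byrow = TRUE)
  list(twin1 = rows[, 1], twin2 = rows[, 2],
       zygosity = cohort$zygosity[rows[, 1]])
}

#' Model-implied twin-pair covariance
#'
#' The 2p-by-2p covariance of a twin pair's stacked phenotypes under the
#' ACE model: diagonal blocks `V = A + C + E`, cross-twin blocks
#' `R = A + C` for MZ pairs and `R = A/2 + C` for DZ pairs (additive genetic
#' correlation 1 and 1/2 respectively).
#'
#' @param A,C,E Symmetric p x p variance-component matrices.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 2p x 2p matrix `[[V, R], [R, V]]`.
#' @export
implied_covariance <- function(A, C, E, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  A <- as.matrix(A); C <- as.matrix(C); E <- as.matrix(E)
  if (!all(dim(A) == dim(C)) || !all(dim(A) == dim(E)) || nrow(A) != ncol(A))
    stop("A, C, E must be symmetric matrices of identical dimension")
  V <- A + C + E
  R <- if (zygosity == "MZ") A + C else A / 2 + C
  rbind(cbind(V, R), cbind(R, V))
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

unvech <- function(v, p) {
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M), p)
}

# gradient of a scalar wrt vech(theta) given the full-matrix derivative H
vech_grad <- function(H) {
  G <- H + t(H)
  diag(G) <- diag(H)
  G[lower.tri(G, diag = TRUE)]
}

# per-group sufficient statistics: n, mean, scatter about the mean, and the
# cross-twin genetic weight k (1 for MZ, 1/2 for DZ)
suff_stats <- function(data) {
  lapply(list(mz = list(x = data$mz, k = 1), dz = list(x = data$dz, k = 0.5)),
         function(g) {
           n <- nrow(g$x); m <- colMeans(g$x)
           W <- crossprod(sweep(g$x, 2, m))
           list(n = n, m = m, W = W, k = g$k)
         })
}

# -2 log-likelihood and analytic gradient over par = c(mu, vechA, vechC, vechE).
# Non-positive-definite implied covariances contribute a smooth eigenvalue
# penalty instead of -Inf so quasi-Newton steps stay finite.
ace_objective <- function(par, stats, p, penalty_scale = 1e9) {
  q <- p * (p + 1) / 2
  mu <- par[seq_len(p)]
  A <- unvech(par[p + seq_len(q)], p)
  C <- unvech(par[p + q + seq_len(q)], p)
  E <- unvech(par[p + 2 * q + seq_len(q)], p)
  V <- A + C + E
  mu2 <- c(mu, mu)
  f2 <- 0
  gmu2 <- numeric(2 * p)
  HA <- matrix(0, p, p); HC <- HA; HE <- HA
  ip <- seq_len(p); jp <- p + seq_len(p)
  for (g in stats) {
    R <- g$k * A + C
    Sg <- rbind(cbind(V, R), cbind(R, V))
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    eps <- 1e-8
    if (is.null(ch)) {
      ev <- eigen(Sg, symmetric = TRUE)
      lmin <- ev$values[2 * p]
      v <- ev$vectors[, 2 * p]
      f2 <- f2 + penalty_scale * (eps - lmin)
      Hfull <- -penalty_scale * tcrossprod(v)      # d f2 / d Sigma
      SV <- Hfull[ip, ip] + Hfull[jp, jp]
      SR <- Hfull[ip, jp] + Hfull[jp, ip]
      HA <- HA + SV + g$k * SR
      HC <- HC + SV + SR
      HE <- HE + SV
      next
    }
    Si <- chol2inv(ch)
    d <- g$m - mu2
    Sid <- Si %*% d
    logdet <- 2 * sum(log(diag(ch)))
    f2 <- f2 + g$n * (2 * p * log(2 * pi) + logdet) +
      sum(Si * g$W) + g$n * sum(d * Sid)
    B <- g$W + g$n * tcrossprod(d)
    Hfull <- g$n * Si - Si %*% B %*% Si             # d f2 / d Sigma (full matrix)
    gmu2 <- gmu2 - 2 * g$n * Sid
    SV <- Hfull[ip, ip] + Hfull[jp, jp]
    SR <- Hfull[ip, jp] + Hfull[jp, ip]
    HA <- HA + SV + g$k * SR
    HC <- HC + SV + SR
    HE <- HE + SV
  }
  grad <- c(gmu2[ip] + gmu2[jp], vech_grad(HA), vech_grad(HC), vech_grad(HE))
  list(value = f2, grad = grad)
}

#' ACE model log-likelihood
#'
#' Sum over zygosity groups and pairs of the 2p-dimensional Gaussian
#' log-density with mean `c(mu, mu)` and the model-implied covariance of
#' [implied_covariance()]. The default path works from per-group sufficient
#' statistics; `method = "perpair"` sums per-pair densities directly and is
#' retained as an independent cross-check. Non-positive-definite implied
#' covariances give `-Inf`.
#'
#' @param data A `paired_phenotypes` object.
#' @param A,C,E Symmetric p x p component matrices.
#' @param mu Length-p mean vector.
#' @param method `"suffstat"` or `"perpair"`.
#' @return Scalar log-likelihood.
#' @export
ace_loglik <- function(data, A, C, E, mu, method = c("suffstat", "perpair")) {
  method <- match.arg(method)
  p <- data$p
  if (method == "suffstat") {
    par <- c(mu, vech(as.matrix(A)), vech(as.matrix(C)), vech(as.matrix(E)))
    st <- suff_stats(data)
    for (g in st) {
      Sg <- implied_covariance(A, C, E, if (g$k == 1) "MZ" else "DZ")
      if (inherits(tryCatch(chol(Sg), error = function(e) e), "error")) return(-Inf)
    }
    return(-ace_objective(par, st, p)$value / 2)
  }
  mu2 <- c(mu, mu)
  ll <- 0
  for (z in c("MZ", "DZ")) {
    x <- if (z == "MZ") data$mz else data$dz
    Sg <- implied_covariance(A, C, E, z)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    for (r in seq_len(nrow(x))) {
      d <- x[r, ] - mu2
      q <- sum(backsolve(ch, d, transpose = TRUE)^2)
      ll <- ll - 0.5 * (2 * p * log(2 * pi) + logdet + q)
    }
  }
  ll
}

#' Fit the multivariate ACE model by maximum likelihood
#'
#' Maximizes the Gaussian twin-pair likelihood over a shared mean vector and
#' the free elements of symmetric A, C, E matrices in a direct
#' variance-component parameterization: diagonal entries are unbounded, so
#' estimates (and zygosity-shuffled nulls) are zero-centered rather than
#' floored at zero. Optimization is quasi-Newton (L-BFGS-B with analytic
#' gradients) from `A = C = E = S/3` (S the pooled phenotypic covariance),
#' with one jittered restart if the first attempt fails to converge.
#'
#' @param data A `paired_phenotypes` object, or a precomputed
#'   `paired_stats` object from [paired_stats()].
#' @param maxit Iteration cap per optimizer attempt.
#' @param factr L-BFGS-B relative convergence tolerance factor.
#' @return An `ace_fit`: matrices `A`, `C`, `E`, mean `mu`, `loglik`,
#'   `converged`, `n_iter`.
#' @export
fit_ace <- function(data, maxit = 2000, factr = 1e4) {
  if (inherits(data, "paired_phenotypes")) {
    p <- data$p
    st <- suff_stats(data)
  } else if (inherits(data, "paired_stats")) {
    p <- data$p
    st <- data$stats
  } else stop("`data` must be paired_phenotypes or paired_stats")
  if (p < 1) stop("need at least one phenotype")
  ip <- seq_len(p); jp <- p + ip

  n_tot <- sum(vapply(st, `[[`, numeric(1), "n"))
  S <- matrix(0, p, p); mbar <- numeric(p)
  for (g in st) {   # pooled phenotypic covariance over individual twins
    S <- S + g$W[ip, ip] + g$W[jp, jp] +
      g$n * (tcrossprod(g$m[ip]) + tcrossprod(g$m[jp]))
    mbar <- mbar + g$n * (g$m[ip] + g$m[jp])
  }
  mbar <- mbar / (2 * n_tot)
  S <- S / (2 * n_tot) - tcrossprod(mbar)
  S <- (S + t(S)) / 2

  start <- c(mbar, rep(vech(S / 3), 3))
  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    o <- ace_objective(par, st, p)
    cache$par <- par; cache$grad <- o$grad
    o$value
  }
  gr <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$grad)
    ace_objective(par, st, p)$grad
  }
  attempt <- function(par0) {
    stats::optim(par0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = factr))
  }
  opt <- attempt(start)
  n_iter <- opt$counts[["function"]]
  if (opt$convergence != 0) {
    jitter <- stats::rnorm(length(start), sd = 0.05 * (abs(start) + 0.1))
    opt2 <- attempt(start + jitter)
    n_iter <- n_iter + opt2$counts[["function"]]
    if (opt2$value < opt$value || opt2$convergence == 0) opt <- opt2
  }
  q <- p * (p + 1) / 2
  out <- list(A = unvech(opt$par[p + seq_len(q)], p),
              C = unvech(opt$par[p + q + seq_len(q)], p),
              E = unvech(opt$par[p + 2 * q + seq_len(q)], p),
              mu = opt$par[seq_len(p)],
              loglik = -opt$value / 2,
              converged = opt$convergence == 0,
              n_iter = n_iter)
  class(out) <- "ace_fit"
  out
}

#' @export
print.ace_fit <- function(x, ...) {
  s <- standardize(x)
  cat(sprintf("<ace_fit> p=%d, loglik=%.3f, converged=%s\n",
              nrow(x$A), x$loglik, x$converged))
  cat("mean standardized components: h2=", round(mean(s$h2), 3),
      " c2=", round(mean(s$c2), 3), " e2=", round(mean(s$e2), 3), "\n", sep = "")
  invisible(x)
}

#' Build an ACE input from moment matrices
#'
#' Wraps per-group means and covariances as the sufficient statistics
#' consumed by [fit_ace()], e.g. to check self-consistency against
#' model-implied moments.
#'
#' @param p Phenotype count.
#' @param n_mz,n_dz Nominal pair counts.
#' @param cov_mz,cov_dz 2p x 2p covariance matrices (ML convention).
#' @param mean_mz,mean_dz Length-2p mean vectors (default zero).
#' @return A `paired_stats` object.
#' @export
paired_stats <- function(p, n_mz, cov_mz, n_dz, cov_dz,
                         mean_mz = numeric(2 * p), mean_dz = numeric(2 * p)) {
  structure(list(p = as.integer(p), stats = list(
    mz = list(n = n_mz, m = mean_mz, W = n_mz * cov_mz, k = 1),
    dz = list(n = n_dz, m = mean_dz, W = n_dz * cov_dz, k = 0.5))),
    class = "paired_stats")
}

#' Standardized variance fractions
#'
#' Per phenotype: `h2 = A_ii / V_ii`, `c2 = C_ii / V_ii`, `e2 = E_ii / V_ii`
#' with `V = A + C + E`; the three sum to 1 by construction.
#'
#' @param fit An `ace_fit`.
#' @return data.frame with columns `h2`, `c2`, `e2`, one row per phenotype.
#' @export
standardize <- function(fit) {
  V <- diag(fit$A + fit$C + fit$E)
  if (any(V <= 0)) stop("non-positive total variance; cannot standardize")
  data.frame(h2 = diag(fit$A) / V, c2 = diag(fit$C) / V, e2 = diag(fit$E) / V)
}

#' Falconer's closed-form variance decomposition
#'
#' `a2 = 2 (r_MZ - r_DZ)`, `c2 = 2 r_DZ - r_MZ`, `e2 = 1 - r_MZ` from the
#' two twin correlations — the classical closed form, used as an independent
#' oracle for the likelihood fit.
#'
#' @param r_mz,r_dz Twin correlations in `[-1, 1]`.
#' @return Named numeric vector `c(a2, c2, e2)`.
#' @export
falconer <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) stop("correlations must lie in [-1, 1]")
  c(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz, e2 = 1 - r_mz)
}

#' Univariate ACE fit
#'
#' Thin wrapper over [fit_ace()] at p = 1 for a single edge phenotype.
#'
#' @param mz,dz Pairs x 2 matrices of twin values per zygosity group.
#' @return An `ace_fit` with p = 1.
#' @export
fit_univariate <- function(mz, dz) fit_ace(paired_phenotypes(mz, dz))
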