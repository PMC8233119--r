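test_that("the implied twin-pair covariance has the biometric block structure", {
  one <- matrix(1, 1, 1)
  expect_equal(implied_covariance(one, one, one, "MZ"),
               rbind(c(3, 2), c(2, 3)))
  expect_equal(implied_covariance(one, one, one, "DZ"),
               rbind(c(3, 1.5), c(1.5, 3)))
  zero <- matrix(0, 1, 1)
  expect_equal(implied_covariance(zero, one, one, "MZ"),
               implied_covariance(zero, one, one, "DZ"))  # no genetic signal
  expect_error(implied_covariance(diag(2), diag(3), diag(2)), "dimension")
})

test_that("the log-likelihood matches the Gaussian density and twin-order symmetry", {
  # two pairs at the origin under A=C=0, E=1: each contributes -log(2*pi)
  dat0 <- suppressWarnings(paired_phenotypes(matrix(0, 1, 2), matrix(0, 1, 2)))
  z <- matrix(0, 1, 1); one <- matrix(1, 1, 1)
  ll <- ace_loglik(dat0, z, z, one, mu = 0, method = "perpair")
  expect_equal(ll, -2 * log(2 * pi))
  expect_equal(ace_loglik(dat0, z, z, one, mu = 0, method = "suffstat"), ll)

  set.seed(61)
  p <- 3
  A <- crossprod(matrix(rnorm(9), 3)) / 3
  C <- crossprod(matrix(rnorm(9), 3)) / 4
  E <- crossprod(matrix(rnorm(9), 3)) / 2 + diag(0.2, 3)
  mu <- rnorm(p)
  dat <- paired_phenotypes(matrix(rnorm(12 * 2 * p), 12), matrix(rnorm(9 * 2 * p), 9))
  l1 <- ace_loglik(dat, A, C, E, mu, method = "suffstat")
  l2 <- ace_loglik(dat, A, C, E, mu, method = "perpair")
  expect_equal(l1, l2, tolerance = 1e-8)
  expect_equal(l1, loglik_oracle(dat, A, C, E, mu), tolerance = 1e-8)

  swap <- paired_phenotypes(dat$mz[, c(p + 1:p, 1:p)], dat$dz[, c(p + 1:p, 1:p)])
  expect_equal(ace_loglik(swap, A, C, E, mu, method = "perpair"), l2)
  expect_equal(ace_loglik(swap, A, C, E, mu, method = "suffstat"), l1)

  # non-positive-definite implied covariance yields -Inf
  expect_identical(ace_loglik(dat0, -one, z, z, mu = 0, method = "perpair"), -Inf)
  expect_identical(ace_loglik(dat0, -one, z, z, mu = 0, method = "suffstat"), -Inf)
})

test_that("fitting the model to its own implied moments recovers the parameters", {
  A <- rbind(c(0.4, 0.1, 0.0), c(0.1, 0.3, 0.05), c(0.0, 0.05, 0.5))
  C <- diag(c(0.2, 0.2, 0.1))
  E <- diag(c(0.4, 0.5, 0.4))
  mu <- c(0.1, -0.2, 0)
  m2 <- c(mu, mu)
  ps <- paired_stats(3, 1e6, implied_covariance(A, C, E, "MZ"),
                     1e6, implied_covariance(A, C, E, "DZ"),
                     mean_mz = m2, mean_dz = m2)
  fit <- fit_ace(ps)
  expect_true(fit$converged)
  expect_equal(fit$A, A, tolerance = 1e-4)
  expect_equal(fit$C, C, tolerance = 1e-4)
  expect_equal(fit$E, E, tolerance = 1e-4)
  expect_equal(fit$mu, mu, tolerance = 1e-4)
})

test_that("exchangeable phenotype copies get exchangeable component diagonals", {
  # two copies of one edge phenotype, distinguished only by iid measurement
  # noise: by symmetry the fitted diagonals of each component must agree
  A <- matrix(0.4, 2, 2); C <- matrix(0.2, 2, 2)
  E <- matrix(0.4, 2, 2) + diag(0.2, 2)   # shared signal + copy-specific noise
  ps <- paired_stats(2, 1e5, implied_covariance(A, C, E, "MZ"),
                     1e5, implied_covariance(A, C, E, "DZ"))
  fit <- fit_ace(ps)
  expect_true(fit$converged)
  expect_equal(fit$A[1, 1], fit$A[2, 2], tolerance = 1e-4)
  expect_equal(fit$C[1, 1], fit$C[2, 2], tolerance = 1e-4)
  expect_equal(fit$E[1, 1], fit$E[2, 2], tolerance = 1e-4)

  # and on finite simulated data the symmetry holds within sampling error
  coh <- generate_cohort(400, 300, seed = 62)
  ph <- simulate_edge_phenotypes(coh, ace_truth(1, a2 = 0.4, c2 = 0.2), seed = 63)
  set.seed(64)
  v <- ph$values[, 1]
  dup <- cbind(v + rnorm(length(v), sd = 0.3), v + rnorm(length(v), sd = 0.3))
  pidx <- twinconn:::pair_structure(coh)
  two_p <- cbind(dup[pidx$twin1, ], dup[pidx$twin2, ])
  dat <- paired_phenotypes(two_p[pidx$zygosity == "MZ", ],
                           two_p[pidx$zygosity == "DZ", ])
  fit2 <- fit_ace(dat)
  s <- standardize(fit2)
  expect_equal(s$h2[1], s$h2[2], tolerance = 0.15)
})

test_that("standardized fractions divide the diagonals by total variance and sum to one", {
  fit <- structure(list(A = diag(c(0.4, 0)), C = diag(c(0.2, 0.3)),
                        E = diag(c(0.4, 0.7))), class = "ace_fit")
  s <- standardize(fit)
  expect_equal(s$h2, c(0.4, 0))
  expect_equal(s$h2 + s$c2 + s$e2, c(1, 1))
  set.seed(64)
  for (i in 1:20) {
    f <- structure(list(A = crossprod(matrix(rnorm(4), 2)),
                        C = crossprod(matrix(rnorm(4), 2)),
                        E = crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2)),
                   class = "ace_fit")
    ss <- standardize(f)
    expect_equal(ss$h2 + ss$c2 + ss$e2, c(1, 1), tolerance = 1e-8)
  }
  degenerate <- structure(list(A = diag(1) * -1, C = diag(1) * 0.2,
                               E = diag(1) * 0.3), class = "ace_fit")
  expect_error(standardize(degenerate), "total variance")
})

test_that("Falconer's closed form matches direct substitution", {
  expect_equal(falconer(0.6, 0.4), c(a2 = 0.4, c2 = 0.2, e2 = 0.4))
  expect_equal(falconer(0.5, 0.5), c(a2 = 0, c2 = 0.5, e2 = 0.5))
  expect_error(falconer(1.2, 0), "\\[-1, 1\\]")
})

test_that("univariate likelihood fits track Falconer's estimator at moderate n", {
  coh <- generate_cohort(500, 500, seed = 65)
  ph <- simulate_edge_phenotypes(coh, ace_truth(1, a2 = 0.5, c2 = 0.3), seed = 66)
  dat <- pair_edges(ph, coh)
  fit <- fit_univariate(dat$mz, dat$dz)
  expect_true(fit$converged)
  r_mz <- cor(dat$mz[, 1], dat$mz[, 2])
  r_dz <- cor(dat$dz[, 1], dat$dz[, 2])
  fal <- falconer(r_mz, r_dz)
  s <- standardize(fit)
  expect_equal(s$h2, unname(fal["a2"]), tolerance = 0.1 / fal["a2"], ignore_attr = TRUE)
  # the wrapper and the general fitter are the same model
  fit2 <- fit_ace(dat)
  expect_equal(standardize(fit2)$h2, s$h2, tolerance = 1e-4)
})
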