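test_that("generate_cohort builds valid twin cohorts deterministically", {
  coh <- generate_cohort(123, 67, seed = 5)
  expect_s3_class(coh, "twin_cohort")
  expect_equal(nrow(coh), 380)
  expect_identical(coh, generate_cohort(123, 67, seed = 5))
  # twins share pair id, zygosity and age
  by_pair <- split(coh, coh$pair_id)
  expect_true(all(vapply(by_pair, function(p) length(unique(p$age)) == 1, logical(1))))
  expect_true(all(coh$age >= 22 & coh$age <= 36))
  small <- generate_cohort(1, 1, seed = 1)
  expect_equal(nrow(small), 4)
  expect_equal(length(unique(small$pair_id)), 2)
  expect_error(generate_cohort(0, 1), "at least 1 pair")
})

test_that("perfect heritability makes MZ twins identical and pure noise makes them independent", {
  coh <- generate_cohort(10, 10, seed = 2)
  det <- simulate_edge_phenotypes(coh, ace_truth(5, a2 = 1, c2 = 0), seed = 3)
  pidx <- twinconn:::pair_structure(coh)
  mz <- pidx$zygosity == "MZ"
  expect_equal(det$values[pidx$twin1[mz], ], det$values[pidx$twin2[mz], ],
               ignore_attr = TRUE)

  coh2 <- generate_cohort(500, 2, seed = 4)
  ind <- simulate_edge_phenotypes(coh2, ace_truth(1, a2 = 0, c2 = 0), seed = 5)
  p2 <- twinconn:::pair_structure(coh2)
  mz2 <- p2$zygosity == "MZ"
  r <- cor(ind$values[p2$twin1[mz2], 1], ind$values[p2$twin2[mz2], 1])
  expect_lt(abs(r), 0.1)
})

test_that("within-pair correlations converge to a2+c2 (MZ) and a2/2+c2 (DZ)", {
  coh <- generate_cohort(2000, 2000, seed = 6)
  ph <- simulate_edge_phenotypes(coh, ace_truth(1, a2 = 0.4, c2 = 0.2), seed = 7)
  pidx <- twinconn:::pair_structure(coh)
  r_by <- function(z) {
    sel <- pidx$zygosity == z
    cor(ph$values[pidx$twin1[sel], 1], ph$values[pidx$twin2[sel], 1])
  }
  expect_equal(r_by("MZ"), 0.6, tolerance = 0.03 / 0.6)
  expect_equal(r_by("DZ"), 0.4, tolerance = 0.03 / 0.4)
})

test_that("phenotype generation is bit-reproducible and yields valid edge tables", {
  coh <- generate_cohort(5, 5, seed = 8)
  truth <- ace_truth(7, a2 = 0.3, c2 = 0.2, beta_age = 0.02, beta_sex = 0.1)
  a <- simulate_edge_phenotypes(coh, truth, seed = 9)
  b <- simulate_edge_phenotypes(coh, truth, seed = 9)
  expect_identical(a$values, b$values)
  expect_s3_class(validate_edge_table(a), "edge_table")
  expect_error(ace_truth(3, a2 = 0.5, c2 = 0.3, e2 = 0.3), "equal 1")
  expect_error(ace_truth(3, a2 = 0.9, c2 = 0.3), "\\[0, 1\\]")  # implied e2 < 0
  expect_error(ace_truth(3, a2 = -0.1, c2 = 0.3, e2 = 0.8), "\\[0, 1\\]")
})

test_that("session simulation adds independent noise around stable phenotypes", {
  coh <- generate_cohort(5, 5, seed = 10)
  stable <- simulate_edge_phenotypes(coh, ace_truth(6, a2 = 0.4, c2 = 0.2), seed = 11)
  same <- simulate_sessions(stable, 0, seed = 12)
  expect_identical(same$rest1$values, same$rest2$values)
  expect_identical(same$rest1$values, stable$values)
  expect_equal(same$rest1$session, "REST1")
  noisy <- simulate_sessions(stable, 100, seed = 13)
  r_self <- mean(diag(cor(t(noisy$rest1$values), t(noisy$rest2$values))))
  expect_lt(abs(r_self), 0.5)  # overwhelming noise kills cross-session similarity
  expect_error(simulate_sessions(stable, -1), ">= 0")
})

test_that("simulated ROI time series reproduce the target correlation", {
  idty <- diag(4)
  ts <- simulate_roi_timeseries(idty, 10000, seed = 14)
  off <- compute_fc(ts)[upper.tri(idty)]
  expect_true(all(abs(off) < 0.05))

  target <- matrix(c(1, 0.8, 0.8, 1), 2)
  ts2 <- simulate_roi_timeseries(target, 50000, seed = 15)
  expect_equal(cor(ts2)[1, 2], 0.8, tolerance = 0.02 / 0.8)
  expect_identical(ts2, simulate_roi_timeseries(target, 50000, seed = 15))

  non_psd <- matrix(c(1, 0.9, 0.9, 1), 2); non_psd[1, 2] <- non_psd[2, 1] <- 1.5
  expect_error(simulate_roi_timeseries(non_psd, 10), "\\[-1, 1\\]")
  singular_bad <- rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1)) # symmetric, unit diag, not PSD
  expect_error(simulate_roi_timeseries(singular_bad, 10), "positive semidefinite")
})

test_that("network-specific truth assigns fractions to the right edges", {
  parc <- generate_parcellation(c(visA = 4, moto = 3, unassigned = 2))
  truth <- ace_truth_by_network(parc, c(visA = 0.5, moto = 0.3),
                                c(visA = 0.1, moto = 0.2),
                                between = c(a2 = 0.05, c2 = 0.05))
  expect_equal(nrow(truth), n_edges(9))
  expect_true(all(truth$a2[network_edges(parc, "visA")] == 0.5))
  expect_true(all(truth$a2[network_edges(parc, "moto")] == 0.3))
  rest <- setdiff(seq_len(nrow(truth)),
                  c(network_edges(parc, "visA"), network_edges(parc, "moto")))
  expect_true(all(truth$a2[rest] == 0.05))
})
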