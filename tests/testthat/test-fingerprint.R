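test_that("similarity matrices hold Pearson correlations of vectorized connectomes", {
  coh <- tiny_cohort()
  et <- tiny_edges(coh, n_edges = 20, seed = 31)
  sim <- similarity_matrix(et, et)
  expect_equal(diag(unclass(sim)), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(sim >= -1 & sim <= 1))

  flipped <- et
  flipped$values <- -et$values + 3
  sim2 <- similarity_matrix(et, flipped)
  expect_equal(diag(unclass(sim2)), rep(-1, 6), ignore_attr = TRUE)

  flat <- et; flat$values[2, ] <- 7
  expect_error(similarity_matrix(flat, et), "S2")
  expect_error(similarity_matrix(subset_edges(et, 1:5), et), "edge indices differ")
})

test_that("individual identification is perfect on identical tables and near chance on noise", {
  coh <- generate_cohort(25, 25, seed = 32)
  et <- tiny_edges(coh, n_edges = 30, seed = 33)
  res <- identify_individuals(similarity_matrix(et, et))
  expect_identical(res$accuracy, 1)
  expect_equal(res$n_comparisons, 100 * 100)

  db <- tiny_edges(coh, n_edges = 30, seed = 34)  # independent of targets
  res2 <- identify_individuals(similarity_matrix(et, db))
  expect_lt(res2$accuracy, 0.15)                  # chance is 1/100
})

test_that("argmax ties are broken by first index with a warning", {
  coh <- tiny_cohort()
  et <- tiny_edges(coh, n_edges = 10, seed = 35)
  dup <- et
  dup$values[2, ] <- dup$values[1, ]  # two identical database connectomes
  expect_warning(res <- identify_individuals(similarity_matrix(et, dup)), "tie")
  expect_equal(res$predictions$predicted[1], "S1")
})

test_that("twin identification finds MZ twins exactly under perfect heritability", {
  sc <- twin_scenario(10, 10, 25, a2 = 1, c2 = 0, noise_sd = 0, seed = 36)
  sim <- similarity_matrix(sc$rest1, sc$rest2)
  res <- identify_twins(sim, sc$cohort, "MZ")
  expect_identical(res$accuracy, 1)
  expect_equal(res$n_comparisons, 20 * 40)

  dropped <- subset_edges(sc$rest2, seq_len(25))
  dropped$values <- dropped$values[-2, , drop = FALSE]  # remove S2 from database
  dropped <- edge_table(dropped$values, dropped$edges, dropped$session)
  expect_error(identify_twins(similarity_matrix(sc$rest1, dropped), sc$cohort, "MZ"),
               "S0001")
})

test_that("twin identification is near chance when phenotypes carry no genetic signal", {
  sc <- twin_scenario(20, 20, 40, a2 = 0, c2 = 0, noise_sd = 0.1, seed = 37)
  sim <- similarity_matrix(sc$rest1, sc$rest2)
  acc <- c(identify_twins(sim, sc$cohort, "MZ")$accuracy,
           identify_twins(sim, sc$cohort, "DZ")$accuracy)
  expect_true(all(acc < 0.25))  # chance is 1/79
})

test_that("session-combination averaging uses 2 combinations for individuals and 4 for twins", {
  sc <- twin_scenario(8, 8, 20, a2 = 0.5, c2 = 0.2, noise_sd = 0, seed = 38)
  ind <- mean_accuracy_over_combinations(sc$rest1, sc$rest2, "individual")
  expect_length(ind$accuracies, 2)
  expect_identical(ind$mean, 1)   # identical sessions: self-correlation is 1
  expect_identical(ind$sd, 0)
  tw <- mean_accuracy_over_combinations(sc$rest1, sc$rest2, "mz", sc$cohort)
  expect_length(tw$accuracies, 4)
  expect_true(tw$sd >= 0)
})

test_that("the twin permutation test gives reproducible add-one p-values in (0, 1]", {
  sc <- twin_scenario(15, 15, 30, a2 = 0.9, c2 = 0, noise_sd = 0.2, seed = 39)
  sim <- similarity_matrix(sc$rest1, sc$rest2)
  pt <- permutation_test_twin(sim, sc$cohort, "MZ", n_perm = 200, seed = 40)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  pt2 <- permutation_test_twin(sim, sc$cohort, "MZ", n_perm = 200, seed = 40)
  expect_identical(pt$permuted, pt2$permuted)
  # strong signal: observed accuracy beats (nearly) all permutations
  expect_lt(pt$p_value, 0.05)
  expect_error(permutation_test_twin(sim, sc$cohort, "MZ", n_perm = 0), ">= 1")
})

test_that("an observed accuracy of zero can never beat a permutation", {
  # engineer connectomes where each MZ target's best match is an unrelated subject
  coh <- tiny_cohort()
  set.seed(41)
  v <- matrix(rnorm(6 * 12), 6, 12, dimnames = list(coh$subject_id, NULL))
  v[5, ] <- v[1, ] + rnorm(12, sd = 1e-3)  # S1's argmax is S5 (a DZ subject)
  v[6, ] <- v[2, ] + rnorm(12, sd = 1e-3)
  et <- edge_table(v, twinconn:::edge_node_pairs_for(12))
  sim <- similarity_matrix(et, et)
  res <- identify_twins(sim, coh[coh$pair_id %in% c("MZ1", "DZ1"), ], "MZ")
  expect_identical(res$accuracy, 0)
  pt <- permutation_test_twin(sim, coh[coh$pair_id %in% c("MZ1", "DZ1"), ], "MZ",
                              n_perm = 50, seed = 42)
  expect_identical(pt$p_value, 1)
})

test_that("edge-subset curves report per-size accuracy and grow with subset size", {
  sc <- twin_scenario(12, 12, 60, a2 = 0.6, c2 = 0.2, noise_sd = 1.2, seed = 43)
  curve <- edge_subset_curve(sc$rest1, sc$rest2, sc$cohort,
                             sizes = c(5, 60), n_reps = 8, seed = 44)
  expect_equal(nrow(curve), 2 * 3)
  ind <- curve[curve$mode == "individual", ]
  expect_gte(ind$mean[ind$size == 60] + 2 * ind$sd[ind$size == 60] / sqrt(8),
             ind$mean[ind$size == 5])

  full <- edge_subset_curve(sc$rest1, sc$rest2, sc$cohort, sizes = 60,
                            n_reps = 1, seed = 45, modes = "individual")
  direct <- mean_accuracy_over_combinations(sc$rest1, sc$rest2, "individual")
  expect_equal(full$mean, direct$mean)
  expect_error(edge_subset_curve(sc$rest1, sc$rest2, sc$cohort, sizes = 61),
               "exceed")
  expect_length(eval(formals(edge_subset_curve)$sizes), 7)
})
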