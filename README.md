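# twinconn

Twin-based heritability and fingerprinting of functional connectomes.

`twinconn` is for researchers who study individual differences in
resting-state functional connectivity with twin designs. Given a cohort of
monozygotic (MZ) and dizygotic (DZ) twin pairs, each with ROI-to-ROI
connectivity matrices from two scanning sessions, the package answers
three questions:

1. **Connectome fingerprinting** — can a subject, or their twin, be
   identified across sessions as the database connectome with the maximal
   Pearson correlation to the target's vectorized connectivity matrix?
   Significance comes from a permutation test that shuffles twin-pair
   identities; accuracy curves over random edge subsets trace how much of
   the connectome is needed.
2. **Relatedness effect sizes** — similarity scores are grouped into
   same-individual (SI), MZ, DZ and unrelated (UN) cells and separations
   are quantified with Cliff's delta,
   `d = (#{x1 > x2} − #{x1 < x2}) / (n1 n2)`.
3. **Heritability** — edge connectivity is decomposed into additive
   genetic (A), shared environment (C) and unique (E) variance with a
   maximum-likelihood multivariate ACE model: a twin pair's stacked
   phenotypes are Gaussian with covariance `[[V, R], [R, V]]`, `V = A+C+E`
   and `R = A+C` (MZ) or `A/2+C` (DZ). A bootstrap repeatedly fits the
   model to random 10-edge subsets and averages the standardized
   diagonals (`h² = A_ii/V_ii`), giving a distribution of network
   heritability means; permuting MZ/DZ labels across pairs at every
   iteration yields the matching null distribution, centered at zero.

Because twin fMRI datasets of this kind are access-restricted, the package
includes a synthetic-cohort generator with exact ACE structure (MZ genetic
correlation 1, DZ ½), age/sex covariate effects and two-session noise, so
the entire pipeline runs — and is tested — against known ground truth.
See the methods vignette (`vignettes/twinconn-methods.Rmd`) for the model,
assumptions and numerical choices.

## Worked example

```r
library(twinconn)
coh    <- generate_cohort(n_mz_pairs = 60, n_dz_pairs = 40, seed = 1)
truth  <- ace_truth(150, a2 = 0.4, c2 = 0.2, beta_age = 0.01, beta_sex = 0.05)
stable <- simulate_edge_phenotypes(coh, truth, seed = 2)
ses    <- simulate_sessions(stable, session_noise_sd = 0.8, seed = 3)

# fingerprinting: MZ twin identification over all four session combinations
acc <- mean_accuracy_over_combinations(ses$rest1, ses$rest2, "mz", coh)
sim <- similarity_matrix(ses$rest1, ses$rest2)
pt  <- permutation_test_twin(sim, coh, "MZ", n_perm = 1000, seed = 4)

# effect size of MZ similarity against unrelated pairs
g <- group_scores(sim, coh)
d <- cliffs_delta(g$scores$MZ, g$scores$UN)

# bootstrapped heritability with zygosity-shuffled null
edges <- residualize(average_sessions(ses$rest1, ses$rest2), coh)
est <- bootstrap_heritability(edges, coh, subset_size = 10, n_iterations = 200, seed = 5)
nul <- null_distribution(edges, coh, subset_size = 10, n_iterations = 200, seed = 6)
cmp <- compare_to_null(est, nul)
```

This prints:

```
MZ twin identification accuracy: 0.948 (SD 0.004)
permutation p-value: 0.000999
Cliff's delta MZ vs UN: 0.999
mean h2: 0.312 (stable-connectome truth 0.4, diluted by session noise); null mean: 0.011; Welch t = 25.0, p = 3.84e-83
```

Reading the numbers: with strong genetic structure (`a2 = 0.4`) and
moderate session noise, 94.8% of MZ targets are matched to their co-twin,
far above the 1/199 chance level (add-one permutation p ≈ 0.001, the
smallest value 1,000 permutations can report). MZ similarity scores almost
completely dominate unrelated ones (delta near 1). The bootstrap recovers
a mean edge heritability of 0.31 — the stable-connectome truth of 0.40
diluted by the session noise that remains after averaging two sessions —
while the zygosity-shuffled null sits at 0.01, essentially zero.

A full configuration-driven run (simulate → fingerprint → effect size →
network heritability, with TSV/JSON outputs and a log) is available via

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "twinconn"),
             out_dir = "demo_out")
```

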