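#' Run the full analysis pipeline from a configuration
#'
#' One reproducible run chaining the stages: simulate a twin cohort with
#' known ACE structure (or read cohort/parcellation/edge tables from disk),
#' fingerprint (individual/MZ/DZ accuracies over session combinations, with
#' an optional permutation test), group similarity scores and compute
#' Cliff's deltas, and run the bootstrapped network heritability with its
#' zygosity-shuffled null. Every random draw derives from the master seed,
#' machine-readable summaries go to `summary.json`, and a run log records
#' versions, seeds and per-stage timing. Numeric outputs are byte-identical
#' across reruns of the same configuration.
#'
#' @param config A named list or the path of a YAML file. Recognized keys:
#'   `seed` (master seed, required), `out_dir`, `stages` (character subset
#'   of simulate/fingerprint/effect_size/heritability), `simulate` (a list:
#'   `n_mz_pairs`, `n_dz_pairs`, `network_sizes`, `a2_by_network`,
#'   `c2_by_network`, `between`, `beta_age`, `beta_sex`,
#'   `session_noise_sd`), `inputs` (paths `cohort`, `parcellation`,
#'   `edges_rest1`, `edges_rest2`; used when `"simulate"` is not requested),
#'   `fingerprint` (`n_perm`), `heritability` (`subset_size`,
#'   `n_iterations`, `networks`).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config must set a master `seed`")
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("config must set `out_dir` (or pass out_dir=)")
  stages <- cfg$stages %||% c("simulate", "fingerprint", "effect_size", "heritability")
  seed <- as.integer(cfg$seed)

  if (!"simulate" %in% stages) {
    paths <- unlist(cfg$inputs[c("cohort", "parcellation", "edges_rest1", "edges_rest2")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat(sprintf("twinconn %s | master seed %d\n",
              as.character(utils::packageVersion("twinconn")), seed),
      file = log_path)

  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))
    log_line("stage %-12s done in %.2f s", stage, proc.time()[["elapsed"]] - t0)
    out
  }
  summary <- list(seed = seed,
                  version = as.character(utils::packageVersion("twinconn")))

  if ("simulate" %in% stages) {
    sim_cfg <- cfg$simulate %||% list()
    sizes <- unlist(sim_cfg$network_sizes %||% c(netA = 8, netB = 8))
    parc <- generate_parcellation(sizes)
    coh <- generate_cohort(sim_cfg$n_mz_pairs %||% 30,
                           sim_cfg$n_dz_pairs %||% 30, seed = seed)
    truth <- ace_truth_by_network(
      parc,
      unlist(sim_cfg$a2_by_network %||% stats::setNames(rep(0.3, length(sizes)), names(sizes))),
      unlist(sim_cfg$c2_by_network %||% stats::setNames(rep(0.2, length(sizes)), names(sizes))),
      between = unlist(sim_cfg$between %||% c(a2 = 0.2, c2 = 0.1)),
      beta_age = sim_cfg$beta_age %||% 0.01,
      beta_sex = sim_cfg$beta_sex %||% 0.05)
    stable <- simulate_edge_phenotypes(coh, truth, seed = seed + 1L)
    ses <- simulate_sessions(stable, sim_cfg$session_noise_sd %||% 0.4,
                             seed = seed + 2L)
    rest1 <- ses$rest1; rest2 <- ses$rest2
    timed("simulate", {
      write_cohort(coh, file.path(out_dir, "cohort.tsv"))
      write_parcellation(parc, file.path(out_dir, "parcellation.tsv"))
      utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_edge_table(rest1, file.path(out_dir, "edges_rest1.tsv"))
      write_edge_table(rest2, file.path(out_dir, "edges_rest2.tsv"))
    })
    summary$simulate <- list(n_subjects = nrow(coh), n_edges = ncol(rest1$values))
  } else {
    coh <- read_cohort(cfg$inputs$cohort)
    parc <- read_parcellation(cfg$inputs$parcellation)
    rest1 <- read_edge_table(cfg$inputs$edges_rest1)
    rest2 <- read_edge_table(cfg$inputs$edges_rest2)
  }

  if ("fingerprint" %in% stages) {
    fp <- timed("fingerprint", {
      acc <- lapply(c(individual = "individual", mz = "mz", dz = "dz"),
                    function(m) mean_accuracy_over_combinations(rest1, rest2, m, coh))
      n_perm <- cfg$fingerprint$n_perm %||% 0
      perm <- if (n_perm > 0)
        permutation_test_twin(similarity_matrix(rest1, rest2), coh, "MZ",
                              n_perm = n_perm, seed = seed + 10L)
      list(acc = acc, perm = perm)
    })
    acc_df <- do.call(rbind, lapply(names(fp$acc), function(m)
      data.frame(mode = m, mean = fp$acc[[m]]$mean, sd = fp$acc[[m]]$sd)))
    utils::write.table(acc_df, file.path(out_dir, "fingerprint_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$fingerprint <- list(
      accuracy = stats::setNames(lapply(fp$acc, function(a)
        list(mean = a$mean, sd = a$sd)), names(fp$acc)))
    if (!is.null(fp$perm))
      summary$fingerprint$permutation_mz <- list(p_value = fp$perm$p_value,
                                                 observed = fp$perm$observed)
  }

  if ("effect_size" %in% stages) {
    es <- timed("effect_size", {
      grouped <- group_scores(similarity_matrix(rest1, rest2), coh)
      deltas <- lapply(c(SI = "SI", MZ = "MZ", DZ = "DZ"), function(g)
        cliffs_delta(grouped$scores[[g]], grouped$scores$UN))
      list(grouped = grouped, deltas = deltas)
    })
    jsonlite::write_json(list(counts = as.list(es$grouped$counts),
                              delta_vs_UN = es$deltas),
                         file.path(out_dir, "effect_size.json"),
                         auto_unbox = TRUE, digits = NA)
    summary$effect_size <- list(counts = as.list(es$grouped$counts),
                                delta_vs_UN = es$deltas)
  }

  if ("heritability" %in% stages) {
    h_cfg <- cfg$heritability %||% list()
    networks <- h_cfg$networks %||% c("whole-brain", network_names(parc))
    her <- timed("heritability", {
      network_heritability(rest1, rest2, coh, parc, networks,
                           subset_size = h_cfg$subset_size %||% 10,
                           n_iterations = h_cfg$n_iterations,
                           seed = seed + 100L)
    })
    utils::write.table(her$summary, file.path(out_dir, "heritability_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (net in names(her$distributions)) {
      d <- her$distributions[[net]]
      df <- rbind(cbind(set = "estimate", d$estimate), cbind(set = "null", d$null))
      utils::write.table(df, file.path(out_dir, paste0("heritability_", gsub("[^A-Za-z0-9]", "_", net), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$heritability <- lapply(seq_len(nrow(her$summary)), function(i)
      as.list(her$summary[i, ]))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("run complete; summary.json written")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
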