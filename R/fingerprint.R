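#' Target-by-database similarity matrix
#'
#' Entry (i, N) is the Pearson correlation over edges between target subject
#' i's vectorized connectome and database subject N's — the score used for
#' connectome fingerprinting.
#'
#' @param targets,database `edge_table`s with identical edge indices and at
#'   least 2 edges.
#' @return A `similarity_matrix`: numeric targets x database matrix with
#'   subject ids as dimnames and session tags as attributes.
#' @export
similarity_matrix <- function(targets, database) {
  validate_edge_table(targets); validate_edge_table(database)
  if (!identical(edge_labels(targets$edges), edge_labels(database$edges)))
    stop("target and database edge indices differ")
  if (ncol(targets$values) < 2) stop("need at least 2 edges")
  flag_flat <- function(x, which) {
    sds <- apply(x$values, 1, stats::sd)
    if (any(sds == 0))
      stop(sprintf("zero-variance connectome for %s subject(s): %s", which,
                   paste(rownames(x$values)[sds == 0], collapse = ", ")))
  }
  flag_flat(targets, "target"); flag_flat(database, "database")
  sim <- stats::cor(t(targets$values), t(database$values))
  structure(sim, class = c("similarity_matrix", class(sim)),
            session_target = targets$session, session_database = database$session)
}

new_identification <- function(df, accuracy, mode, n_comparisons) {
  structure(list(predictions = df, accuracy = accuracy, mode = mode,
                 n_comparisons = n_comparisons), class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> mode %s: accuracy %.4f over %d targets (%d comparisons)\n",
              x$mode, x$accuracy, nrow(x$predictions), x$n_comparisons))
  invisible(x)
}

# first-index argmax per row with a warning when the maximum is tied
row_argmax <- function(sim) {
  pred <- max.col(sim, ties.method = "first")
  n_ties <- rowSums(sim == sim[cbind(seq_len(nrow(sim)), pred)])
  if (any(n_ties > 1))
    warning(sprintf("tie at the maximum for %d target(s); first database index used",
                    sum(n_ties > 1)))
  pred
}

#' Individual identification by maximal correlation
#'
#' Predicts, for every target, the database subject with the maximal
#' similarity score; a prediction is correct when it names the target
#' itself. Ties are broken by first database index with a warning.
#'
#' @param sim A `similarity_matrix` whose target subjects all appear in the
#'   database.
#' @return An `identification_result` (accuracy, per-target predictions,
#'   `n_comparisons = targets x database`).
#' @export
identify_individuals <- function(sim) {
  missing <- setdiff(rownames(sim), colnames(sim))
  if (length(missing))
    stop("target subject(s) absent from database: ", paste(missing, collapse = ", "))
  pred <- colnames(sim)[row_argmax(unclass(sim))]
  df <- data.frame(target = rownames(sim), predicted = pred,
                   correct = pred == rownames(sim))
  new_identification(df, mean(df$correct), "individual", nrow(sim) * ncol(sim))
}

twin_map <- function(cohort) {
  split_ids <- split(cohort$subject_id, cohort$pair_id)
  twin <- unlist(lapply(split_ids, rev), use.names = FALSE)
  names(twin) <- unlist(split_ids, use.names = FALSE)
  twin
}

#' Twin identification by maximal correlation
#'
#' Restricts targets to subjects of the requested zygosity, masks each
#' target's own database column (the same-individual score), and predicts
#' the database argmax; a prediction is correct when it names the target's
#' pair partner. `n_comparisons` counts targets times the full database.
#'
#' @param sim A `similarity_matrix` over the full cohort.
#' @param cohort A `twin_cohort`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return An `identification_result` with mode `"mz"` or `"dz"`.
#' @export
identify_twins <- function(sim, cohort, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  cohort <- validate_cohort(cohort)
  twin <- twin_map(cohort)
  rows <- rownames(sim)[rownames(sim) %in% cohort$subject_id[cohort$zygosity == zygosity]]
  if (!length(rows)) stop("no targets of zygosity ", zygosity, " in the similarity matrix")
  absent <- rows[!twin[rows] %in% colnames(sim)]
  if (length(absent))
    stop("twin absent from database for subject(s): ", paste(absent, collapse = ", "))
  s <- unclass(sim)[rows, , drop = FALSE]
  self <- match(rows, colnames(s))
  has_self <- !is.na(self)
  s[cbind(which(has_self), self[has_self])] <- -Inf
  pred <- colnames(s)[row_argmax(s)]
  df <- data.frame(target = rows, predicted = pred, correct = pred == twin[rows])
  new_identification(df, mean(df$correct), tolower(zygosity),
                     length(rows) * ncol(sim))
}

#' Mean identification accuracy over session combinations
#'
#' Individual identification averages the two cross-session combinations
#' (RESTX targets vs RESTY database, X != Y); twin identification averages
#' all four combinations (X, Y in \{1, 2\}). The SD is taken over those
#' combination accuracies.
#'
#' @param rest1,rest2 `edge_table`s for the two sessions.
#' @param mode `"individual"`, `"mz"` or `"dz"`.
#' @param cohort Required for twin modes.
#' @return List with `mean`, `sd`, the per-combination `accuracies`, and
#'   `mode`.
#' @export
mean_accuracy_over_combinations <- function(rest1, rest2,
                                            mode = c("individual", "mz", "dz"),
                                            cohort = NULL) {
  mode <- match.arg(mode)
  sessions <- list(rest1, rest2)
  combos <- if (mode == "individual") list(c(1, 2), c(2, 1))
            else list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  acc <- vapply(combos, function(xy) {
    sim <- similarity_matrix(sessions[[xy[1]]], sessions[[xy[2]]])
    if (mode == "individual") identify_individuals(sim)$accuracy
    else identify_twins(sim, cohort, toupper(mode))$accuracy
  }, numeric(1))
  list(mean = mean(acc), sd = stats::sd(acc), accuracies = acc, mode = mode)
}

#' Permutation test for twin identification
#'
#' Keeps the observed argmax predictions fixed and, at each permutation,
#' reassigns the "correct twin" label by shuffling the pairing among the
#' analyzed targets (a derangement is not enforced). The p-value uses the
#' add-one estimator `(1 + #\{permuted >= observed\}) / (1 + n_perm)`, so it
#' lies in (0, 1].
#'
#' @param sim A `similarity_matrix` over the full cohort.
#' @param cohort A `twin_cohort`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @return List with `p_value`, `observed` accuracy, and the vector of
#'   `permuted` accuracies.
#' @export
permutation_test_twin <- function(sim, cohort, zygosity = c("MZ", "DZ"),
                                  n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  zygosity <- match.arg(zygosity)
  res <- identify_twins(sim, cohort, zygosity)
  twins <- twin_map(validate_cohort(cohort))[res$predictions$target]
  if (!is.null(seed)) set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(b) {
    mean(res$predictions$predicted == sample(twins))
  }, numeric(1))
  list(p_value = (1 + sum(permuted >= res$accuracy)) / (1 + n_perm),
       observed = res$accuracy, permuted = permuted, n_perm = n_perm)
}

#' Identification accuracy over random edge subsets
#'
#' For each subset size, draws `n_reps` random edge subsets (without
#' replacement within a draw, independently across draws) and reruns the
#' session-combination identification on each draw, reporting mean and SD
#' per size and mode.
#'
#' @param rest1,rest2 `edge_table`s for the two sessions.
#' @param cohort A `twin_cohort` (needed for twin modes).
#' @param sizes Subset sizes; default the seven sizes 10, 50, 100, 500,
#'   1000, 5000, 10000 (must not exceed the edge count).
#' @param n_reps Random draws per size.
#' @param seed Optional integer seed.
#' @param modes Which identification modes to run.
#' @return data.frame with columns `size`, `mode`, `mean`, `sd`.
#' @export
edge_subset_curve <- function(rest1, rest2, cohort,
                              sizes = c(10, 50, 100, 500, 1000, 5000, 10000),
                              n_reps = 100, seed = NULL,
                              modes = c("individual", "mz", "dz")) {
  validate_edge_table(rest1)
  E <- ncol(rest1$values)
  if (any(sizes > E))
    stop(sprintf("subset size(s) %s exceed the %d available edges",
                 paste(sizes[sizes > E], collapse = ", "), E))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (size in sizes) {
    acc <- matrix(NA_real_, n_reps, length(modes), dimnames = list(NULL, modes))
    for (r in seq_len(n_reps)) {
      sel <- sample.int(E, size)
      s1 <- subset_edges(rest1, sel); s2 <- subset_edges(rest2, sel)
      for (m in modes)
        acc[r, m] <- mean_accuracy_over_combinations(s1, s2, m, cohort)$mean
    }
    out[[length(out) + 1L]] <- data.frame(
      size = size, mode = modes, mean = colMeans(acc),
      sd = apply(acc, 2, stats::sd), row.names = NULL)
  }
  do.call(rbind, out)
}
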