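#' Group similarity scores by familial relationship
#'
#' Assigns every ordered (target, database) cell of a REST1-by-REST2
#' similarity matrix to exactly one of four groups: same individual (SI),
#' monozygotic twin pair (MZ), dizygotic twin pair (DZ), or unrelated
#' individuals (UN). Counts refer to ordered cells, so a twin pair present
#' in both sets contributes two MZ (or DZ) cells.
#'
#' @param sim A `similarity_matrix` over the full cohort.
#' @param cohort A `twin_cohort` covering every subject in `sim`.
#' @return A `grouped_correlations` object: list of score vectors `SI`,
#'   `MZ`, `DZ`, `UN` and their `counts`.
#' @export
group_scores <- function(sim, cohort) {
  cohort <- validate_cohort(cohort)
  ids_t <- rownames(sim); ids_d <- colnames(sim)
  missing <- setdiff(c(ids_t, ids_d), cohort$subject_id)
  if (length(missing))
    stop("subject(s) in similarity matrix missing from cohort: ",
         paste(missing, collapse = ", "))
  pos_t <- match(ids_t, cohort$subject_id)
  pos_d <- match(ids_d, cohort$subject_id)
  same <- outer(ids_t, ids_d, "==")
  paired <- outer(cohort$pair_id[pos_t], cohort$pair_id[pos_d], "==") & !same
  mz <- paired & cohort$zygosity[pos_t] == "MZ"
  dz <- paired & cohort$zygosity[pos_t] == "DZ"
  s <- unclass(sim)
  scores <- list(SI = s[same], MZ = s[mz], DZ = s[dz], UN = s[!same & !paired])
  structure(list(scores = scores, counts = lengths(scores)),
            class = "grouped_correlations")
}

#' @export
print.grouped_correlations <- function(x, ...) {
  cat("<grouped_correlations> counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Cliff's delta effect size
#'
#' `d = (#\{x1 > x2 pairs\} - #\{x1 < x2 pairs\}) / (n1 * n2)` over all
#' `n1 * n2` cross-sample pairs; ties contribute zero. `d` lies in
#' `[-1, 1]`, is 0 for identical distributions, 1 when every `x1` exceeds
#' every `x2`, and is antisymmetric in its arguments. The default method
#' counts via a sorted search in `O((n1 + n2) log n2)`; `method = "brute"`
#' evaluates the definition literally and is kept as a cross-check.
#'
#' @param x1,x2 Non-empty numeric samples.
#' @param method `"sort"` (default) or `"brute"`.
#' @return Scalar effect size in `[-1, 1]`.
#' @examples
#' cliffs_delta(c(3, 4, 5), c(0, 1, 2))  # 1
#' @export
cliffs_delta <- function(x1, x2, method = c("sort", "brute")) {
  method <- match.arg(method)
  if (!length(x1) || !length(x2)) stop("both samples must be non-empty")
  n1 <- length(x1); n2 <- length(x2)
  if (method == "brute") {
    wins <- 0; losses <- 0
    for (a in x1) { wins <- wins + sum(a > x2); losses <- losses + sum(a < x2) }
  } else {
    sx2 <- sort(x2)
    wins <- sum(findInterval(x1, sx2, left.open = TRUE))  # #{x2 <  x1_i}
    losses <- sum(n2 - findInterval(x1, sx2))             # #{x2 >  x1_i}
  }
  (wins - losses) / (n1 * n2)
}

#' Pair effect sizes with identification accuracies
#'
#' One row per network and relatedness group (SI, MZ, DZ): Cliff's delta of
#' that group's similarity scores against the unrelated (UN) scores of the
#' same network, next to the matching identification accuracy.
#'
#' @param grouped Named list of `grouped_correlations`, one per network.
#' @param accuracies data.frame with columns `network`, `group` (SI/MZ/DZ)
#'   and `accuracy` covering the same networks.
#' @return data.frame with columns `network`, `group`, `delta`, `accuracy`.
#' @export
accuracy_vs_effect_size <- function(grouped, accuracies) {
  nets <- names(grouped)
  miss <- setdiff(nets, unique(accuracies$network))
  if (length(miss))
    stop("network(s) missing from accuracies: ", paste(miss, collapse = ", "))
  miss2 <- setdiff(unique(accuracies$network), nets)
  if (length(miss2))
    stop("network(s) missing from grouped scores: ", paste(miss2, collapse = ", "))
  rows <- list()
  for (net in nets) {
    g <- grouped[[net]]
    for (grp in c("SI", "MZ", "DZ")) {
      acc <- accuracies$accuracy[accuracies$network == net & accuracies$group == grp]
      if (!length(acc)) stop(sprintf("no accuracy for network '%s' group %s", net, grp))
      rows[[length(rows) + 1L]] <- data.frame(
        network = net, group = grp,
        delta = cliffs_delta(g$scores[[grp]], g$scores$UN), accuracy = acc[1])
    }
  }
  do.call(rbind, rows)
}
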