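#' Pearson ROI-to-ROI connectivity from time series
#'
#' @param timeseries Numeric matrix, time points x nodes (>= 3 time points,
#'   no constant column).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(timeseries) {
  if (!is.matrix(timeseries)) timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3) stop("need at least 3 time points")
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(timeseries)
    bad <- if (is.null(nm)) which(sds == 0) else nm[sds == 0]
    stop("constant time series for node(s): ", paste(bad, collapse = ", "))
  }
  m <- stats::cor(timeseries)
  diag(m) <- 1
  validate_connectivity(m)
}

#' Average two sessions edge-wise
#'
#' @param rest1,rest2 `edge_table`s over identical subjects and edges.
#' @return An `edge_table` of element-wise means with session tag `"mean"`.
#' @export
average_sessions <- function(rest1, rest2) {
  validate_edge_table(rest1); validate_edge_table(rest2)
  if (!identical(rownames(rest1$values), rownames(rest2$values)))
    stop("sessions cover different subjects")
  if (!identical(edge_labels(rest1$edges), edge_labels(rest2$edges)))
    stop("sessions cover different edges")
  edge_table((rest1$values + rest2$values) / 2, rest1$edges, session = "mean")
}

#' Canonical edge positions of a functional network
#'
#' Returns the canonical lower-triangle positions of all edges with both
#' endpoints inside the named network (k member nodes give k(k-1)/2
#' positions). Edges touching nodes outside the network, including
#' `"unassigned"` ones, are excluded.
#'
#' @param parc A `parcellation`.
#' @param network A network name present in `parc`.
#' @return Sorted integer vector of edge positions (possibly empty).
#' @export
network_edges <- function(parc, network) {
  parc <- validate_parcellation(parc)
  if (!network %in% parc$network)
    stop(sprintf("unknown network '%s'; valid networks: %s", network,
                 paste(network_names(parc), collapse = ", ")))
  nodes <- which(parc$network == network)
  if (length(nodes) < 2) return(integer(0))
  pr <- t(utils::combn(nodes, 2))        # each row (a, b) with a < b
  sort(edge_index(pr[, 2], pr[, 1], n_nodes(parc)))
}

#' Regress age and sex out of every edge
#'
#' Per edge, ordinary least squares on intercept + age + male indicator over
#' the full sample (MZ and DZ pooled); residuals are returned. A covariate
#' that is constant across all subjects is dropped with a warning. Output
#' edges have zero sample correlation with age and the sex indicator and the
#' operation is idempotent.
#'
#' @param edges An `edge_table` whose rows match `cohort` subjects.
#' @param cohort A `twin_cohort`.
#' @return An `edge_table` of residuals (same session tag).
#' @export
residualize <- function(edges, cohort) {
  validate_edge_table(edges); cohort <- validate_cohort(cohort)
  ids <- rownames(edges$values)
  if (!setequal(ids, cohort$subject_id))
    stop("edge table and cohort cover different subjects")
  cohort <- cohort[match(ids, cohort$subject_id), ]
  covs <- list(age = cohort$age, sexM = as.numeric(cohort$sex == "M"))
  keep <- vapply(covs, function(v) stats::var(v) > 0, logical(1))
  if (any(!keep))
    warning("dropping constant covariate(s): ", paste(names(covs)[!keep], collapse = ", "))
  X <- cbind(intercept = 1, do.call(cbind, covs[keep]))
  res <- stats::lm.fit(X, edges$values)$residuals
  dimnames(res) <- dimnames(edges$values)
  edge_table(res, edges$edges, session = edges$session)
}
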