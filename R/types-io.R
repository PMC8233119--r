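#' Twin cohort table
#'
#' A cohort is a data.frame with one row per subject and columns
#' `subject_id`, `pair_id`, `zygosity` (`"MZ"` or `"DZ"`), `age` (years) and
#' `sex` (`"F"` or `"M"`). Every `pair_id` occurs exactly twice with
#' identical zygosity; subject ids are unique.
#'
#' @param subject_id,pair_id Character vectors.
#' @param zygosity Character vector of `"MZ"`/`"DZ"`.
#' @param age Numeric, years.
#' @param sex Character vector of `"F"`/`"M"`.
#' @return A validated `twin_cohort` data.frame.
#' @export
cohort <- function(subject_id, pair_id, zygosity, age, sex) {
  x <- data.frame(subject_id = as.character(subject_id),
                  pair_id = as.character(pair_id),
                  zygosity = as.character(zygosity),
                  age = as.numeric(age),
                  sex = as.character(sex),
                  stringsAsFactors = FALSE)
  class(x) <- c("twin_cohort", "data.frame")
  validate_cohort(x)
}

#' @rdname cohort
#' @param x An object to validate.
#' @export
validate_cohort <- function(x) {
  req <- c("subject_id", "pair_id", "zygosity", "age", "sex")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) stop("cohort is empty")
  dup <- unique(x$subject_id[duplicated(x$subject_id)])
  if (length(dup)) stop("duplicated subject_id(s): ", paste(dup, collapse = ", "))
  bad_z <- unique(x$zygosity[!x$zygosity %in% c("MZ", "DZ")])
  if (length(bad_z)) stop("unknown zygosity value(s): ", paste(bad_z, collapse = ", "))
  bad_s <- unique(x$sex[!x$sex %in% c("F", "M")])
  if (length(bad_s)) stop("unknown sex value(s): ", paste(bad_s, collapse = ", "))
  sizes <- table(x$pair_id)
  odd <- names(sizes)[sizes != 2]
  if (length(odd))
    stop("pair_id(s) not occurring exactly twice: ", paste(odd, collapse = ", "))
  zper <- tapply(x$zygosity, x$pair_id, function(z) length(unique(z)))
  mixed <- names(zper)[zper != 1]
  if (length(mixed))
    stop("pair_id(s) with inconsistent zygosity: ", paste(mixed, collapse = ", "))
  if (!is.numeric(x$age) || anyNA(x$age)) stop("age must be numeric and non-missing")
  if (!inherits(x, "twin_cohort")) class(x) <- c("twin_cohort", class(x))
  x
}

#' Read / write a cohort table
#'
#' Tab-separated text with a header row and columns `subject_id`, `pair_id`,
#' `zygosity`, `age`, `sex`. Writing then reading is value-identical.
#'
#' @param path File path.
#' @return `read_cohort()`: a validated `twin_cohort`.
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  x$age <- as.numeric(x$age)
  validate_cohort(structure(x, class = c("twin_cohort", "data.frame")))
}

#' @rdname read_cohort
#' @param x A `twin_cohort`.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parcellation table
#'
#' Maps ordered nodes to named functional networks. Nodes labelled
#' `"unassigned"` are allowed; they take part in whole-brain analyses only.
#'
#' @param node_id Character (or coercible) node identifiers, in node order.
#' @param network Character network label per node.
#' @return A validated `parcellation` data.frame.
#' @export
parcellation <- function(node_id, network) {
  x <- data.frame(node_id = as.character(node_id),
                  network = as.character(network), stringsAsFactors = FALSE)
  class(x) <- c("parcellation", "data.frame")
  validate_parcellation(x)
}

#' @rdname parcellation
#' @param x An object to validate.
#' @export
validate_parcellation <- function(x) {
  if (!all(c("node_id", "network") %in% names(x)))
    stop("parcellation needs columns node_id and network")
  if (nrow(x) < 2) stop("parcellation needs at least 2 nodes")
  dup <- unique(x$node_id[duplicated(x$node_id)])
  if (length(dup)) stop("duplicated node_id(s): ", paste(dup, collapse = ", "))
  if (anyNA(x$network) || any(!nzchar(x$network)))
    stop("every node needs a non-empty network label")
  if (!inherits(x, "parcellation")) class(x) <- c("parcellation", class(x))
  x
}

#' @rdname parcellation
#' @export
network_names <- function(x) unique(x$network)

#' @rdname parcellation
#' @export
n_nodes <- function(x) nrow(x)

#' @rdname read_cohort
#' @return `read_parcellation()`: a validated `parcellation`.
#' @export
read_parcellation <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  validate_parcellation(structure(x, class = c("parcellation", "data.frame")))
}

#' @rdname read_cohort
#' @export
write_parcellation <- function(x, path) {
  validate_parcellation(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subjects-by-edges table
#'
#' Holds one row per subject and one column per canonical edge (labels
#' `"i_j"` with `i > j`), plus the node-pair index and a session tag
#' (`"REST1"`, `"REST2"` or `"mean"`).
#'
#' @param values Numeric matrix, subjects x edges, with subject ids as row
#'   names. Column names, if present, must be canonical edge labels.
#' @param edges Optional data.frame with columns `node_i`, `node_j`
#'   (`node_i > node_j`); parsed from column names when omitted.
#' @param session Session tag.
#' @return A validated `edge_table`.
#' @export
edge_table <- function(values, edges = NULL, session = "REST1") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("`values` needs subject ids as row names")
  if (is.null(edges)) {
    if (is.null(colnames(values)))
      stop("provide `edges` or canonical edge labels as column names")
    edges <- parse_edge_labels(colnames(values))
  }
  colnames(values) <- edge_labels(edges)
  x <- structure(list(values = values, edges = edges, session = session),
                 class = "edge_table")
  validate_edge_table(x)
}

#' @rdname edge_table
#' @param x An object to validate.
#' @export
validate_edge_table <- function(x) {
  if (!is.list(x) || !all(c("values", "edges", "session") %in% names(x)))
    stop("edge_table needs values, edges and session")
  e <- x$edges
  if (nrow(e) != ncol(x$values))
    stop("edge index length does not match value columns")
  if (any(e$node_i <= e$node_j))
    stop("edge index must satisfy node_i > node_j (self-pairs forbidden)")
  lab <- edge_labels(e)
  dup <- unique(lab[duplicated(lab)])
  if (length(dup)) stop("duplicated edge(s): ", paste(dup, collapse = ", "))
  dup_s <- unique(rownames(x$values)[duplicated(rownames(x$values))])
  if (length(dup_s)) stop("duplicated subject row(s): ", paste(dup_s, collapse = ", "))
  if (!inherits(x, "edge_table")) class(x) <- "edge_table"
  x
}

#' @export
print.edge_table <- function(x, ...) {
  cat(sprintf("<edge_table> %d subjects x %d edges, session %s\n",
              nrow(x$values), ncol(x$values), x$session))
  invisible(x)
}

#' @rdname edge_table
#' @export
subjects <- function(x) rownames(x$values)

#' Subset an edge table by canonical edge positions
#'
#' @param x An `edge_table`.
#' @param positions Integer column positions (relative to `x`'s edge index).
#' @return An `edge_table` holding only the requested edges.
#' @export
subset_edges <- function(x, positions) {
  validate_edge_table(x)
  if (any(positions < 1 | positions > ncol(x$values)))
    stop("edge positions out of range")
  edge_table(x$values[, positions, drop = FALSE],
             x$edges[positions, , drop = FALSE], session = x$session)
}

#' Read / write a subjects-by-edges table
#'
#' Wide tab-separated text: a `# session: <tag>` comment line, then a header
#' (`subject_id` followed by one `"i_j"` label per edge) and one row per
#' subject. Round-trips exactly at 17 significant digits.
#'
#' @param path File path.
#' @return `read_edge_table()`: a validated `edge_table`.
#' @export
read_edge_table <- function(path) {
  first <- readLines(path, n = 1L)
  session <- if (startsWith(first, "# session:"))
    trimws(sub("^# session:", "", first)) else "REST1"
  x <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  vals <- as.matrix(x[, -1, drop = FALSE])
  rownames(vals) <- as.character(x[[1]])
  edge_table(vals, parse_edge_labels(colnames(vals)), session = session)
}

#' @rdname read_edge_table
#' @param x An `edge_table`.
#' @export
write_edge_table <- function(x, path) {
  validate_edge_table(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# session: ", x$session), con)
  df <- data.frame(subject_id = rownames(x$values),
                   signif(x$values, 17), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a connectivity matrix
#'
#' A connectivity matrix is square, symmetric (within `tol`, then
#' symmetrized by averaging), has unit diagonal and entries in `[-1, 1]`.
#'
#' @param m Numeric matrix.
#' @param tol Symmetry/diagonal tolerance.
#' @return The symmetrized matrix, invisibly usable downstream.
#' @export
validate_connectivity <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2)
    stop("connectivity matrix must be square with >= 2 nodes")
  asym <- max(abs(m - t(m)))
  if (asym > tol) stop(sprintf("not symmetric: max asymmetry %.3g", asym))
  m <- (m + t(m)) / 2
  if (max(abs(diag(m) - 1)) > tol) stop("diagonal must be 1")
  if (max(abs(m)) > 1 + tol) stop("entries must lie in [-1, 1]")
  diag(m) <- 1
  m[m > 1] <- 1; m[m < -1] <- -1
  m
}

#' Read / write a square connectivity matrix
#'
#' Square tab-separated text with node ids as both header and first column.
#'
#' @param path File path.
#' @return `read_connectivity()`: a validated symmetric matrix with node ids
#'   as dimnames.
#' @export
read_connectivity <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  validate_connectivity(m)
}

#' @rdname read_connectivity
#' @param m A connectivity matrix with node-id dimnames.
#' @export
write_connectivity <- function(m, path) {
  m <- validate_connectivity(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
  df <- data.frame(node_id = rownames(m), signif(m, 17), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
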