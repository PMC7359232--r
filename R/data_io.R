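#' Read a counts or covariates table
#'
#' Tables are TSV or CSV (sniffed from the file extension), with a header row
#' of taxon/covariate names and the first column holding subject ids.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @return numeric matrix with subject ids as rownames.
#' @export
read_table_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @rdname read_table_matrix
#' @export
read_counts <- function(path) {
  m <- read_table_matrix(path)
  if (any(m < 0)) stop("negative counts in ", path)
  if (any(m != round(m))) stop("non-integer counts in ", path)
  m
}

#' @rdname read_table_matrix
#' @export
read_covariates <- function(path) read_table_matrix(path)

#' Standardize continuous covariates
#'
#' Continuous columns are z-scored (sample standard deviation, `n - 1`
#' denominator); columns named in `indicator_cols` (0/1 dummies for
#' categorical covariates) are left untouched.  The centring and scaling
#' constants are retained as attributes for reporting back-transformed
#' effects.  Standardizing is strongly recommended before fitting: the
#' log-linear link exponentiates `x * beta`, so raw-scale covariates easily
#' overflow.
#'
#' @param X numeric matrix, subjects x covariates, with column names.
#' @param indicator_cols character vector of column names to leave unscaled.
#' @return the standardized matrix, with attributes `center`, `scale`, and
#'   `standardized = TRUE`.
#' @export
standardize_covariates <- function(X, indicator_cols = character()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  bad <- setdiff(indicator_cols, colnames(X))
  if (length(bad)) stop("unknown indicator columns: ", paste(bad, collapse = ", "))
  cont <- setdiff(colnames(X), indicator_cols)
  ctr <- stats::setNames(numeric(ncol(X)), colnames(X))
  scl <- stats::setNames(rep(1, ncol(X)), colnames(X))
  for (nm in cont) {
    s <- stats::sd(X[, nm])
    if (!is.finite(s) || s == 0)
      stop("constant continuous column cannot be standardized: ", nm)
    ctr[nm] <- mean(X[, nm])
    scl[nm] <- s
    X[, nm] <- (X[, nm] - ctr[nm]) / s
  }
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  attr(X, "standardized") <- TRUE
  X
}

#' Decompose leaf counts into node-local child counts
#'
#' The DTM likelihood factorizes over internal nodes: each node sees, per
#' subject, the counts allocated among its children, where a child's count is
#' the sum of the subject's leaf counts descending from it.  This function
#' performs that aggregation.  Column labels of `counts` must match the
#' tree's leaf labels exactly (as sets); a mismatch is a hard error rather
#' than a silent prune, since silent pruning hides data bugs.
#'
#' @param counts nonnegative integer matrix, subjects x taxa, with taxon
#'   column names.
#' @param tree a [dtm_tree].
#' @return an object of class `dtm_node_counts`: a list with `node_y` (per
#'   internal node, an n x C_v matrix of child counts whose columns are that
#'   node's child branches), `node_total` (per node, the n-vector of node
#'   totals) and `tree`.
#' @export
decompose_counts <- function(counts, tree) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  labs <- colnames(counts)
  if (is.null(labs)) stop("count matrix must have taxon column names")
  missing_in_counts <- setdiff(tree$leaf_labels, labs)
  extra_in_counts <- setdiff(labs, tree$leaf_labels)
  if (length(missing_in_counts) || length(extra_in_counts))
    stop("count/tree label mismatch; missing from counts: {",
         paste(missing_in_counts, collapse = ", "), "}; not in tree: {",
         paste(extra_in_counts, collapse = ", "), "}")
  counts <- counts[, tree$leaf_labels, drop = FALSE]

  node_y <- vector("list", length(tree$node_ids))
  node_total <- vector("list", length(tree$node_ids))
  for (k in seq_along(tree$node_ids)) {
    bs <- tree$node_branches[[k]]
    yk <- vapply(bs, function(b)
      rowSums(counts[, tree$leaf_sets[[b]], drop = FALSE]),
      numeric(nrow(counts)))
    if (nrow(counts) == 1L) yk <- matrix(yk, nrow = 1L)
    colnames(yk) <- tree$branch_labels[bs]
    node_y[[k]] <- yk
    node_total[[k]] <- rowSums(yk)
  }
  structure(list(node_y = node_y, node_total = node_total, tree = tree),
            class = "dtm_node_counts")
}

#' Bundle counts, covariates and tree into a model-ready object
#'
#' Validates dimensions and labels, standardizes covariates (unless already
#' standardized), and precomputes the node-level count decomposition used by
#' the likelihood and sampler.
#'
#' @param counts subjects x taxa count matrix (taxon column names matching
#'   the tree's leaves).
#' @param covariates subjects x covariates numeric matrix.
#' @param tree a [dtm_tree]; pass `NULL` to use a star tree over the count
#'   columns (the DM fallback).
#' @param indicator_cols covariate columns to exempt from standardization.
#' @param standardize logical; set `FALSE` if `covariates` is already
#'   prepared.
#' @return an object of class `dtm_data`.
#' @export
dtm_data <- function(counts, covariates, tree = NULL,
                     indicator_cols = character(), standardize = TRUE) {
  counts <- as.matrix(counts)
  covariates <- as.matrix(covariates)
  if (nrow(counts) != nrow(covariates))
    stop("counts and covariates disagree on the number of subjects (",
         nrow(counts), " vs ", nrow(covariates), ")")
  if (is.null(tree)) tree <- star_tree(colnames(counts))
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (standardize)
    covariates <- standardize_covariates(covariates, indicator_cols)
  nc <- decompose_counts(counts, tree)
  structure(list(tree = tree, counts = counts[, tree$leaf_labels, drop = FALSE],
                 X = covariates, node_counts = nc,
                 n = nrow(counts), P = ncol(covariates), B = tree$B),
            class = "dtm_data")
}

#' @export
print.dtm_data <- function(x, ...) {
  cat("dtm_data:", x$n, "subjects,", length(x$tree$leaf_labels), "taxa,",
      x$P, "covariates,", x$B, "branches\n")
  invisible(x)
}

#' Read or build a covariate-relation graph
#'
#' The Markov-random-field inclusion prior takes a symmetric 0/1 adjacency
#' matrix over covariates.  `read_graph` reads one from a TSV with covariate
#' names as header; `correlation_graph` thresholds an empirical covariate
#' correlation matrix (`|r| >= cutoff`) into an adjacency.
#'
#' @param path TSV file of the adjacency matrix.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @export
read_graph <- function(path) {
  G <- read_table_matrix(path)
  validate_graph(G)
}

#' @rdname read_graph
#' @param X covariate matrix.
#' @param cutoff absolute-correlation threshold for drawing an edge.
#' @export
correlation_graph <- function(X, cutoff = 0.7) {
  R <- stats::cor(as.matrix(X))
  G <- (abs(R) >= cutoff) * 1
  diag(G) <- 0
  validate_graph(G)
}

validate_graph <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("adjacency matrix must be square")
  if (any(G != t(G))) stop("adjacency matrix must be symmetric")
  if (any(diag(G) != 0)) stop("adjacency matrix must have zero diagonal")
  if (!all(G %in% c(0, 1))) stop("adjacency entries must be 0/1")
  G
}
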