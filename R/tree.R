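#' Rooted trees with deterministic branch indexing
#'
#' A `dtm_tree` wraps an [ape::phylo] topology and fixes a bijection between
#' parent->child edges ("branches") and the integers `1..B`.  Every branch
#' carries its own intercept and covariate coefficients in the Dirichlet-tree
#' multinomial (DTM) model, so the indexing must be reproducible: branches are
#' numbered depth-first from the root, visiting children in their input
#' (Newick source) order.  Branch lengths, if present, are discarded; the
#' model uses topology only.  Unary internal nodes (single-child chains) are
#' collapsed on load, since a one-child node contributes a degenerate
#' multinomial and non-identifiable parameters.
#'
#' @param phy an [ape::phylo] object (rooted, >= 2 leaves).
#' @return An object of class `dtm_tree` with components:
#'   \describe{
#'     \item{phylo}{the underlying `phylo`, singles collapsed}
#'     \item{B}{total number of branches (edges)}
#'     \item{leaf_labels}{taxon names, in tip order}
#'     \item{node_ids}{internal node ids (ape numbering) in depth-first
#'       preorder; the root is first}
#'     \item{node_labels}{stable labels `"node_1"`, `"node_2"`, ... for the
#'       internal nodes, in the same order}
#'     \item{children}{list: ordered child node ids per internal node}
#'     \item{node_branches}{list: branch ids of each internal node's child
#'       edges, in child order}
#'     \item{branch_parent}{for each branch, the index (into `node_ids`) of
#'       its parent node}
#'     \item{branch_child_pos}{for each branch, the position of the child
#'       among its parent's children}
#'     \item{branch_labels}{for each branch, the label of its child: a leaf
#'       name, or the synthesized internal label}
#'     \item{leaf_sets}{list: tip indices descending from each branch's child}
#'   }
#' @export
dtm_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  if (length(phy$tip.label) < 2L)
    stop("structural error: a tree needs at least 2 leaves")
  phy <- ape::collapse.singles(phy)
  phy$edge.length <- NULL # topology only
  if (anyDuplicated(phy$tip.label))
    stop("leaf labels must be unique; duplicated: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  ntip <- length(phy$tip.label)
  root <- ntip + 1L

  child_rows <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])

  node_ids <- integer(0)
  children <- list()
  node_branches <- list()
  branch_parent <- integer(0)
  branch_child_pos <- integer(0)
  branch_child <- integer(0)

  # depth-first from the root: assign a branch id to each child edge as it is
  # encountered, recursing into internal children immediately
  visit <- function(v) {
    node_ids[[length(node_ids) + 1L]] <<- v
    k <- length(node_ids)
    kids <- phy$edge[child_rows[[as.character(v)]], 2L]
    children[[k]] <<- kids
    bs <- integer(length(kids))
    for (j in seq_along(kids)) {
      b <- length(branch_child) + 1L
      branch_child[[b]] <<- kids[j]
      branch_parent[[b]] <<- k
      branch_child_pos[[b]] <<- j
      bs[j] <- b
      if (kids[j] > ntip) visit(kids[j])
    }
    node_branches[[k]] <<- bs
  }
  # iterative-safe recursion depth for deep trees
  old_exp <- getOption("expressions")
  on.exit(options(expressions = old_exp), add = TRUE)
  options(expressions = max(old_exp, 50000L))
  visit(root)
  B <- length(branch_child)

  # descendant tip sets per branch
  leaf_sets <- vector("list", B)
  desc <- function(v) {
    if (v <= ntip) return(v)
    k <- match(v, node_ids)
    sort(unlist(lapply(children[[k]], desc), use.names = FALSE))
  }
  for (b in seq_len(B)) leaf_sets[[b]] <- desc(branch_child[b])

  node_labels <- paste0("node_", seq_along(node_ids))
  branch_labels <- ifelse(branch_child <= ntip,
                          phy$tip.label[pmin(branch_child, ntip)],
                          node_labels[match(branch_child, node_ids)])

  structure(list(phylo = phy, B = B, leaf_labels = phy$tip.label,
                 node_ids = node_ids, node_labels = node_labels,
                 children = children, node_branches = node_branches,
                 branch_parent = branch_parent,
                 branch_child = branch_child,
                 branch_child_pos = branch_child_pos,
                 branch_labels = branch_labels,
                 leaf_sets = leaf_sets),
            class = "dtm_tree")
}

#' Parse a Newick string or file into a branch-indexed tree
#'
#' Thin wrapper around [ape::read.tree] that validates the string, collapses
#' unary nodes, discards branch lengths, and builds the deterministic branch
#' index (see [dtm_tree]).
#'
#' @param text a Newick string (mutually exclusive with `file`).
#' @param file path to a Newick file.
#' @return a [dtm_tree].
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' tr$B # 4 branches
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  .check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("malformed Newick string (ape could not parse it)")
  dtm_tree(phy)
}

# cheap structural validation with a character offset in the error message
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i)
    }
    if (chars[i] == "," && depth == 0L)
      stop("malformed Newick: ',' outside any clade at character offset ", i)
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character offset ",
         length(chars))
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick: missing terminating ';' at character offset ",
         length(chars))
  invisible(TRUE)
}

#' Build a star tree (Dirichlet-multinomial fallback)
#'
#' A star tree has a single internal node (the root) with every taxon as a
#' direct child, so `B` equals the number of taxa and the DTM model collapses
#' to ordinary Dirichlet-multinomial (DM) regression on the full count
#' matrix.  This is the recommended fallback for larger data sets where no
#' tree structure is available or wanted.
#'
#' @param labels character vector of taxon names (>= 2, unique).
#' @return a [dtm_tree] with `B == length(labels)`.
#' @export
star_tree <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("structural error: a star tree needs at least 2 labels")
  J <- length(labels)
  phy <- structure(list(edge = cbind(rep(J + 1L, J), seq_len(J)),
                        tip.label = labels, Nnode = 1L),
                   class = "phylo", order = "cladewise")
  dtm_tree(phy)
}

#' @export
print.dtm_tree <- function(x, ...) {
  cat("dtm_tree:", length(x$leaf_labels), "leaves,",
      length(x$node_ids), "internal nodes,", x$B, "branches\n")
  invisible(x)
}

#' Branches on the root-to-leaf path of a taxon
#'
#' Used to restrict association networks to the lineage of named taxa, e.g.
#' reporting all covariates selected anywhere along the path from the root to
#' a genus of interest.
#'
#' @param tree a [dtm_tree].
#' @param taxon a leaf label.
#' @return integer vector of branch ids from the root down to the leaf.
#' @export
leaf_path_branches <- function(tree, taxon) {
  tip <- match(taxon, tree$leaf_labels)
  if (is.na(tip)) stop("unknown taxon name: ", taxon)
  path <- integer(0)
  for (b in seq_len(tree$B)) {
    if (tip %in% tree$leaf_sets[[b]]) path <- c(path, b)
  }
  path[order(lengths(tree$leaf_sets[path]), decreasing = TRUE)]
}
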