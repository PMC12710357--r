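# Tree topology utilities. All downstream analyses are purely topological:
# branch lengths and node support are parsed (ape handles them) but ignored.

#' Read a rooted tree topology from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that adds a pre-parse bracket check
#' (so malformed files fail with a character position) and validates that leaf
#' labels are unique. Branch lengths and support values, if present, are kept
#' on the returned `phylo` object but ignored by every function in this
#' package.
#'
#' @param path Path to a Newick file containing a single tree.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("(A,(B,C));", tf)
#' tr <- read_newick(tf)
#' tr$tip.label
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop("tree file not found: ", path, call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt, path)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    stop("malformed newick in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in '", path, "': ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tr
}

# Bracket-balance scan; reports the 1-based character position of the first
# violation, which ape's own parser does not do.
check_newick_syntax <- function(txt, path = "<text>") {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error in '", path,
             "': unmatched ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("newick parse error in '", path, "': ", depth,
         " unclosed '(' at end of input", call. = FALSE)
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop("newick parse error in '", path, "': missing terminating ';' at character ",
         nchar(txt), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Restrict a tree to a subset of its leaves
#'
#' Returns the induced subtree on `leaves`: all other tips are dropped and the
#' resulting degree-2 internal nodes are suppressed.
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of tip labels, a subset of
#'   `tree$tip.label`, with at least 2 elements.
#' @return A `phylo` object on exactly `leaves`.
#' @export
induced_subtree <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- as.character(leaves)
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(leaves) < 2) {
    stop("need at least 2 leaves to induce a subtree", call. = FALSE)
  }
  ape::keep.tip(tree, leaves)
}

#' Robinson-Foulds distance between two topologies
#'
#' Unrooted RF distance: the number of bipartitions present in exactly one of
#' the two trees. Both trees must have the same leaf set. Trees with three or
#' fewer leaves have no nontrivial bipartitions, so their distance is always
#' zero. Computed via [phangorn::RF.dist()]; the test suite cross-checks it
#' against a direct bipartition symmetric-difference enumeration.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return A non-negative integer; 0 iff the unrooted topologies are
#'   identical.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (length(t1$tip.label) != length(t2$tip.label) ||
      !setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf sets differ between the two trees", call. = FALSE)
  }
  n <- length(t1$tip.label)
  if (n <= 3) {
    return(0L)
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

# Children of an internal node (node numbers, ape convention).
node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

# Tip labels descending from a node (the node itself if it is a tip).
node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    return(tree$tip.label[node])
  }
  out <- character(0)
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[[1]]
    stack <- stack[-1]
    ch <- node_children(tree, nd)
    tips <- ch[ch <= ntip]
    out <- c(out, tree$tip.label[tips])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}
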