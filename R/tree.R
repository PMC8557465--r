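#' Read a newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] with validation of unique,
#' non-empty leaf labels.
#'
#' @param path path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path, call. = FALSE)
  .validate_tree(tree)
  tree
}

.validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("empty leaf label(s) in tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' Leaves on the focal side of an internal branch
#'
#' The branch above an internal node induces a bipartition of the leaves;
#' this returns the leaf set descending from that node (the focal clade).
#' The branch may be named by the ape node number, by an internal node label,
#' or by a character vector of two or more taxa whose most recent common
#' ancestor defines the clade.
#'
#' @param tree a `phylo` object.
#' @param branch integer node id, internal node label, or a character vector
#'   of taxon names (MRCA rule).
#' @return Character vector of clade member leaf labels.
#' @export
clade_members <- function(tree, branch) {
  .validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (is.numeric(branch) && length(branch) == 1L) {
    node <- as.integer(branch)
  } else if (is.character(branch) && length(branch) == 1L &&
             !(branch %in% tree$tip.label)) {
    if (is.null(tree$node.label))
      stop("lookup error: tree has no internal node labels", call. = FALSE)
    hit <- which(tree$node.label == branch)
    if (length(hit) != 1L)
      stop("lookup error: node label '", branch, "' not found (or not unique)",
           call. = FALSE)
    node <- ntip + hit
  } else if (is.character(branch)) {
    if (length(branch) < 2L)
      stop("lookup error: a taxon-list branch specification needs >= 2 taxa",
           call. = FALSE)
    unknown <- setdiff(branch, tree$tip.label)
    if (length(unknown) > 0L)
      stop("lookup error: unknown taxon/taxa: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    node <- ape::getMRCA(tree, branch)
  } else {
    stop("lookup error: unsupported branch specification", call. = FALSE)
  }
  if (is.na(node) || node <= ntip || node > ntip + tree$Nnode)
    stop("lookup error: branch must identify an internal node", call. = FALSE)
  members <- ape::extract.clade(tree, node)$tip.label
  if (length(members) == 0L || length(members) >= ntip)
    stop("degenerate-bipartition error: branch leaves an empty side",
         call. = FALSE)
  members
}

#' Enumerate internal branches inducing usable bipartitions
#'
#' Returns, for every internal node whose clade is a proper subset of the
#' leaves, the node id and both sides of the induced bipartition.  Branches
#' with a side smaller than `min_class_size` are flagged ineligible.
#'
#' @param tree a `phylo` object.
#' @param min_class_size minimum leaves required on each side (default 2).
#' @return Data frame with columns `node`, `label`, `n_in`, `n_out`,
#'   `eligible`; attribute `members` holds the per-node clade leaf sets.
#' @export
internal_branches <- function(tree, min_class_size = 2L) {
  .validate_tree(tree)
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  members <- lapply(nodes, function(nd) ape::extract.clade(tree, nd)$tip.label)
  sizes <- lengths(members)
  keep <- sizes < ntip  # drop the root (clade = all leaves)
  nodes <- nodes[keep]; members <- members[keep]; sizes <- sizes[keep]
  labels <- if (!is.null(tree$node.label)) tree$node.label[nodes - ntip] else
    rep(NA_character_, length(nodes))
  out <- data.frame(node = nodes, label = labels,
                    n_in = sizes, n_out = ntip - sizes,
                    eligible = sizes >= min_class_size &
                      (ntip - sizes) >= min_class_size,
                    stringsAsFactors = FALSE)
  names(members) <- as.character(nodes)
  attr(out, "members") <- members
  out
}
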