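#' Lineage trees
#'
#' A lineage tree records the observed division history of a single founder
#' cell: every internal node is one cell dividing into exactly two
#' sublineages, and every leaf is a clone grown from a terminal cell and
#' bulk-sequenced. The tree is therefore rooted and strictly binary, with
#' uniquely labelled leaves. Branch lengths, if present in the Newick input,
#' are accepted and ignored: all downstream classification uses topology
#' only.
#'
#' Internally a `lineage_tree` wraps an [ape::read.tree()] `phylo` object
#' after validation.
#'
#' @param x a Newick string, a `phylo` object, or a `lineage_tree`.
#' @return an object of class `lineage_tree`.
#' @examples
#' tr <- lineage_tree("((A,B),(C,D));")
#' tree_leaves(tr)
#' @export
lineage_tree <- function(x) {
  if (inherits(x, "lineage_tree")) return(x)
  if (is.character(x)) {
    txt <- trimws(paste(x, collapse = ""))
    if (!nzchar(txt)) stop("empty Newick string")
    np <- sum(strsplit(txt, "")[[1]] == "(")
    nq <- sum(strsplit(txt, "")[[1]] == ")")
    if (np != nq)
      stop("unbalanced parentheses in Newick: ", np, " '(' vs ", nq, " ')'")
    phy <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(phy)) stop("malformed Newick: ", txt)
  } else if (inherits(x, "phylo")) {
    phy <- x
  } else {
    stop("cannot build a lineage_tree from class ", paste(class(x), collapse = "/"))
  }
  validate_lineage_tree(phy)
}

validate_lineage_tree <- function(phy) {
  if (is.null(phy$tip.label) || ape::Ntip(phy) < 2)
    stop("lineage tree needs at least 2 labelled leaves")
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup))
    stop("duplicate leaf labels: ", paste(unique(dup), collapse = ", "))
  ## strictly binary: every internal node has exactly 2 children (checked
  ## before rootedness so a trifurcating root reports as non-binary)
  kids <- tabulate(phy$edge[, 1], nbins = ape::Ntip(phy) + phy$Nnode)
  bad <- which(kids != 0 & kids != 2)
  if (length(bad)) {
    lab <- node_leafset(phy, bad[1])
    stop("non-binary internal node (", kids[bad[1]], " children) above leaves: ",
         paste(lab, collapse = ","))
  }
  if (!ape::is.rooted(phy)) stop("lineage tree must be rooted")
  if (phy$Nnode != ape::Ntip(phy) - 1)
    stop("internal node count ", phy$Nnode, " != leaves - 1")
  structure(list(phylo = phy), class = "lineage_tree")
}

node_leafset <- function(phy, node) {
  sort(phy$tip.label[phangorn::Descendants(phy, node, type = "tips")[[1]]])
}

#' @rdname lineage_tree
#' @param path path to a Newick file.
#' @export
read_lineage_tree <- function(path) {
  lineage_tree(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname lineage_tree
#' @param tree a `lineage_tree`.
#' @export
write_lineage_tree <- function(tree, path) {
  tree <- lineage_tree(tree)
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' @rdname lineage_tree
#' @export
tree_leaves <- function(tree) {
  lineage_tree(tree)$phylo$tip.label
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree:", ape::Ntip(x$phylo), "leaves,",
      x$phylo$Nnode, "internal nodes\n")
  cat("  leaves:", paste(sort(x$phylo$tip.label), collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.lineage_tree <- function(x, ...) ape::write.tree(x$phylo)

#' Sister leaf pairs
#'
#' The unordered leaf pairs whose parent node has two leaf children
#' (cherries). Sister samples share every lineage-validated variant, so
#' they cannot serve as tumor / mixed-in-normal assignments.
#'
#' @param tree a [lineage_tree()].
#' @return a list of sorted character vectors of length 2, ordered by first
#'   element.
#' @export
sister_pairs <- function(tree) {
  phy <- lineage_tree(tree)$phylo
  ntip <- ape::Ntip(phy)
  pairs <- list()
  for (node in unique(phy$edge[, 1])) {
    ch <- phy$edge[phy$edge[, 1] == node, 2]
    if (all(ch <= ntip))
      pairs[[length(pairs) + 1L]] <- sort(phy$tip.label[ch])
  }
  pairs[order(vapply(pairs, `[`, "", 1L))]
}

#' Clade leaf subsets
#'
#' One leaf subset per internal non-root node: the leaves below that node.
#' These are exactly the carrier sets a single branch mutation can produce,
#' sizes 2 to n-1; a rooted binary tree over n leaves has n-2 of them.
#'
#' @param tree a [lineage_tree()].
#' @return named list of sorted leaf-label vectors; names are internal node
#'   numbers of the underlying `phylo`.
#' @export
clade_subsets <- function(tree) {
  phy <- lineage_tree(tree)$phylo
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  nodes <- setdiff((ntip + 1L):(ntip + phy$Nnode), root)
  out <- lapply(nodes, function(nd) node_leafset(phy, nd))
  names(out) <- as.character(nodes)
  out
}

#' Lineage concordance of a carrier set
#'
#' A carrier set is lineage concordant when all carriers share a single
#' common ancestor and no non-carrier shares it, i.e. the carriers equal the
#' leaf set of some internal non-root node.
#'
#' @param tree a [lineage_tree()].
#' @param carriers character vector of leaf labels, 2 <= length <= n-1.
#' @return logical scalar.
#' @export
is_lineage_concordant <- function(tree, carriers) {
  tree <- lineage_tree(tree)
  leaves <- tree_leaves(tree)
  carriers <- unique(as.character(carriers))
  unknown <- setdiff(carriers, leaves)
  if (length(unknown))
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  if (length(carriers) < 2 || length(carriers) > length(leaves) - 1)
    stop("carrier set size ", length(carriers),
         " outside [2, ", length(leaves) - 1, "]")
  key <- paste(sort(carriers), collapse = "\r")
  key %in% vapply(clade_subsets(tree), paste, "", collapse = "\r")
}

#' Nearest relatives of a leaf
#'
#' The leaves of the sibling subtree of `leaf`, sorted lexicographically.
#' The first element is used as the matched normal when `leaf` is the
#' mixed-in normal of a tumor-normal mixture.
#'
#' @param tree a [lineage_tree()].
#' @param leaf a leaf label.
#' @return character vector of leaf labels.
#' @export
nearest_relatives <- function(tree, leaf) {
  phy <- lineage_tree(tree)$phylo
  i <- match(leaf, phy$tip.label)
  if (is.na(i)) stop("unknown leaf: ", leaf)
  parent <- phy$edge[phy$edge[, 2] == i, 1]
  sib <- setdiff(phy$edge[phy$edge[, 1] == parent, 2], i)
  if (sib <= ape::Ntip(phy)) phy$tip.label[sib] else node_leafset(phy, sib)
}

#' The 11-leaf HT115 lineage fixture
#'
#' The lineage tree of the HT115 colon-cancer cell line used throughout the
#' examples: 11 leaves with five sister pairs (S57/S56, S45/S48, S63/S49,
#' S44/S34, S47/S54) and S38 sibling to the (S45,S48) clade. Topology above
#' those nodes is not determined by the published constraints and is fixed
#' arbitrarily in the shipped Newick.
#'
#' @return a [lineage_tree()] with 11 leaves.
#' @export
ht115_tree <- function() {
  read_lineage_tree(system.file("extdata", "ht115_tree.nwk",
                                package = "lineagetruth", mustWork = TRUE))
}
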