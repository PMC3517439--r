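#' Serialize a tree to Newick text
#'
#' Branch lengths are written as `:<float>` and bootstrap supports (if
#' present as `node.label`) as internal-node labels, the convention used by
#' MEGA-era distance phylogenetics. `read_newick(write_newick(t))`
#' preserves topology, branch lengths (to 6 decimals) and supports.
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return Newick string (invisibly, if written to `path`).
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object")
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse Newick text or file
#'
#' @param x A Newick string or a path to a Newick file.
#' @return An `ape::phylo` object; internal-node labels are kept (they carry
#'   bootstrap supports).
#' @export
read_newick <- function(x) {
  tree <- if (length(x) == 1 && file.exists(x) && !grepl("\\(", x)) {
    ape::read.tree(x)
  } else if (length(x) == 1 && grepl("\\(", x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(tree)) abort("could not parse Newick input")
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels in tree")
  tree
}

#' Node ages of an ultrametric species tree
#'
#' @param tree Rooted, ultrametric `phylo` with branch lengths in MY.
#' @return Tibble with `node` (internal node number) and `age_mya`.
#' @export
species_node_ages <- function(tree) {
  validate_species_tree(tree)
  bt <- ape::branching.times(tree)
  tibble(node = as.integer(names(bt)), age_mya = unname(bt))
}

#' @noRd
validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) abort("species tree needs branch lengths (MY)")
  if (!ape::is.rooted(tree)) abort("species tree must be rooted")
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    abort("species tree must be ultrametric (all leaves at age 0)")
  }
  invisible(tree)
}

#' Divergence time of two species on an ultrametric tree
#'
#' @param tree Rooted ultrametric `phylo` with branch lengths in MY.
#' @param a,b Leaf labels.
#' @return Split age in MYA (age of the most recent common ancestor).
#' @export
species_split_age <- function(tree, a, b) {
  validate_species_tree(tree)
  missing <- setdiff(c(a, b), tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("unknown leaf label: %s", paste(missing, collapse = ", ")))
  }
  if (a == b) return(0)
  node <- ape::getMRCA(tree, c(a, b))
  bt <- ape::branching.times(tree)
  unname(bt[as.character(node)])
}
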