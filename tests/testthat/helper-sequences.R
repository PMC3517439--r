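# Shared fixtures built in code: engineered K2P pairs, random alignments,
# additive distance matrices, and small independent oracles.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# pair of sequences with exactly `ts` transitions and `tv` transversions
# over `sites` comparable sites (reference is poly-A)
engineered_pair <- function(sites, ts, tv) {
  a <- rep("A", sites)
  b <- a
  if (ts > 0) b[seq_len(ts)] <- "G"                     # A->G transitions
  if (tv > 0) b[ts + seq_len(tv)] <- "C"                # A->C transversions
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# independent K2P oracle: direct evaluation of the closed form
k2p_oracle <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# large-sample SE of the K2P distance estimate at true (P, Q) (delta method)
k2p_se <- function(P, Q, L) {
  a <- 1 / (1 - 2 * P - Q)
  b <- 0.5 * (1 / (1 - 2 * P - Q) + 1 / (1 - 2 * Q))
  sqrt((a^2 * P + b^2 * Q - (a * P + b * Q)^2) / L)
}

# additive distance matrix of a random tree, plus the generating tree
random_additive_case <- function(ntaxa) {
  tr <- ape::rtree(ntaxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.01, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

same_unrooted_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# alignment of two clearly separated clades (for bootstrap checks)
two_clade_alignment <- function(n_per_clade = 3, L = 2000,
                                within = 0.01, between = 0.5) {
  anc1 <- tedater::random_ancestor(L, id = "anc1")
  anc2 <- tedater::mutate_sequence(anc1, between, id = "anc2")
  rows <- list()
  for (i in seq_len(n_per_clade)) {
    rows[[length(rows) + 1]] <-
      tedater::mutate_sequence(anc1, within, id = paste0("cladeA_", i))
    rows[[length(rows) + 1]] <-
      tedater::mutate_sequence(anc2, within, id = paste0("cladeB_", i))
  }
  dplyr::bind_rows(rows)
}

# brute-force Dollo oracle: minimal number of cut edges under the MRCA of
# the presence set such that exactly the absent leaves are disconnected
dollo_bruteforce <- function(tree, present_in) {
  ntip <- length(tree$tip.label)
  pres <- match(present_in, tree$tip.label)
  if (length(pres) == 1) return(0L)
  mrca <- ape::getMRCA(tree, present_in)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  clade_tips <- tips_under(mrca)
  absent <- setdiff(clade_tips, pres)
  # candidate loss edges: all edges inside the MRCA clade
  inside <- function(node) {
    out <- list()
    for (ch in children[[as.character(node)]]) {
      out[[length(out) + 1]] <- ch
      if (ch > ntip) out <- c(out, inside(ch))
    }
    out
  }
  edges <- unlist(inside(mrca))
  for (k in 0:length(edges)) {
    combos <- utils::combn(length(edges), k, simplify = FALSE)
    for (cut in combos) {
      lost <- unique(unlist(lapply(edges[cut], tips_under)))
      if (setequal(lost, absent)) return(k)
    }
  }
  length(absent)
}
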