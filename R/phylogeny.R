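# Distance-matrix phylogenetics: K2P matrices, Saitou-Nei neighbor joining
# with the Studier-Keppler Q-criterion, and Felsenstein column-resampling
# bootstrap supports.

# fast pairwise K2P on pre-split character rows; returns NA when saturated
# or when no comparable sites remain
k2p_from_chars <- function(ca, cb) {
  cmp <- ca %in% DNA_BASES4 & cb %in% DNA_BASES4
  sites <- sum(cmp)
  if (sites == 0) return(c(d = NA_real_, sites = 0))
  a <- ca[cmp]
  b <- cb[cmp]
  diff <- a != b
  ts <- sum(diff & b == unname(TRANSITION_PARTNER[a]))
  P <- ts / sites
  Q <- (sum(diff) - ts) / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(c(d = NA_real_, sites = sites))
  c(d = -0.5 * log(w1) - 0.25 * log(w2), sites = sites)
}

#' K2P distance matrix of an alignment
#'
#' Pairwise K2P distances with pairwise deletion: each pair is compared
#' over the columns where both residues are unambiguous bases.
#'
#' @param aln Alignment tibble with >= 3 members.
#' @param on_incomplete `"error"` (default) to fail, listing the offending
#'   pairs, when any pair is saturated or shares no comparable columns
#'   (neighbor joining needs a complete matrix); `"na"` to leave `NA`s.
#' @return Symmetric numeric matrix (substitutions/site) with taxon
#'   dimnames.
#' @export
distance_matrix <- function(aln, on_incomplete = c("error", "na")) {
  on_incomplete <- match.arg(on_incomplete)
  aln <- as_te_alignment(aln)
  if (nrow(aln) < 3) abort("distance matrix needs >= 3 sequences")
  res <- dm_from_char_matrix(seq_char_matrix(aln))
  if (length(res$bad) > 0 && on_incomplete == "error") {
    abort(sprintf("incomparable or saturated pairs: %s",
                  paste(res$bad, collapse = ", ")))
  }
  res$D
}

dm_from_char_matrix <- function(m) {
  n <- nrow(m)
  ids <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  bad <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- k2p_from_chars(m[i, ], m[j, ])
      if (is.na(v[["d"]])) {
        bad <- c(bad, sprintf("%s/%s", ids[i], ids[j]))
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- v[["d"]]
      }
    }
  }
  list(D = D, bad = bad)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' `Q(i,j) = (m-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`; branch lengths
#' from the standard two-point formulas. Negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch. Ties
#' in `Q` are broken by the lexicographically smallest label pair (each
#' cluster is identified by its smallest member label), so the result is
#' deterministic and invariant to taxon input order. An all-zero matrix
#' yields a star tree.
#'
#' @param dm Complete symmetric distance matrix with dimnames.
#' @return Unrooted `phylo`.
#' @export
neighbor_joining <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) abort("`dm` must be a square matrix")
  if (anyNA(dm)) abort("distance matrix has missing entries")
  if (max(abs(dm - t(dm))) > 1e-12) abort("distance matrix is not symmetric")
  n <- nrow(dm)
  if (n < 3) abort("neighbor joining needs >= 3 taxa")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  if (all(dm == 0)) {
    return(ape::read.tree(text = paste0(
      "(", paste0(labels, ":0", collapse = ","), ");")))
  }
  # active clusters: newick fragment + tie-break key (smallest member label)
  nwk <- labels
  key <- labels
  D <- dm
  fmt <- function(x) sprintf("%.10g", x)
  while (length(nwk) > 3) {
    m <- length(nwk)
    r <- rowSums(D)
    Qm <- (m - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- vapply(seq_len(nrow(cand)), function(k) {
      p <- sort(c(key[cand[k, 1]], key[cand[k, 2]]))
      paste(p, collapse = "\r")
    }, character(1))
    pick <- cand[order(pair_key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    new_key <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    dimnames(D) <- NULL
  }
  # resolve the final three clusters around the central node
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(va, vb, vc), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], fmt(v[1]), nwk[2], fmt(v[2]), nwk[3], fmt(v[3]))
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `replicates` times, rebuilding the matrix and tree each
#' time. Replicates in which any pair becomes saturated or incomparable
#' are dropped (and counted). Support for each internal edge of the
#' full-data tree is the percentage of retained replicates whose tree
#' contains that bipartition, rounded to integer and stored as
#' `node.label`.
#'
#' @param aln Alignment tibble with >= 4 members.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Seed for column resampling.
#' @return `phylo` with integer supports as `node.label` and attributes
#'   `replicates_used` / `replicates_dropped`.
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1L) {
  aln <- as_te_alignment(aln)
  if (nrow(aln) < 4) abort("bootstrap needs >= 4 sequences")
  D <- distance_matrix(aln)
  main <- neighbor_joining(D)
  if (main$Nnode <= 1) {
    # star tree: no internal edges to support
    attr(main, "replicates_used") <- 0L
    attr(main, "replicates_dropped") <- 0L
    return(main)
  }
  m <- seq_char_matrix(aln)
  L <- ncol(m)
  trees <- withr::with_seed(seed, {
    map(seq_len(replicates), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      Db <- dm_from_char_matrix(m[, cols, drop = FALSE])$D
      if (anyNA(Db)) return(NULL)
      neighbor_joining(Db)
    })
  })
  dropped <- sum(vapply(trees, is.null, logical(1)))
  trees <- trees[!vapply(trees, is.null, logical(1))]
  if (dropped > replicates / 2) {
    abort("alignment too saturated for bootstrap (>50% replicates dropped)")
  }
  counts <- ape::prop.clades(main, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round_half_up(100 * counts / length(trees))
  lab <- as.character(support)
  lab[1] <- ""  # basal trifurcation carries no bipartition
  main$node.label <- lab
  attr(main, "replicates_used") <- length(trees)
  attr(main, "replicates_dropped") <- dropped
  main
}
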