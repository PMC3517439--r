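test_that("distance matrices are exact on engineered alignments", {
  aln <- tibble::tibble(id = c("a", "b", "c"),
                        seq = c(strrep("A", 1000),
                                engineered_pair(1000, 100, 50)$b,
                                engineered_pair(1000, 50, 20)$b))
  D <- distance_matrix(aln)
  expect_equal(D["a", "b"], k2p_oracle(0.1, 0.05), tolerance = 1e-12)
  expect_equal(D["a", "c"], k2p_oracle(0.05, 0.02), tolerance = 1e-12)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), aln$id))
})

test_that("identical sequences give the zero matrix", {
  aln <- tibble::tibble(id = c("a", "b", "c"), seq = rep("ACGTACGT", 3))
  expect_true(all(distance_matrix(aln) == 0))
})

test_that("incomparable pairs are reported by name", {
  aln <- tibble::tibble(id = c("a", "b", "c"),
                        seq = c("AANN", "NNAA", "AAAA"))
  expect_error(distance_matrix(aln), "a/b")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")],
               c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("NJ recovers additive four-taxon trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> hand-built additive distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- neighbor_joining(D)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_true(same_unrooted_topology(tr, ref))
  expect_equal(sort(tr$edge.length), sort(ref$edge.length), tolerance = 1e-9)
})

test_that("NJ is consistent on random additive five-taxon matrices", {
  withr::with_seed(101, {
    for (i in 1:30) {
      case <- random_additive_case(5)
      tr <- neighbor_joining(case$D)
      expect_true(same_unrooted_topology(tr, case$tree))
    }
  })
})

test_that("NJ agrees with an independent reference implementation", {
  withr::with_seed(19, {
    anc <- random_ancestor(1500)
    aln <- dplyr::bind_rows(lapply(1:6, function(i) {
      mutate_sequence(anc, runif(1, 0.05, 0.3), id = paste0("t", i))
    }))
  })
  D <- distance_matrix(aln)
  expect_true(same_unrooted_topology(neighbor_joining(D), ape::nj(D)))
})

test_that("taxon input order changes neither topology nor branch lengths", {
  withr::with_seed(29, {
    case <- random_additive_case(6)
  })
  tr1 <- neighbor_joining(case$D)
  perm <- sample(rownames(case$D))
  tr2 <- neighbor_joining(case$D[perm, perm])
  expect_true(same_unrooted_topology(tr1, tr2))
  expect_equal(sort(tr1$edge.length), sort(tr2$edge.length), tolerance = 1e-9)
})

test_that("NJ trees are unrooted with n leaves and rejects bad matrices", {
  withr::with_seed(41, {
    case <- random_additive_case(8)
  })
  tr <- neighbor_joining(case$D)
  expect_equal(length(tr$tip.label), 8)
  expect_equal(tr$Nnode, 6)  # unrooted binary: n - 2 internal nodes
  bad <- case$D
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(neighbor_joining(bad), "not symmetric")
})

test_that("bootstrap gives full support to an unambiguous split", {
  for (seed in c(1, 2)) {
    aln <- withr::with_seed(300 + seed, two_clade_alignment())
    tr <- bootstrap_support(aln, replicates = 100, seed = seed)
    # the clade bipartition must carry 100% support
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    sup <- as.numeric(tr$node.label[tr$node.label != ""])
    expect_true(all(sup >= 0 & sup <= 100))
    clade_a <- sort(grep("cladeA", labs))
    found <- any(vapply(seq_along(parts)[-1], function(k) {
      s <- sort(parts[[k]])
      (identical(s, clade_a) || identical(s, sort(setdiff(seq_along(labs), clade_a)))) &&
        tr$node.label[k] == "100"
    }, logical(1)))
    expect_true(found)
  }
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  aln <- withr::with_seed(55, two_clade_alignment(n_per_clade = 2, L = 800))
  t1 <- bootstrap_support(aln, replicates = 50, seed = 9)
  t2 <- bootstrap_support(aln, replicates = 50, seed = 9)
  expect_identical(write_newick(t1), write_newick(t2))
})

test_that("an alignment of identical sequences yields a star tree", {
  aln <- tibble::tibble(id = paste0("t", 1:5), seq = rep(strrep("ACGT", 50), 5))
  tr <- bootstrap_support(aln, replicates = 20, seed = 1)
  expect_equal(tr$Nnode, 1)
  expect_null(tr$node.label)
})

test_that("saturated alignments abort the bootstrap", {
  sat <- engineered_pair(200, ts = 90, tv = 40)
  aln <- tibble::tibble(id = paste0("t", 1:4),
                        seq = c(sat$a, sat$b,
                                engineered_pair(200, 95, 40)$b,
                                engineered_pair(200, 85, 44)$b))
  expect_error(bootstrap_support(aln, replicates = 20, seed = 1), "")
})
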