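test_that("copies identical to the consensus give 0 +/- 0 (n)", {
  copies <- tibble::tibble(id = paste0("c", 1:10), seq = rep("ACGTACGTAC", 10))
  res <- family_divergence(copies, "ACGTACGTAC")
  expect_equal(res, tibble::tibble(divergence_pct = 0, divergence_sd_pct = 0,
                                   n_sampled = 10L))
})

test_that("mean and sample SD match hand-computed per-copy distances", {
  # two copies with exact substitution counts; expected values computed
  # with the closed-form oracle on those counts
  cons <- strrep("A", 1000)
  c1 <- engineered_pair(1000, ts = 91, tv = 0)$b    # d ~ 0.100
  c2 <- engineered_pair(1000, ts = 165, tv = 0)$b   # d ~ 0.200
  d1 <- k2p_oracle(0.091, 0)
  d2 <- k2p_oracle(0.165, 0)
  res <- family_divergence(tibble::tibble(id = c("c1", "c2"), seq = c(c1, c2)),
                           cons)
  expect_equal(res$divergence_pct, 100 * mean(c(d1, d2)), tolerance = 1e-12)
  expect_equal(res$divergence_sd_pct, 100 * stats::sd(c(d1, d2)),
               tolerance = 1e-12)
  expect_equal(res$n_sampled, 2L)
  # values land near the 15 +/- 7 pattern of a {10%, 20%} copy pair
  expect_equal(res$divergence_pct, 15.03, tolerance = 0.01)
  expect_equal(res$divergence_sd_pct, 7.06, tolerance = 0.01)
})

test_that("copies below the coverage threshold are excluded", {
  cons <- strrep("ACGT", 25)                        # 100 bases
  full <- cons
  half <- paste0(substr(cons, 1, 50), strrep("-", 50))  # 50% coverage
  copies <- tibble::tibble(id = c("full", "half"), seq = c(full, half))
  res <- family_divergence(copies, cons, min_coverage = 0.7)
  expect_equal(res$n_sampled, 1L)
  expect_error(family_divergence(copies[2, ], cons, min_coverage = 0.7),
               "coverage")
})

test_that("random subsampling of copies is reproducible with a seed", {
  withr::with_seed(21, {
    anc <- random_ancestor(400)
    copies <- dplyr::bind_rows(lapply(1:12, function(i) {
      mutate_sequence(anc, 0.1, id = paste0("c", i))
    }))
  })
  r1 <- family_divergence(copies, anc, sample_size = 5, seed = 99)
  r2 <- family_divergence(copies, anc, sample_size = 5, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$n_sampled, 5L)
})

test_that("family_observation assembles a full per-family record", {
  b <- simulate_burst(burst_scenario(ancestral_length = 600, burst_age = 50,
                                     copy_count = 20, rate = 0.002, seed = 8),
                      family = "famA")
  obs <- family_observation(b$copies, family = "famA", genome = "gnm")
  expect_equal(obs$family, "famA")
  expect_equal(obs$consensus_length, 600)
  expect_equal(obs$copy_number, 20)
  expect_equal(obs$n_sampled, 20L)
  # true expected divergence is rate x age = 10%
  expect_equal(obs$divergence_pct, 10, tolerance = 2)
  expect_equal(format_divergence(15.04, 2.2, 183), "15.0 ± 2 (183)")
})
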