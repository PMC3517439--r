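test_that("zero distance leaves the sequence unchanged", {
  s <- "ACGTACGTACGT"
  expect_equal(mutate_sequence(s, 0)$seq, s)
  expect_error(mutate_sequence(s, -0.1), "non-negative")
  expect_error(mutate_sequence("AC-GT", 0.1), "gap-free")
})

test_that("mutation reproduces the K80 closed forms at moderate distance", {
  L <- 20000
  d <- 0.1
  withr::with_seed(31, {
    anc <- random_ancestor(L)
    mut <- mutate_sequence(anc, d, kappa = 2)
  })
  est <- k2p_distance(anc, mut)
  probs <- k80_site_probs(d, kappa = 2)
  expect_lt(abs(est$P - probs$P), 3 * sqrt(probs$P * (1 - probs$P) / L))
  expect_lt(abs(est$Q - probs$Q), 3 * sqrt(probs$Q * (1 - probs$Q) / L))
  expect_lt(abs(est$d - d), 3 * k2p_se(probs$P, probs$Q, L))
})

test_that("deep time saturates to 1/4 identical sites", {
  L <- 50000
  withr::with_seed(37, {
    anc <- random_ancestor(L)
    mut <- mutate_sequence(anc, 30)
  })
  frac_same <- mean(strsplit(anc$seq, "")[[1]] == strsplit(mut$seq, "")[[1]])
  expect_lt(abs(frac_same - 0.25), 3 * sqrt(0.25 * 0.75 / L))
})

test_that("the K2P estimator is consistent on simulated mutation", {
  # mean estimate over replicates within 2% relative error of the truth
  for (d in c(0.05, 0.1, 0.2)) {
    ests <- withr::with_seed(1000 + round(1000 * d), {
      vapply(1:30, function(i) {
        anc <- random_ancestor(30000)
        k2p_distance(anc, mutate_sequence(anc, d))$d
      }, numeric(1))
    })
    expect_lt(abs(mean(ests) - d) / d, 0.02)
  }
})

test_that("burst simulation matches its scenario and is deterministic", {
  sc <- burst_scenario(ancestral_length = 800, burst_age = 0, copy_count = 5,
                       seed = 2)
  b0 <- simulate_burst(sc)
  expect_true(all(b0$copies$seq == b0$ancestor$seq))
  expect_equal(nrow(simulate_burst(burst_scenario(copy_count = 1))$copies), 1)

  b1 <- simulate_burst(burst_scenario(seed = 77))
  b2 <- simulate_burst(burst_scenario(seed = 77))
  expect_identical(b1$copies, b2$copies)
  b3 <- simulate_burst(burst_scenario(seed = 78))
  expect_false(identical(b1$copies, b3$copies))
})

test_that("mean copy divergence tracks rate x age", {
  b <- simulate_burst(burst_scenario(ancestral_length = 2000, burst_age = 100,
                                     copy_count = 50, rate = 0.001, seed = 5))
  g <- glance(b)
  se <- stats::sd(tidy(b)$d) / sqrt(g$n_copies)
  expect_lt(abs(g$mean_d - 0.1), 3 * se)
})

test_that("expected divergence grows linearly with age", {
  ages <- c(25, 50, 100)
  mean_d <- vapply(seq_along(ages), function(i) {
    b <- simulate_burst(burst_scenario(ancestral_length = 20000,
                                       burst_age = ages[i], copy_count = 10,
                                       rate = 0.002, seed = 40 + i))
    mean(tidy(b)$d)
  }, numeric(1))
  slope <- stats::coef(stats::lm(mean_d ~ ages))[["ages"]]
  expect_lt(abs(slope - 0.002) / 0.002, 0.05)
})

test_that("indels change copy lengths only when enabled", {
  b <- simulate_burst(burst_scenario(ancestral_length = 500, copy_count = 10,
                                     indel_rate = 0.01, seed = 4))
  expect_gt(length(unique(nchar(b$copies$seq))), 1)
  b0 <- simulate_burst(burst_scenario(ancestral_length = 500, copy_count = 10,
                                      seed = 4))
  expect_equal(unique(nchar(b0$copies$seq)), 500)
})

test_that("HT simulation places the focal family per the scenario", {
  sim <- simulate_ht_scenario(ht_scenario(seed = 3))
  expect_setequal(names(sim$copies), c("ant_A", "shrew"))
  expect_setequal(sim$truth$family, c("focal", "calibration"))
  expect_equal(sim$truth$true_age[sim$truth$genome == "shrew" &
                                    sim$truth$family == "focal"], 80)
  expect_equal(sim$truth$true_age[sim$truth$genome == "ant_A" &
                                    sim$truth$family == "focal"], 150)
  # determinism: same seed, byte-identical output files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_ht_sim(simulate_ht_scenario(ht_scenario(seed = 3)), d1)
  write_ht_sim(simulate_ht_scenario(ht_scenario(seed = 3)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a transfer at the burst age makes native and recipient copies exchangeable", {
  for (seed in c(11, 12, 13)) {
    sc <- ht_scenario(transfer_age = 150,
                      focal_burst = burst_scenario(burst_age = 150),
                      seed = seed)
    sim <- simulate_ht_scenario(sc)
    d_native <- copy_divergences(sim$copies$ant_A$focal, sim$ancestors$focal)$d
    d_recip <- copy_divergences(sim$copies$shrew$focal, sim$ancestors$focal)$d
    expect_gt(stats::wilcox.test(d_native, d_recip)$p.value, 0.01)
  }
})

test_that("without recipients the focal family exists only in the native genome", {
  sc <- ht_scenario(recipient_lineages = character(0), seed = 6)
  sim <- simulate_ht_scenario(sc)
  expect_equal(names(sim$copies), "ant_A")
  expect_true("focal" %in% names(sim$copies$ant_A))
  expect_error(ht_scenario(recipient_lineages = "martian"), "not in species tree")
})
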