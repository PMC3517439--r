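# Synthetic TE family histories: amplification bursts of known age under a
# site-independent K80 substitution process, plus horizontal-transfer
# scenarios that seed a young family into a recipient genome. Every
# downstream stage can be validated against the ground truth these emit.

TRANSVERSION_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                              C = c("A", "G"), T = c("A", "G"))

#' Define a TE amplification burst
#'
#' @param ancestral_length Element length in sites.
#' @param burst_age Age of the burst in MYA.
#' @param copy_count Number of copies inserted at the burst.
#' @param rate Neutral substitution rate, substitutions/site/MY.
#' @param kappa Transition/transversion rate ratio (alpha/beta).
#' @param indel_rate Indel events/site applied after substitution
#'   (geometric lengths, mean 3); default 0 so distances stay closed-form.
#' @param seed Seed making the burst reproducible.
#' @return A `te_burst_scenario` list.
#' @export
burst_scenario <- function(ancestral_length = 1300, burst_age = 100,
                           copy_count = 50, rate = 0.002, kappa = 2,
                           indel_rate = 0, seed = 1L) {
  stopifnot(ancestral_length >= 1, burst_age >= 0, copy_count >= 1,
            rate >= 0, kappa > 0, indel_rate >= 0)
  structure(list(ancestral_length = as.integer(ancestral_length),
                 burst_age = burst_age, copy_count = as.integer(copy_count),
                 rate = rate, kappa = kappa, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "te_burst_scenario")
}

#' Random ancestral element with uniform base composition
#'
#' @param length Sites.
#' @param id Sequence id.
#' @return One-row sequence tibble.
#' @export
random_ancestor <- function(length, id = "ancestor") {
  seq_tbl(id, chars_to_string(sample(DNA_BASES4, length, replace = TRUE)))
}

#' Evolve a sequence under the K80 model for a given distance
#'
#' Each site is resampled independently using the exact K80 transition
#' probabilities at total divergence `d` (see [k80_site_probs()]), so the
#' estimated K2P distance between input and output converges to `distance`
#' as the length grows. `N` sites are carried through unchanged.
#'
#' @param seq Gap-free sequence (string or 1-row tibble).
#' @param distance Expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @param id Id for the mutated sequence.
#' @return One-row sequence tibble.
#' @export
mutate_sequence <- function(seq, distance, kappa = 2, id = NULL) {
  s <- seq_string(seq)
  if (grepl("-", s, fixed = TRUE)) abort("`seq` must be gap-free")
  if (!is.numeric(distance) || length(distance) != 1 || distance < 0) {
    abort("`distance` must be a single non-negative number")
  }
  id <- id %||% "mutant"
  if (distance == 0) return(seq_tbl(id, s))
  probs <- k80_site_probs(distance, kappa)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  u <- runif(L)
  mutable <- ch %in% DNA_BASES4
  is_ts <- mutable & u < probs$P
  is_tv <- mutable & u >= probs$P & u < probs$P + probs$Q
  if (any(is_ts)) ch[is_ts] <- unname(TRANSITION_PARTNER[ch[is_ts]])
  if (any(is_tv)) {
    # second half of the Q band picks the second transversion partner
    pick2 <- u[is_tv] >= probs$P + probs$Q / 2
    orig <- ch[is_tv]
    ch[is_tv] <- vapply(seq_along(orig), function(i) {
      TRANSVERSION_PARTNERS[[orig[i]]][1 + pick2[i]]
    }, character(1))
  }
  seq_tbl(id, chars_to_string(ch))
}

# geometric-length indels (mean 3), insertions and deletions equiprobable
apply_indels <- function(s, indel_rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n_events <- rbinom(1, length(ch), indel_rate)
  for (k in seq_len(n_events)) {
    len <- stats::rgeom(1, 1 / 3) + 1
    pos <- sample.int(length(ch), 1)
    if (runif(1) < 0.5) {
      ch <- ch[-(pos:min(pos + len - 1, length(ch)))]
      if (length(ch) == 0) ch <- sample(DNA_BASES4, 1)
    } else {
      ch <- append(ch, sample(DNA_BASES4, len, replace = TRUE), after = pos)
    }
  }
  chars_to_string(ch)
}

#' Simulate one amplification burst
#'
#' Draws a random ancestor and emits `copy_count` copies, each an
#' independent K80 draw at distance `rate * burst_age` from the ancestor
#' (a star phylogeny within the family, the model under which
#' mean-divergence dating is unbiased).
#'
#' @param scenario A [burst_scenario()].
#' @param family Family label used in copy ids.
#' @return A `te_burst` list: `ancestor` and `copies` sequence tibbles plus
#'   the scenario. With `indel_rate = 0` the copies are already aligned
#'   (equal length, gap-free).
#' @export
simulate_burst <- function(scenario, family = "family") {
  stopifnot(inherits(scenario, "te_burst_scenario"))
  withr::with_seed(scenario$seed, {
    anc <- random_ancestor(scenario$ancestral_length,
                           id = paste0(family, "_ancestor"))
    d <- scenario$rate * scenario$burst_age
    copies <- map(seq_len(scenario$copy_count), function(i) {
      s <- mutate_sequence(anc, d, scenario$kappa,
                           id = sprintf("%s_copy%03d", family, i))
      if (scenario$indel_rate > 0) s$seq <- apply_indels(s$seq, scenario$indel_rate)
      s
    })
    structure(list(ancestor = anc, copies = bind_rows(copies),
                   scenario = scenario, family = family),
              class = "te_burst")
  })
}

#' Define a horizontal-transfer scenario
#'
#' A focal TE family bursts in the native lineage at `focal_burst$burst_age`
#' MYA and is horizontally transferred into the recipient lineages at
#' `transfer_age` MYA, where it bursts on arrival. Every genome also carries
#' its own old calibration family, inherited vertically from the species'
#' common ancestor, which bursts at `calibration_burst$burst_age` in each
#' genome. The active master element is treated as conserved (selection on
#' an active transposase), so recipient copies diverge from the shared
#' ancestral element by `rate * transfer_age`.
#'
#' @param species_tree Rooted ultrametric `phylo`, branch lengths in MY.
#' @param native_lineage Leaf carrying the focal family since its burst.
#' @param recipient_lineages Leaves that receive the focal family by HT.
#' @param transfer_age HT age in MYA; must be below the focal burst age.
#' @param focal_burst,calibration_burst [burst_scenario()]s (the
#'   calibration scenario is applied per genome).
#' @param seed Master seed.
#' @return A `te_ht_scenario` list.
#' @export
ht_scenario <- function(species_tree = default_species_tree(),
                        native_lineage = "ant_A",
                        recipient_lineages = "shrew",
                        transfer_age = 80,
                        focal_burst = burst_scenario(burst_age = 150),
                        calibration_burst = burst_scenario(burst_age = 145),
                        seed = 1L) {
  validate_species_tree(species_tree)
  missing <- setdiff(c(native_lineage, recipient_lineages), species_tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("lineage not in species tree: %s", paste(missing, collapse = ", ")))
  }
  if (transfer_age > focal_burst$burst_age) {
    abort("transfer_age must not exceed the focal burst age")
  }
  structure(list(species_tree = species_tree, native_lineage = native_lineage,
                 recipient_lineages = recipient_lineages,
                 transfer_age = transfer_age, focal_burst = focal_burst,
                 calibration_burst = calibration_burst, seed = as.integer(seed)),
            class = "te_ht_scenario")
}

#' Toy mammal/insect species tree (ultrametric, MY)
#'
#' Two insect and two mammal lineages separated by a deep (1000 MY) split.
#' @return `phylo`.
#' @export
default_species_tree <- function() {
  read_newick("((ant_A:100,ant_B:100):900,(shrew:100,hedgehog:100):900);")
}

#' Simulate a horizontal-transfer scenario
#'
#' @param scenario An [ht_scenario()].
#' @return A `te_ht_sim` list: `copies[[genome]][[family]]` sequence
#'   tibbles, `ancestors`, and a ground-truth tibble `truth` with one row
#'   per (genome, family) recording role, true burst age and rate, plus
#'   the HT edges.
#' @export
simulate_ht_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "te_ht_scenario"))
  genomes <- c(scenario$native_lineage, scenario$recipient_lineages)
  fb <- scenario$focal_burst
  cb <- scenario$calibration_burst
  root_age <- max(ape::branching.times(scenario$species_tree))
  withr::with_seed(scenario$seed, {
    focal_anc <- random_ancestor(fb$ancestral_length, id = "focal_ancestor")
    calib_anc <- random_ancestor(cb$ancestral_length, id = "calibration_ancestor")
    copies <- list()
    truth <- list()
    for (g in genomes) {
      is_native <- g == scenario$native_lineage
      age <- if (is_native) fb$burst_age else scenario$transfer_age
      d <- fb$rate * age
      fam_copies <- bind_rows(map(seq_len(fb$copy_count), function(i) {
        mutate_sequence(focal_anc, d, fb$kappa,
                        id = sprintf("%s_focal_copy%03d", g, i))
      }))
      # calibration family descends vertically: the master drifts from the
      # shared ancestor until its in-genome burst, then copies radiate
      master <- mutate_sequence(calib_anc,
                                cb$rate * max(root_age - cb$burst_age, 0),
                                cb$kappa, id = paste0(g, "_calibration_master"))
      cal_copies <- bind_rows(map(seq_len(cb$copy_count), function(i) {
        mutate_sequence(master, cb$rate * cb$burst_age, cb$kappa,
                        id = sprintf("%s_calibration_copy%03d", g, i))
      }))
      copies[[g]] <- list(focal = fam_copies, calibration = cal_copies)
      truth[[g]] <- tibble(
        genome = g, family = c("focal", "calibration"),
        role = c(if (is_native) "native" else "recipient", "calibration"),
        true_age = c(age, cb$burst_age),
        rate = c(fb$rate, cb$rate),
        n_copies = c(fb$copy_count, cb$copy_count)
      )
    }
    ht_edges <- tibble(from = scenario$native_lineage,
                       to = scenario$recipient_lineages,
                       transfer_age = scenario$transfer_age)
    structure(list(copies = copies, truth = bind_rows(truth),
                   ancestors = list(focal = focal_anc, calibration = calib_anc),
                   ht_edges = ht_edges, scenario = scenario),
              class = "te_ht_sim")
  })
}

#' Write a simulated HT scenario to disk
#'
#' One FASTA per (genome, family) plus a TSV ground-truth table.
#'
#' @param sim A `te_ht_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ht_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "te_ht_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$copies)) {
    for (fam in names(sim$copies[[g]])) {
      write_te_fasta(sim$copies[[g]][[fam]],
                     file.path(dir, sprintf("%s_%s.fasta", g, fam)))
    }
  }
  readr::write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"))
  write_newick(sim$scenario$species_tree, file.path(dir, "species_tree.nwk"))
  invisible(dir)
}
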