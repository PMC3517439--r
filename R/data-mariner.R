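# Bundled study inputs for the Mariner horizontal-transfer case: published
# per-family divergence summaries and the phylogenetic calibration priors
# (age windows and caps) they are dated against. Genome codes: TBel tree
# shrew, EEu European hedgehog, BT cow, TTr bottlenose dolphin, PBa red
# harvester ant, HSa Jerdon's jumping ant, SIn fire ant.

#' Published Mariner family divergence table
#'
#' Family length, copy number and mean +/- SD (n) K2P divergence of each
#' Mariner-type family per genome, as published for the mammal/insect HT
#' case. Copy numbers are the published lower bounds (kept as text).
#'
#' @return Tibble: `family`, `genome`, `length_bp`, `copy_number`,
#'   `divergence_pct`, `divergence_sd_pct`, `n_sampled`.
#' @export
mariner_divergences <- function() {
  readr::read_tsv(pkg_extdata("mariner_family_divergence.tsv"),
                  col_types = readr::cols(
                    family = "c", genome = "c", length_bp = "i",
                    copy_number = "c", divergence_pct = "d",
                    divergence_sd_pct = "d", n_sampled = "i"))
}

#' Calibration windows for the Mariner dating analysis
#'
#' TIGGER1 (bracketed by the marsupial-placental split at 190 MYA and the
#' placental radiation at ~100 MYA) calibrates the mammalian genomes;
#' Mariner-28_SIn at the ant common-ancestor age (140 MYA, an outermost
#' age, hence a zero-width window) calibrates the ant genomes.
#'
#' @return Calibration tibble usable by [date_all()].
#' @export
mariner_calibrations <- function() {
  readr::read_tsv(pkg_extdata("mariner_calibrations.tsv"),
                  col_types = readr::cols(
                    genome = "c", cal_family = "c", cal_genome = "c",
                    age_min = "d", age_max = "d", rationale = "c"))
}

#' Phylogenetic age caps for the Mariner dating analysis
#'
#' Upper bounds that the raw divergence-ratio estimates may not exceed:
#' the placental radiation (100 MYA) for Mariner-1_Tbel and a 90 MYA
#' lineage constraint for Mariner1_BT.
#'
#' @return Cap tibble usable by [date_all()].
#' @export
mariner_caps <- function() {
  readr::read_tsv(pkg_extdata("mariner_age_caps.tsv"),
                  col_types = readr::cols(
                    family = "c", genome = "c", cap_mya = "d",
                    rationale = "c"))
}

#' Toy ultrametric species tree for the studied genomes
#'
#' Approximate divergence times (MY) for the seven genomes in the bundled
#' divergence table; suitable for split-age lookups and Dollo loss counts.
#'
#' @return `phylo`.
#' @export
mariner_species_tree <- function() {
  read_newick(pkg_extdata("mammal_insect_species_tree.nwk"))
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tedater")
  if (!nzchar(path)) abort(sprintf("bundled data file missing: %s", file))
  path
}
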