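# Horizontal-transfer evidence: observed cross-genome consensus divergence
# against the divergence expected under vertical descent, plus
# Dollo-parsimony loss counts measuring distribution patchiness.

K2P_SATURATION_CEILING <- 75

#' Expected divergence under vertical descent
#'
#' Two lineages that split `split_age` MYA and each accumulate
#' substitutions at `rate` are expected to differ by
#' `2 * rate * split_age` percent, capped at the K2P saturation ceiling of
#' 75% (beyond which the distance is undefined and any observed high
#' identity is decisive).
#'
#' @param split_age Species divergence time, MYA.
#' @param rate Substitution rate in %/MY.
#' @return One-row tibble: `expected_pct`, `saturated`.
#' @export
expected_divergence <- function(split_age, rate) {
  if (!is.numeric(split_age) || split_age < 0) abort("`split_age` must be >= 0")
  if (!is.numeric(rate) || rate <= 0) abort("`rate` must be > 0")
  raw <- 2 * rate * split_age
  tibble(expected_pct = min(raw, K2P_SATURATION_CEILING),
         saturated = raw > K2P_SATURATION_CEILING)
}

#' Substitution rate implied by a calibration family
#'
#' The calibration family accumulated `d_calib` percent divergence over
#' its age window; the implied rate is `d_calib / midpoint(window)`.
#'
#' @param calib One-row tibble from [calibration_window()].
#' @param d_calib Calibration family divergence (%).
#' @return Rate in %/MY.
#' @export
calibrate_rate <- function(calib, d_calib) {
  mid <- (calib$age_min + calib$age_max) / 2
  if (mid <= 0) abort("calibration window midpoint must be > 0")
  d_calib / mid
}

#' Horizontal-transfer verdict from observed vs expected divergence
#'
#' `ratio = observed / expected`. The verdict is `HT-supported` when the
#' ratio falls below `threshold` (the families are far too similar for
#' vertical descent), `vertical-plausible` when it is at least
#' `vertical_band`, and `indeterminate` in between. Both bounds are
#' configuration, not biology: clear HT cases sit one to two orders of
#' magnitude below any reasonable threshold, and the ratio is always
#' reported alongside the verdict.
#'
#' @param obs Observed consensus-to-consensus K2P divergence (%); `NA`
#'   (saturated) is treated as the 75% ceiling.
#' @param exp_pct Expected divergence (%) from [expected_divergence()].
#' @param threshold HT ratio threshold (default 0.25).
#' @param vertical_band Lower edge of the vertical-plausible band
#'   (default 0.75).
#' @param split_known Set `FALSE` when the species split is unknown or 0;
#'   the verdict is then at most `indeterminate`.
#' @return One-row tibble: `ratio`, `verdict`.
#' @export
ht_verdict <- function(obs, exp_pct, threshold = 0.25, vertical_band = 0.75,
                       split_known = TRUE) {
  if (is.na(obs)) obs <- K2P_SATURATION_CEILING
  if (!is.numeric(exp_pct) || exp_pct <= 0) abort("`exp_pct` must be > 0")
  ratio <- obs / exp_pct
  verdict <- if (ratio < threshold && split_known) {
    "HT-supported"
  } else if (ratio >= vertical_band) {
    "vertical-plausible"
  } else {
    "indeterminate"
  }
  tibble(ratio = ratio, verdict = verdict)
}

#' Minimal Dollo loss count for a presence/absence pattern
#'
#' Assuming a single gain at the most recent common ancestor of the
#' species that carry the element, returns the minimal number of loss
#' events: the number of maximal subtrees under that ancestor containing
#' no presence leaf. High counts flag the patchy distributions typical of
#' horizontal transfer.
#'
#' @param species_tree Rooted `phylo`.
#' @param present_in Non-empty character vector of leaf labels carrying
#'   the element.
#' @return Integer loss count.
#' @examples
#' tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' dollo_losses(tr, c("a", "c"))
#' @export
dollo_losses <- function(species_tree, present_in) {
  if (!inherits(species_tree, "phylo")) abort("`species_tree` must be a 'phylo'")
  if (length(present_in) == 0) abort("`present_in` must be non-empty")
  missing <- setdiff(present_in, species_tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("unknown leaf label: %s", paste(missing, collapse = ", ")))
  }
  if (length(unique(present_in)) == 1) return(0L)  # gain on the terminal branch
  ntip <- length(species_tree$tip.label)
  pres <- match(unique(present_in), species_tree$tip.label)
  children <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  n_pres <- integer(ntip + species_tree$Nnode)
  count_pres <- function(node) {
    if (node <= ntip) return(as.integer(node %in% pres))
    sum(vapply(children[[as.character(node)]], count_pres, integer(1)))
  }
  mrca <- ape::getMRCA(species_tree, unique(present_in))
  losses <- function(node) {
    if (node <= ntip) return(0L)
    tot <- 0L
    for (ch in children[[as.character(node)]]) {
      if (count_pres(ch) == 0L) tot <- tot + 1L else tot <- tot + losses(ch)
    }
    tot
  }
  losses(mrca)
}
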