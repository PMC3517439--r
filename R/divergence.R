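#' Per-copy K2P distances to the family consensus
#'
#' @param copies Alignment tibble of copies, each row aligned to
#'   `consensus` (same column count; gapped).
#' @param consensus One-row sequence tibble or string, gapped to the same
#'   column count as the copies.
#' @return Tibble with `id`, `d` (substitutions/site), `sites`.
#' @export
copy_divergences <- function(copies, consensus) {
  assert_seq_tbl(copies)
  cons <- seq_string(consensus)
  res <- map(copies$seq, function(s) k2p_distance(s, cons))
  tibble(id = copies$id,
         d = map_dbl(res, "d"),
         sites = map_dbl(res, "sites"))
}

#' Family divergence: mean K2P distance of copies to their consensus
#'
#' Copies whose comparable sites with the consensus fall below
#' `min_coverage` times the (ungapped) consensus length are excluded.
#' Reports the mean and sample standard deviation of the per-copy K2P
#' distances, in percent, and the number of copies used. If `sample_size`
#' is given, that many qualifying copies are drawn without replacement
#' (mirrors divergence estimation from a random subset of family members).
#'
#' @param copies Alignment tibble of copies aligned to the consensus.
#' @param consensus Consensus sequence (string or 1-row tibble), gapped to
#'   the copy alignment.
#' @param min_coverage Minimum fraction of the consensus length a copy must
#'   cover with comparable sites (default 0.7).
#' @param sample_size Optional number of copies to sample.
#' @param seed Optional seed for the sampling step.
#' @return One-row tibble: `divergence_pct`, `divergence_sd_pct`,
#'   `n_sampled`.
#' @export
family_divergence <- function(copies, consensus, min_coverage = 0.7,
                              sample_size = NULL, seed = NULL) {
  assert_seq_tbl(copies)
  cons <- seq_string(consensus)
  cons_len <- nchar(ungap(cons))
  per <- copy_divergences(copies, consensus)
  per <- per[per$sites >= min_coverage * cons_len, , drop = FALSE]
  if (nrow(per) == 0) abort("no copies pass the coverage filter")
  if (!is.null(sample_size) && sample_size < nrow(per)) {
    idx <- if (is.null(seed)) {
      sample.int(nrow(per), sample_size)
    } else {
      withr::with_seed(seed, sample.int(nrow(per), sample_size))
    }
    per <- per[idx, , drop = FALSE]
  }
  tibble(
    divergence_pct = 100 * mean(per$d),
    divergence_sd_pct = if (nrow(per) > 1) 100 * sd(per$d) else 0,
    n_sampled = nrow(per)
  )
}

#' Summarise one TE family in one genome
#'
#' Builds the full per-family record (one row of a divergence report):
#' consensus, consensus length, copy number and divergence statistics.
#'
#' @param copies Alignment tibble of the family's copies.
#' @param family,genome Labels.
#' @param copy_number Total copies in the genome, if known (defaults to the
#'   number of rows of `copies`).
#' @inheritParams family_divergence
#' @param gap_threshold Passed to [build_consensus()].
#' @return One-row tibble: `family`, `genome`, `consensus_length`,
#'   `copy_number`, `divergence_pct`, `divergence_sd_pct`, `n_sampled`,
#'   plus a `consensus` list-column holding the consensus tibble.
#' @export
family_observation <- function(copies, family, genome,
                               copy_number = nrow(copies),
                               min_coverage = 0.7, sample_size = NULL,
                               seed = NULL, gap_threshold = 0.5) {
  cons <- build_consensus(copies, gap_threshold = gap_threshold,
                          id = paste0(family, "@", genome))
  # re-gap the consensus onto the copy alignment so columns line up:
  # build_consensus drops high-gap columns, so recompute it column-wise
  gapped <- gapped_consensus(copies, gap_threshold = gap_threshold)
  div <- family_divergence(copies, gapped, min_coverage = min_coverage,
                           sample_size = sample_size, seed = seed)
  tibble(
    family = family, genome = genome,
    consensus_length = nchar(cons$seq),
    copy_number = copy_number,
    divergence_pct = div$divergence_pct,
    divergence_sd_pct = div$divergence_sd_pct,
    n_sampled = div$n_sampled,
    consensus = list(cons)
  )
}

# consensus in alignment coordinates: dropped columns become gaps so the
# result stays comparable column-by-column with the copies
gapped_consensus <- function(aln, gap_threshold = 0.5) {
  aln <- as_te_alignment(aln)
  m <- seq_char_matrix(aln)
  keep <- colMeans(m == "-") <= gap_threshold
  if (!any(keep)) abort("no consensus columns")
  res <- rep("-", ncol(m))
  res[keep] <- apply(m[, keep, drop = FALSE], 2, function(col) {
    counts <- table(factor(col[col %in% DNA_BASES4], levels = DNA_BASES4))
    if (sum(counts) == 0) return("N")
    DNA_BASES4[which.max(counts)]
  })
  chars_to_string(res)
}

#' Format a divergence entry as `mean ± sd (n)`
#'
#' @param mean_pct,sd_pct,n Divergence mean (%), SD (%) and sample size.
#' @return Character, e.g. `"15.0 ± 2 (183)"`.
#' @export
format_divergence <- function(mean_pct, sd_pct, n) {
  sprintf("%.1f ± %d (%d)", mean_pct, round_half_up(sd_pct), n)
}
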