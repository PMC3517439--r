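#' Majority-rule consensus of aligned TE copies
#'
#' Reconstructs the (approximate) ancestral element from an alignment of
#' family copies. Columns whose gap fraction exceeds `gap_threshold` are
#' dropped; in the remaining columns the consensus residue is the most
#' frequent unambiguous base, ties broken by the fixed order A < C < G < T.
#' `N` never wins a column; a column with no unambiguous base at all (only
#' `N` besides gaps) emits `N`. The result is gap-free.
#'
#' @param aln Alignment tibble of family copies.
#' @param gap_threshold Columns with gap fraction strictly above this are
#'   dropped (default 0.5).
#' @param id Id given to the consensus sequence.
#' @return One-row sequence tibble.
#' @examples
#' aln <- tibble::tibble(id = c("c1", "c2", "c3"),
#'                       seq = c("AC-GA", "AC-TN", "GCTTA"))
#' build_consensus(aln)
#' @export
build_consensus <- function(aln, gap_threshold = 0.5, id = "consensus") {
  aln <- as_te_alignment(aln)
  m <- seq_char_matrix(aln)
  keep <- colMeans(m == "-") <= gap_threshold
  if (!any(keep)) abort("no consensus columns")
  m <- m[, keep, drop = FALSE]
  res <- apply(m, 2, function(col) {
    counts <- table(factor(col[col %in% DNA_BASES4], levels = DNA_BASES4))
    if (sum(counts) == 0) return("N")
    DNA_BASES4[which.max(counts)]  # which.max keeps first max: A < C < G < T
  })
  seq_tbl(id, chars_to_string(res))
}
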