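#' Percent identity between two sequences
#'
#' If `prealigned = FALSE` the (ungapped) sequences are first globally
#' aligned with Needleman-Wunsch scoring match 1 / mismatch -1 / gap -2
#' (via `Biostrings::pairwiseAlignment`). Identity is then counted over the
#' aligned columns under one of two documented conventions:
#'
#' * `"gap_mismatch"` (default): denominator = columns where at least one
#'   residue is a base; a gap opposite a base counts as a mismatch;
#'   gap-gap columns are ignored.
#' * `"gap_exclude"`: denominator = columns where both residues are bases;
#'   all gap columns are ignored.
#'
#' Columns containing `N` are excluded from both numerator and denominator
#' under either convention.
#'
#' @param a,b Sequence strings or 1-row sequence tibbles.
#' @param prealigned If `TRUE`, `a` and `b` must already be equal-length
#'   gapped strings and are compared as-is.
#' @param mode Identity convention (see above).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACGT-A", "ACTTTA", prealigned = TRUE)
#' @export
pairwise_identity <- function(a, b, prealigned = FALSE,
                              mode = c("gap_mismatch", "gap_exclude")) {
  mode <- match.arg(mode)
  a <- seq_string(a)
  b <- seq_string(b)
  if (!prealigned) {
    al <- nw_align(ungap(a), ungap(b))
    a <- al[1]
    b <- al[2]
  } else if (nchar(a) != nchar(b)) {
    abort("prealigned sequences must have equal length")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  keep <- ca != "N" & cb != "N"
  ca <- ca[keep]
  cb <- cb[keep]
  base_a <- ca %in% DNA_BASES4
  base_b <- cb %in% DNA_BASES4
  denom_cols <- if (mode == "gap_mismatch") base_a | base_b else base_a & base_b
  if (sum(denom_cols) == 0) abort("empty overlap: no comparable columns")
  matches <- sum(base_a & base_b & ca == cb & denom_cols)
  100 * matches / sum(denom_cols)
}

# global NW alignment, match 1 / mismatch -1 / linear gap -2
nw_align <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2
  )
  c(as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
}

#' Pairwise identity matrix over a set of consensus sequences
#'
#' @param consensuses Tibble with columns `id` and `seq` (typically family
#'   consensuses labelled `family@genome`).
#' @param prealigned If `TRUE`, sequences are columns of one multiple
#'   alignment; otherwise each pair is globally aligned.
#' @inheritParams pairwise_identity
#' @return A symmetric numeric matrix (percent), diagonal 100, with
#'   row/column names from `id`.
#' @export
identity_matrix <- function(consensuses, prealigned = FALSE,
                            mode = c("gap_mismatch", "gap_exclude")) {
  mode <- match.arg(mode)
  assert_seq_tbl(consensuses)
  n <- nrow(consensuses)
  m <- matrix(100, n, n, dimnames = list(consensuses$id, consensuses$id))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pairwise_identity(consensuses$seq[i], consensuses$seq[j],
                             prealigned = prealigned, mode = mode)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
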