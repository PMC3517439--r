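#' Read nucleotide sequences from a FASTA file
#'
#' Reads plain or gapped FASTA and normalises residues for downstream
#' distance work: residues are upper-cased, `U` is mapped to `T`, and any
#' character outside `{A, C, G, T, N, -}` is mapped to `N` (with a warning
#' naming the affected records).
#'
#' @param path Path to a FASTA file. An empty file yields an empty tibble.
#' @return A tibble with columns `id` (first whitespace-delimited header
#'   token) and `seq`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "acg-u"), f)
#' read_te_fasta(f)
#' @export
read_te_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) return(seq_tbl(character(), character()))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate id: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    warn(sprintf("non-standard residues mapped to N in: %s",
                 paste(ids[bad], collapse = ", ")))
    seqs <- gsub("[^ACGTN-]", "N", seqs)
  }
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for id: %s",
                  paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  seq_tbl(ids, seqs)
}

#' Write sequences to FASTA
#'
#' @param x Sequence tibble with columns `id`, `seq`.
#' @param path Output path.
#' @param width Line-wrap width (fixed default 60 for byte-stable output).
#' @return `path`, invisibly.
#' @export
write_te_fasta <- function(x, path, width = 60) {
  assert_seq_tbl(x)
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a multiple alignment from gapped FASTA
#'
#' Applies the same residue normalisation as [read_te_fasta()] and verifies
#' that all records have equal length and that there are at least two.
#'
#' @param path Path to a gapped FASTA file.
#' @return An alignment tibble (`id`, `seq`), all sequences equal length.
#' @export
read_te_alignment <- function(path) {
  as_te_alignment(read_te_fasta(path))
}

#' Validate a sequence tibble as an alignment
#'
#' @param x Sequence tibble.
#' @return `x`, unchanged, if it is a valid alignment (>= 2 members, equal
#'   lengths); otherwise an error naming the offending record.
#' @export
as_te_alignment <- function(x) {
  assert_seq_tbl(x)
  if (nrow(x) < 2) abort("alignment needs ≥2 sequences")
  len <- nchar(x$seq)
  if (length(unique(len)) > 1) {
    ref <- len[1]
    off <- x$id[len != ref][1]
    abort(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                  off, len[len != ref][1], ref))
  }
  x
}

#' Number of columns in an alignment
#' @param x Alignment tibble.
#' @return Integer column count.
#' @export
alignment_length <- function(x) {
  nchar(as_te_alignment(x)$seq[1])
}
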