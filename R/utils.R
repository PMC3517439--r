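# Shared helpers: sequence tibbles are (id, seq) with seq an upper-case
# string over {A,C,G,T,N,-}.

DNA_BASES4 <- c("A", "C", "G", "T")
SEQ_ALPHABET <- c(DNA_BASES4, "N", "-")

# round half away from zero; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

seq_tbl <- function(id, seq) {
  tibble(id = as.character(id), seq = toupper(as.character(seq)))
}

#' @noRd
assert_seq_tbl <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  if (nrow(x) > 0 && any(!nzchar(x$seq))) {
    abort(sprintf("`%s` contains empty sequences", arg))
  }
  invisible(x)
}

# split sequences into a character matrix (rows = sequences)
seq_char_matrix <- function(x) {
  chars <- strsplit(x$seq, "", fixed = TRUE)
  len <- lengths(chars)
  if (length(unique(len)) > 1) {
    abort("sequences have unequal lengths; an alignment is required")
  }
  matrix(unlist(chars), nrow = nrow(x), byrow = TRUE,
         dimnames = list(x$id, NULL))
}

chars_to_string <- function(ch) paste(ch, collapse = "")

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && abs(x - round(x)) < tol
}

# derive a reproducible child seed bounded below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1013L * as.integer(k)) %% 2147483399L
}
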