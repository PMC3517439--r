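#' Seed-and-extend copy search in genomic sequence
#'
#' A deliberately reduced BLASTN-style homology search used to count family
#' copies in (synthetic) genome sequence: exact `word_size`-mer seed
#' matches on both strands, extended ungapped in both directions under an
#' X-drop rule (match +1, mismatch -2, drop 20), overlapping hits merged,
#' then filtered by identity and length. Copy counts from real genomes
#' screened with full BLASTN are not expected to match this surrogate.
#'
#' @param genome Gap-free genome sequence (string or 1-row tibble).
#' @param query Gap-free query (typically a family consensus).
#' @param word_size Exact seed length (default 11).
#' @param min_identity Minimum hit identity fraction (default 0.6).
#' @param min_length Minimum hit length in bp (default 100).
#' @param xdrop Score drop allowed before extension stops (default 20).
#' @return Tibble of hits: `start`, `end` (1-based genome coords),
#'   `strand`, `identity`, `coverage` (of the query), `length`. No hits
#'   yields an empty tibble.
#' @export
find_copies <- function(genome, query, word_size = 11, min_identity = 0.6,
                        min_length = 100, xdrop = 20) {
  g <- seq_string(genome)
  q <- seq_string(query)
  if (grepl("-", g, fixed = TRUE) || grepl("-", q, fixed = TRUE)) {
    abort("inputs must be gap-free")
  }
  hits <- bind_rows(
    scan_strand(g, q, "+", word_size, xdrop),
    scan_strand(g, revcomp(q), "-", word_size, xdrop)
  )
  if (nrow(hits) == 0) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  identity = double(), coverage = double(), length = integer()))
  }
  hits <- merge_hits(hits)
  hits$length <- as.integer(hits$end - hits$start + 1L)
  hits$coverage <- pmin(1, hits$length / nchar(q))
  hits <- hits[hits$identity >= min_identity & hits$length >= min_length, ,
               drop = FALSE]
  hits$start <- as.integer(hits$start)
  hits$end <- as.integer(hits$end)
  arrange(hits[, c("start", "end", "strand", "identity", "coverage", "length")],
          .data$start)
}

#' Reverse complement
#' @param s Sequence string (A/C/G/T/N/-).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  chars_to_string(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq_string(s)),
                               "", fixed = TRUE)[[1]]))
}

scan_strand <- function(g, q, strand, w, xdrop) {
  gc <- strsplit(g, "", fixed = TRUE)[[1]]
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  if (length(qc) < w || length(gc) < w) return(tibble())
  gw <- substring(g, seq_len(nchar(g) - w + 1), seq_len(nchar(g) - w + 1) + w - 1)
  qw <- substring(q, seq_len(nchar(q) - w + 1), seq_len(nchar(q) - w + 1) + w - 1)
  idx <- split(seq_along(gw), gw)
  seeds <- list()
  for (qi in seq_along(qw)) {
    gi <- idx[[qw[qi]]]
    if (!is.null(gi)) seeds[[length(seeds) + 1]] <- cbind(q = qi, g = gi)
  }
  if (length(seeds) == 0) return(tibble())
  seeds <- do.call(rbind, seeds)
  # one extension per diagonal is enough: ungapped extension from any seed
  # on a diagonal explores the same aligned positions
  diag <- seeds[, "g"] - seeds[, "q"]
  first <- !duplicated(diag)
  seeds <- seeds[first, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(seeds))) {
    h <- extend_seed(gc, qc, seeds[k, "g"], seeds[k, "q"], w, xdrop)
    if (!is.null(h)) rows[[length(rows) + 1]] <- h
  }
  if (length(rows) == 0) return(tibble())
  out <- bind_rows(rows)
  out$strand <- strand
  out
}

# ungapped X-drop extension; returns the maximal-scoring span around the seed
extend_seed <- function(gc, qc, gs, qs, w, xdrop) {
  # overlap of query and genome along this diagonal
  off <- gs - qs
  q_lo <- max(1L, 1L - off)
  q_hi <- min(length(qc), length(gc) - off)
  if (q_hi - q_lo + 1 < w) return(NULL)
  m <- gc[(q_lo:q_hi) + off] == qc[q_lo:q_hi]
  step <- ifelse(m, 1, -2)
  seed_i <- qs - q_lo + 1L
  seed_j <- seed_i + w - 1L
  right <- xdrop_best(cumsum(step[seq(seed_j + 1L, length(step))]), xdrop,
                      empty_ok = seed_j >= length(step))
  left <- xdrop_best(cumsum(rev(step[seq_len(seed_i - 1L)])), xdrop,
                     empty_ok = seed_i <= 1L)
  i <- seed_i - left
  j <- seed_j + right
  span <- m[i:j]
  tibble(start = q_lo + i - 1L + off, end = q_lo + j - 1L + off,
         identity = mean(span), score = sum(step[i:j]))
}

# best prefix of a cumulative-score walk before it drops `xdrop` below its max
xdrop_best <- function(cum, xdrop, empty_ok = FALSE) {
  if (empty_ok || length(cum) == 0) return(0L)
  running_max <- cummax(cum)
  stop_at <- which(running_max - cum > xdrop)
  upto <- if (length(stop_at) == 0) length(cum) else stop_at[1] - 1L
  if (upto == 0) return(0L)
  which.max(cum[seq_len(upto)])
}

# merge overlapping same-strand hits, keeping the best-scoring identity
merge_hits <- function(hits) {
  out <- list()
  for (s in unique(hits$strand)) {
    h <- arrange(hits[hits$strand == s, , drop = FALSE], .data$start)
    cur <- h[1, ]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] <= cur$end) {
        if (h$score[i] > cur$score) {
          cur$identity <- h$identity[i]
          cur$score <- h$score[i]
        }
        cur$end <- max(cur$end, h$end[i])
      } else {
        out[[length(out) + 1]] <- cur
        cur <- h[i, ]
      }
    }
    out[[length(out) + 1]] <- cur
  }
  bind_rows(out)
}
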