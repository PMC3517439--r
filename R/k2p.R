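# Kimura two-parameter (K80) distance: the workhorse statistic for
# within-family TE divergence and for all tree building here.

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two aligned sequences
#'
#' Compares only columns where both residues are unambiguous bases
#' (`A`,`C`,`G`,`T`); gaps and `N` are excluded. With `P` the transition
#' proportion and `Q` the transversion proportion over those sites,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` substitutions/site.
#'
#' @param a,b Sequence strings (or 1-row sequence tibbles) of equal length,
#'   i.e. already aligned to each other.
#' @param on_saturation `"error"` (default) to fail when the distance is
#'   undefined (log of a non-positive argument), or `"na"` to return `NA`
#'   for `d` with `saturated = TRUE`.
#' @return A one-row tibble: `d` (substitutions/site), `P`, `Q`, `sites`
#'   (comparable columns), `saturated`.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAC")
#' @export
k2p_distance <- function(a, b, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  a <- seq_string(a)
  b <- seq_string(b)
  if (nchar(a) != nchar(b)) {
    abort("sequences must be aligned (equal length)")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  cmp <- ca %in% DNA_BASES4 & cb %in% DNA_BASES4
  sites <- sum(cmp)
  if (sites == 0) abort("no comparable sites")
  ca <- ca[cmp]
  cb <- cb[cmp]
  diff <- ca != cb
  ts <- sum(diff & cb == unname(TRANSITION_PARTNER[ca]))
  tv <- sum(diff) - ts
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- (w1 <= 0 || w2 <= 0)
  if (saturated) {
    if (on_saturation == "error") abort("saturated")
    d <- NA_real_
  } else {
    d <- -0.5 * log(w1) - 0.25 * log(w2)
  }
  tibble(d = d, P = P, Q = Q, sites = sites, saturated = saturated)
}

# accept either a bare string or a sequence tibble row
seq_string <- function(x) {
  if (is.data.frame(x)) {
    assert_seq_tbl(x)
    if (nrow(x) != 1) abort("expected a single sequence")
    return(x$seq)
  }
  if (!is.character(x) || length(x) != 1) {
    abort("expected a sequence string or 1-row sequence tibble")
  }
  toupper(x)
}

#' Exact K80 substitution probabilities at a given distance
#'
#' Closed-form transition probability `P(d)` and total transversion
#' probability `Q(d)` of the K80 chain after `d` expected
#' substitutions/site with transition/transversion rate ratio `kappa`:
#' with `beta = 1/(kappa + 2)` and `alpha = kappa/(kappa + 2)`,
#' `P(d) = 1/4 + 1/4 exp(-4 beta d) - 1/2 exp(-2 (alpha + beta) d)` and
#' `Q(d) = 1/2 - 1/2 exp(-4 beta d)`.
#'
#' @param d Expected substitutions/site (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return A one-row tibble with `P`, `Q` and `identical` (= 1 - P - Q).
#' @export
k80_site_probs <- function(d, kappa = 2) {
  if (!is.numeric(d) || any(d < 0)) abort("`d` must be non-negative")
  if (!is.numeric(kappa) || kappa <= 0) abort("`kappa` must be positive")
  beta <- 1 / (kappa + 2)
  alpha <- kappa / (kappa + 2)
  P <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  Q <- 0.5 - 0.5 * exp(-4 * beta * d)
  tibble(d = d, P = P, Q = Q, identical = 1 - P - Q)
}
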