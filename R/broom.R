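# broom-style accessors for simulation and report objects

#' Tidy a simulated burst into per-copy divergences
#'
#' @param x A `te_burst` from [simulate_burst()].
#' @param ... Unused.
#' @return Tibble with one row per copy: `id`, `d` (K2P distance to the
#'   true ancestor), `sites`.
#' @method tidy te_burst
#' @export
tidy.te_burst <- function(x, ...) {
  copy_divergences(x$copies, x$ancestor)
}

#' One-row summary of a simulated burst
#'
#' @param x A `te_burst`.
#' @param ... Unused.
#' @return Tibble: true age/rate/expected distance and the realised mean
#'   and SD of copy-to-ancestor K2P distances.
#' @method glance te_burst
#' @export
glance.te_burst <- function(x, ...) {
  per <- tidy(x)
  tibble(
    family = x$family,
    burst_age = x$scenario$burst_age,
    rate = x$scenario$rate,
    expected_d = x$scenario$rate * x$scenario$burst_age,
    mean_d = mean(per$d),
    sd_d = sd(per$d),
    n_copies = nrow(per)
  )
}

#' Tidy an HT report into its evidence table
#'
#' @param x An `ht_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The HT evidence tibble (one row per cross-genome family pair).
#' @method tidy ht_report
#' @export
tidy.ht_report <- function(x, ...) {
  x$evidence %||% tibble()
}

#' One-row summary of an HT report
#'
#' @param x An `ht_report`.
#' @param ... Unused.
#' @return Tibble: family/verdict counts and the smallest observed ratio.
#' @method glance ht_report
#' @export
glance.ht_report <- function(x, ...) {
  ev <- x$evidence
  tibble(
    n_families = length(unique(x$families$family)),
    n_genomes = length(unique(x$families$genome)),
    n_dated = if (is.null(x$ages)) 0L else nrow(x$ages),
    n_pairs = if (is.null(ev)) 0L else nrow(ev),
    n_ht_supported = if (is.null(ev)) 0L else sum(ev$verdict == "HT-supported"),
    min_ratio = if (is.null(ev) || nrow(ev) == 0) NA_real_ else min(ev$ratio)
  )
}
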