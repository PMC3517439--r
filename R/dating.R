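# Relative-age dating: a family's burst age is the calibration family's
# age window scaled by the ratio of the two families' mean divergences
# (strict molecular clock shared by TE families in the same genome).

#' Define a calibration age window
#'
#' @param family Calibration family name.
#' @param genome Genome in which its divergence was measured.
#' @param age_min,age_max Window bounds in MYA (equal bounds make every
#'   scaled estimate an upper bound: the calibration age is itself an
#'   outermost age).
#' @param rationale Free-text provenance of the window.
#' @return One-row tibble.
#' @export
calibration_window <- function(family, genome, age_min, age_max,
                               rationale = "") {
  stopifnot(age_min >= 0, age_min <= age_max)
  tibble(cal_family = family, cal_genome = genome,
         age_min = age_min, age_max = age_max, rationale = rationale)
}

#' Scale a calibration window by a divergence ratio
#'
#' `raw = (d_family / d_calib) * [age_min, age_max]`. Reported bounds are
#' the raw bounds rounded half-up to integer MYA. A zero-width window marks
#' the result as an upper bound only ("expanded at most ~X MYA").
#'
#' @param d_family Focal family mean divergence (%).
#' @param d_calib Calibration family mean divergence (%), > 0.
#' @param calib One-row tibble from [calibration_window()].
#' @param family,genome Labels carried into the estimate.
#' @return One-row tibble: `family`, `genome`, `raw_min`, `raw_max`,
#'   `reported_min`, `reported_max`, `upper_bound_only`,
#'   `constraint_applied` (NA until [apply_constraint()]).
#' @export
estimate_age_range <- function(d_family, d_calib, calib,
                               family = "family", genome = "genome") {
  if (!is.numeric(d_calib) || d_calib <= 0) abort("calibration divergence must be > 0")
  if (!is.numeric(d_family) || d_family < 0) abort("family divergence must be >= 0")
  ratio <- d_family / d_calib
  raw_min <- ratio * calib$age_min
  raw_max <- ratio * calib$age_max
  tibble(
    family = family, genome = genome,
    d_family = d_family, d_calib = d_calib,
    raw_min = raw_min, raw_max = raw_max,
    reported_min = round_half_up(raw_min),
    reported_max = round_half_up(raw_max),
    upper_bound_only = calib$age_min == calib$age_max,
    constraint_applied = NA_real_
  )
}

#' Clip an age estimate at a phylogenetic upper bound
#'
#' Applies an external cap (e.g. a radiation age that the family cannot
#' predate): `reported_max` becomes `min(reported_max, cap)`; the lower
#' bound is untouched. A cap below the lower bound is a contradiction and
#' errors rather than clipping silently.
#'
#' @param est One-row estimate from [estimate_age_range()].
#' @param cap Upper bound in MYA.
#' @return The estimate with `reported_max` clipped and
#'   `constraint_applied` recorded.
#' @export
apply_constraint <- function(est, cap) {
  if (!is.numeric(cap) || cap <= 0) abort("`cap` must be positive")
  if (cap < est$reported_min) {
    abort(sprintf("constraint excludes estimate: cap %g < lower bound %g",
                  cap, est$reported_min))
  }
  if (est$reported_max > cap) {
    est$reported_max <- cap
    est$constraint_applied <- cap
  }
  est
}

#' Date every family in a divergence table
#'
#' For each (family, genome) row that is not itself a calibration family,
#' looks up the genome's calibration window, scales it by the divergence
#' ratio and applies any configured cap.
#'
#' @param families Tibble with at least `family`, `genome`,
#'   `divergence_pct` (one row per family per genome); calibration families
#'   must be present so their divergence can be looked up.
#' @param calibrations Tibble mapping `genome` to a calibration:
#'   columns `genome`, `cal_family`, `cal_genome` (genome in which the
#'   calibration divergence was measured; defaults to `genome`),
#'   `age_min`, `age_max`.
#' @param caps Optional tibble of phylogenetic caps: `family`, `genome`
#'   (or `"*"` for any genome), `cap_mya`.
#' @return Tibble of class `te_ages`, one row per dated (family, genome).
#' @export
date_all <- function(families, calibrations, caps = NULL) {
  stopifnot(is.data.frame(families), is.data.frame(calibrations))
  if (!"cal_genome" %in% names(calibrations)) {
    calibrations$cal_genome <- calibrations$genome
  }
  if (nrow(families) == 0) {
    return(structure(tibble(), class = c("te_ages", class(tibble()))))
  }
  out <- list()
  for (i in seq_len(nrow(families))) {
    fam <- families$family[i]
    gen <- families$genome[i]
    if (any(calibrations$cal_family == fam & calibrations$cal_genome == gen)) {
      next  # this row is a calibration reference, not a dated family
    }
    cal <- calibrations[calibrations$genome == gen, , drop = FALSE]
    if (nrow(cal) == 0) abort(sprintf("no calibration configured for genome '%s'", gen))
    cal <- cal[1, ]
    if (fam == cal$cal_family) next  # the calibration family itself
    cal_row <- families[families$family == cal$cal_family &
                          families$genome == cal$cal_genome, , drop = FALSE]
    if (nrow(cal_row) == 0) {
      abort(sprintf("calibration divergence missing: %s in %s",
                    cal$cal_family, cal$cal_genome))
    }
    est <- estimate_age_range(families$divergence_pct[i],
                              cal_row$divergence_pct[1],
                              cal, family = fam, genome = gen)
    cap <- lookup_cap(caps, fam, gen)
    if (!is.na(cap)) est <- apply_constraint(est, cap)
    out[[length(out) + 1]] <- est
  }
  res <- bind_rows(out)
  structure(res, class = c("te_ages", class(res)))
}

lookup_cap <- function(caps, family, genome) {
  if (is.null(caps) || nrow(caps) == 0) return(NA_real_)
  hit <- caps[caps$family == family &
                (caps$genome == genome | caps$genome == "*"), , drop = FALSE]
  if (nrow(hit) == 0) return(NA_real_)
  min(hit$cap_mya)
}
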