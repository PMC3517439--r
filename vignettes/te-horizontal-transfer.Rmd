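---
title: "Dating TE amplification bursts and detecting horizontal transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating TE amplification bursts and detecting horizontal transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tedater)
library(dplyr)
```

## The inference problem

Horizontal transfer (HT) of transposable elements — a TE family jumping
between species rather than descending from parent to offspring — is
detected inferentially, from two signals: TE sequences in long-diverged
species that are far more similar than vertical descent would allow, and a
patchy taxonomic distribution of the family. `tedater` implements the
complete chain of computations behind that inference:

1. reconstruct each family's **consensus** (a proxy for the ancestral
   active element) from aligned genomic copies;
2. measure **within-family divergence** as the mean Kimura two-parameter
   (K2P) distance of copies to the consensus — a clock-like proxy for the
   time since the family's amplification burst;
3. **date** families by scaling a calibration family's age window by the
   ratio of divergences;
4. build **neighbor-joining trees** with bootstrap support from K2P
   distance matrices;
5. combine cross-genome consensus identity, expected divergence under
   vertical descent, and Dollo-parsimony loss counts into an **HT
   verdict**.

A K80 burst simulator generates family histories with known ages, rates
and transfer events, so every stage is validated against ground truth.

## The substitution model and distance

All distances are Kimura two-parameter: with transition proportion $P$ and
transversion proportion $Q$ over comparable sites (both residues in
$\{A,C,G,T\}$; gaps and `N` excluded),

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

The estimator errors explicitly when $1-2P-Q \le 0$ or $1-2Q \le 0$
("saturated") or when no comparable sites remain; callers that must
tolerate saturation (the HT stage) request `NA` instead and treat it as
the 75% saturation ceiling.

The simulator is the generative counterpart: `mutate_sequence()` resamples
each site independently with the exact K80 probabilities at divergence
$d$ and transition/transversion ratio $\kappa$ ($\beta = 1/(\kappa+2)$,
$\alpha = \kappa/(\kappa+2)$):

$$P(d) = \tfrac14 + \tfrac14 e^{-4\beta d} - \tfrac12 e^{-2(\alpha+\beta)d},
\qquad Q(d) = \tfrac12 - \tfrac12 e^{-4\beta d}.$$

Sites are independent and identically distributed (no rate heterogeneity,
no base-composition bias) — deliberately the exact model the estimator
assumes, so estimator tests have closed-form oracles. Burst copies are
independent draws from the ancestor (a star phylogeny / master-gene
burst), the model under which mean-divergence dating is unbiased.

## Consensus reconstruction

`build_consensus()` drops columns whose gap fraction exceeds 0.5, then
takes the most frequent unambiguous base per column, ties broken by the
fixed order A < C < G < T (determinism matters more than which tie-winner
is chosen: at a genuine tie the column carries no signal). `N` never wins
a column and is excluded from all distance and identity counts. On
simulated bursts with 30+ copies at moderate divergence the consensus
recovers the true ancestor at ≥ 99% identity.

## Family divergence and its report format

`family_divergence()` filters copies whose comparable sites cover less
than 70% of the consensus length (`min_coverage = 0.7`), optionally
subsamples, and reports mean ± SD (n) in percent. The ± term is the
*sample standard deviation* of per-copy distances; published tables of
this form rarely state whether ± is SD or SE, so the value is carried for
display and never used in dating arithmetic.

## Relative-age dating

`estimate_age_range()` implements the ratio clock: if a calibration
family of age window $[a_{\min}, a_{\max}]$ MYA accumulated $d_c$ percent
divergence in a genome, a focal family with divergence $d_f$ in the same
genome is dated to

$$[\,(d_f/d_c)\,a_{\min},\ (d_f/d_c)\,a_{\max}\,].$$

This assumes one substitution rate shared by TE families within (and, for
the ratio, across) genomes — a strict clock. A zero-width window (a
calibration age that is itself an outermost bound, like a common-ancestor
age) makes every scaled estimate an upper bound ("expanded at most ~X
MYA"). `apply_constraint()` clips the upper bound at an external
phylogenetic cap (e.g. a radiation age the family cannot predate) and
refuses a cap below the lower bound instead of silently clipping a
contradiction. Reported values round half-up to integer MYA; no
uncertainty propagation from the ± terms is attempted (the point
estimates drive everything; that is a documented limitation, not an
oversight). Calibration windows and caps are configuration files, not
code constants — they are priors about specific clades.

The bundled tables (`mariner_divergences()`, `mariner_calibrations()`,
`mariner_caps()`) carry the published Mariner case: TIGGER1 calibrates
the four mammalian genomes (window 100–190 MYA, bracketed by the
marsupial–placental split and the placental radiation), Mariner-28_SIn
calibrates the two ant genomes (outermost age 140 MYA, the ant common
ancestor):

```{r dating}
ages <- date_all(mariner_divergences(), mariner_calibrations(), mariner_caps())
ages %>% select(family, genome, raw_min, raw_max, reported_min, reported_max)
```

## Trees

`distance_matrix()` uses pairwise deletion (each pair compared over its
own comparable columns, the MEGA-era default). `neighbor_joining()` is
Saitou–Nei agglomeration with the Studier–Keppler criterion; negative
branch lengths are clamped to zero with the deficit moved to the sister
branch; Q-ties break on the lexicographically smallest label pair so
results are platform- and input-order-independent. `bootstrap_support()`
is the standard Felsenstein column bootstrap: resample columns, rebuild
matrix and tree, count bipartitions of the full-data tree; replicates
with saturated pairs are dropped and the run aborts if more than half
are. An all-zero matrix returns a star tree with no internal edges rather
than an arbitrary resolution.

## HT verdicts

Under vertical descent, two genomes that split $T$ MYA accumulate an
expected $2 r T$ percent divergence between their copies of a shared
family ($r$ from `calibrate_rate()`: calibration divergence over the
window midpoint; the mean of the two genomes' rates when they differ),
capped at the 75% saturation ceiling. The decision statistic is

$$\mathrm{ratio} = d_\mathrm{observed} / d_\mathrm{expected},$$

with observed divergence measured between the two genomes' consensuses.
The verdict is `HT-supported` below 0.25, `vertical-plausible` at or
above 0.75, `indeterminate` between. The bands are configuration: the
motivating insect–mammal case sits at ratio ≈ 0.05 (a few percent
observed against a saturated expectation across a ~1-billion-year split),
so conclusions are robust to any reasonable band choice, and the ratio is
always printed next to the verdict. Equal-length consensus pairs are
compared gaplessly — under the indel-free generator they are positionally
homologous, and global alignment of saturated pairs would bias the
estimate downward by placing gaps where mismatches belong; consensus
pairs of unequal length go through Needleman–Wunsch (match 1, mismatch
−1, gap −2, via Biostrings).

Distribution patchiness is quantified by `dollo_losses()`: assuming a
single gain at the MRCA of the carrier species, the minimal number of
independent losses needed to explain the absences. Verified against
exhaustive enumeration on trees up to 10 leaves.

## The simulator as study design

`ht_scenario()` defaults encode the validation conditions used
throughout: a 1300-bp element (Mariner-scale), 50 copies per burst, rate
0.002 substitutions/site/MY, $\kappa = 2$, no indels; a focal family
bursting at 150 MYA in an insect lineage and transferred at 80 MYA to a
mammal lineage across a 1000-MY split; per-genome calibration families
bursting at 145 MYA, inherited vertically from the species' common
ancestor. The active master element is modelled as conserved (strong
selection on an active transposase), so recipient copies diverge from
the shared ancestral element by rate × transfer age — exactly the
situation in which cross-genome consensus identity stays high after
transfer. Over 20 seeds the pipeline recovers the 80 MYA transfer to
within ~1 MYA on average and calls HT in 20/20 seeds.

What the simulator does *not* emulate: rate heterogeneity across sites
and lineages, base-composition bias, indel-driven alignment uncertainty
(indels are off by default; when enabled, copies must be realigned
before consensus building), nested insertions, and selection beyond
perfect master conservation. Passing tests therefore validate the
*estimators under their own model assumptions* and the end-to-end logic,
not robustness to real-genome messiness.

## Numerical choices and degenerate inputs

* Rounding of reported ages: half-up to integer MYA (published rounding
  of such tables is inconsistent at the unit digit; tests and the
  acceptance machinery use ±1 MYA).
* `find_copies()` is an explicitly reduced BLASTN surrogate (exact 11-mer
  seeds, ungapped X-drop 20 extension, one extension per diagonal,
  overlap merging); copy counts on real genomes are not comparable to
  full BLASTN screens.
* Problem sizes in the test suite — 100-kb sequences for estimator
  checks, 30 replicates at 30-kb for consistency, 20 seeds for
  end-to-end recovery, 100 bootstrap replicates — were chosen so the
  statistical bands (3 SE, 2% relative error) are comfortably resolvable
  while the whole suite runs in about a minute.
* Degenerate inputs error loudly and early: empty alignments, ragged
  records, duplicate ids, saturated pairs, caps that exclude estimates,
  calibration divergence of zero.

## Limitations

The dating model is a strict clock on neutral decay from a star burst;
families with prolonged activity, gene conversion, or non-neutral decay
will violate it in ways the ratio estimate cannot see. The identity
convention of published pairwise-identity tables is rarely stated; both
conventions implemented here (`gap_mismatch`, `gap_exclude`) are exposed
and switchable. Trees are emitted unrooted; display rooting is cosmetic.
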