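---
title: "Methods: characterizing unstable TTTTA/TTTCA pentanucleotide expansions"
author: "famex developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing unstable TTTTA/TTTCA pentanucleotide expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famex)
```

## The problem

Familial adult myoclonic epilepsy (FAME) is caused by intronic tandem
expansions of a mixed pentanucleotide structure,
5'-(TTTTA)~exp~(TTTCA)~exp~(TTTTA)~opt~-3', arising at a locus that in the
reference assembly is a short polymorphic TTTTA microsatellite. Assessing
such an expansion requires several independent measurement chains —
short-read screening, long-read motif decomposition, single-molecule
(molecular combing / fiber FISH) sizing — plus population-genetic dating of
the shared risk haplotype and genotype–phenotype correlation. `famex`
implements each chain as a testable, reusable component, together with a
synthetic-data generator that emulates the statistical structure the
analyses assume, so the whole pipeline can be exercised without access to
patient data (which is not publicly releasable for studies of this kind).

## Motif decomposition of long reads

A long read is anchored at the locus by local alignment of the terminal
150 bases of each flank (unit scores +1/−1/−2, identity ≥ 0.8 over ≥ 60
bases; tolerant of ~10–15% base-calling error). Anchoring on both flanks
gives *full* coverage; one flank gives *left/right-partial* coverage, as
seen in real data where very large expansions exceed single reads.

The enclosed interval is decomposed into maximal runs of **exact** tandem
motif copies. Design choices, each configurable:

* **A run starts at 2 exact copies** (`min_units = 2`): single isolated
  motifs count as gap content, preventing spurious runs in flanking
  sequence. (Inside a spanning short read's inter-anchor region the locus
  is known, so there single copies are counted.)
* **Overlaps between TTTTA and TTTCA candidates** (they share a 3-base
  prefix) are resolved longest-first, leftmost on ties; the losing run is
  trimmed to whole copies. This makes the segmentation deterministic and
  mirrors the visual block rendering of dot plots.
* **Gap merging** (`max_merge_gap = 10`): adjacent same-motif runs
  separated by ≤ 10 bases are reported as one segment whose `unit_count`
  sums only exact copies — one indel cluster should not split a
  homogeneous block.
* **5'/3' assignment**: TTTTA segments upstream of the first TTTCA
  segment are 5', downstream 3'; reads without TTTCA are all 5'.
* **Sizes**: per-motif kb sizes count exact copies only (gap bases
  excluded); the total expansion kb is the physical span including gaps —
  matching the convention that per-motif sizes are motif-specific while
  the total is the molecule's extent.

### Exact counts versus span-based estimates

`total_units` counts exact copies. Under a combined 10% per-base error
rate the probability that a 5-base copy survives untouched is about
0.9^5 ≈ 0.59, so exact-copy counting *systematically undercounts* on noisy
reads — by ~40%, not 10%. Total-repeat-number estimators used on nanopore
data are effectively span-based, so `DecomposedRead` also reports
`units_est` = interval span / 5 (and per-class span / 5). Insertion and
deletion rates nearly cancel (3% vs 4%), leaving `units_est` within ~1% of
truth on typical reads; the package's robustness criterion (≥ 90% of reads
within 10% of truth at 10% error) is defined on this estimator. Both views
are always reported side by side.

Coordinates are 1-based inclusive in genomic references (the printed
convention) and 0-based half-open internally.

## Short-read screen

The screen is deliberately a transparent re-specification of the
anchored/in-repeat read logic that expansion genotypers embody, not a port
of any of them: no BAM realignment, no population model. Reads are
*spanning* (both junction 20-mers present; exact unit counts in between),
*anchored-in-repeat*, *fully-in-repeat* (≥ 90% of the read tiled by
rotations of one motif, either strand), or irrelevant.

One refinement proved necessary beyond the naive "one anchor + ≥ 4 motif
copies" rule for in-repeat evidence: a read spanning a *normal*
microsatellite allele whose far junction lies just beyond the read end
satisfies that rule, which would fabricate lower-bound alleles in
non-carriers. In-repeat evidence therefore additionally requires the
anchor to sit at the read's outer edge and the inner remainder to be
essentially all repeat (≥ 90%) running to the inner edge — i.e. the read
itself must show the repeat continuing past it. With this rule, simulated
non-carriers (alleles of 9–20 TTTTA units) produce two spanning allele
clusters and no calls, while carriers produce a lower-bound allele at
`floor((read_length − 2·min_anchor)/5)` units (22 for 150-bp reads).

Spanning unit counts are clustered with a 1-unit tolerance (PCR-free
stutter is minimal) into at most two alleles. Any TTTCA presence calls a
TTTCA expansion (the motif is never observed at the locus in controls);
the TTTTA call requires exceeding a configured normal maximum (default 30
units) or lower-bound evidence.

## Molecular combing

Input is a measurement table, not images (fiber scanning and segmentation
are upstream, out of scope): per fiber, a token sequence over
B/Y/R/W/G/M/C with kb lengths. The analysis follows the published
measurement conventions exactly:

* Classification of red-negative alleles by the unstained length Y:
  N < 5.5 kb ≤ U < 8.5 kb ≤ P_likely, ties following the printed
  inequalities; red staining ⇒ P_definite. Incomplete and rearranged
  fibers take precedence and are excluded from all size statistics.
* Baseline Y~n~ = median Y of the *same individual's* N alleles.
* Expansion size = Y~p~ − Y~n~ + ΣR + ΣW, with parts 5'-TTTTA = Y~p~ −
  Y~n~, TTTCA = ΣR, 3'-TTTTA = ΣW. Reporting W as "3'-TTTTA" is an
  interpretation of an unstained gap; the raw W measurement is kept
  alongside it. Slightly negative sizes (Y~p~ just below Y~n~) are
  flagged, not clamped, to keep means unbiased.
* Micro-rearrangement grammar: overlay tokens (M/C), a missing flank
  probe while the other flank and red are present, duplicated flank
  probes, or inverted flank polarity. The first matching rule is recorded.
* Configurations C1–C6 are defined pictorially in the source material;
  the mapping used here (C1 = B,Y,R,G; C2 = B,Y,R,W,G; C3 = B,Y,R,W,R,G;
  C4 = B,Y,R,W,R,W,G; C5 = B,Y,G with expanded Y; C6 = any other accepted
  pattern with ≥ 3 red segments) is a **declared convention of this
  package**, not a claim about the original figure.
* The per-cell rearrangement percentage is `min(100, 2 × percent of
  alleles)`, assuming at most one rearranged allele per cell.
* Whether "incomplete" fibers include single-probe fibers is not settled
  by the source text; here both truncated and grammar-ambiguous fibers are
  excluded from sizing.

## Haplotype dating

The age in generations of the most recent common ancestor is estimated
from the genetic length of the shared core haplotype. With `n` independent
meioses per flank, each flank's surviving shared length is the minimum of
`n` exponential(g) breakpoint distances, so the two-sided length L (in
Morgans, cM/100) is Gamma(2, rate n·g). The MLE is ĝ = 2/(n·L) and
2·n·g·L is an exact χ²₄ pivot, giving exact-coverage confidence intervals
(the package verifies 93–97% empirical coverage at g = 250 over 500
seeded simulations). For a 0.35 cM core shared by two families,
ĝ ≈ 285.7 generations (CI 34.6–796.0), ~5,700 years at 20 years per
generation. The externally published bias-corrected estimator is *not*
bundled (its correction is not restated in the source this package is
built from); `method = "published"` is a pluggable slot that currently
fails informatively, and the package deliberately does not tune toward
the externally computed point estimate.

## Phenotype statistics

Pearson correlations are reported with Fisher-z intervals
(tanh(atanh r ± z/√(n−3))) for each combination of onset phenotype
(seizure, tremor) and expansion part (total, 5'-TTTTA, TTTCA,
5'+3'-TTTTA), with pairwise-complete deletion — matching the explicit
inclusion lists of the original correlation figures. Censored table
entries (a nanopore TTTCA mean reported only as "> 5") are stored as
censored values and excluded from means and correlations.

For expression, the ΔΔCt method is implemented in its conventional form:
relative abundance = 2^(−ΔΔCt), ΔΔCt = (Ct~target~ − Ct~ref~)~sample~ −
mean over controls. The printed source formula is dimensionally a *ratio*
of ΔCt values, which contradicts the standard exponent convention; the
package treats that as a transcription artifact, defaults to the
conventional form, and documents both. Groups are compared with an exact
two-sided Wilcoxon–Mann–Whitney rank-sum test.

## The synthetic-data generator

The generator states a world and keeps it fixed; its defaults are the
conditions the analyses assume:

* **Germline structure** ~600–2,800 total units (3–14 kb), default
  560/480/120 units (5.8 kb), spanning the observed per-individual mean
  range without reproducing any individual.
* **Somatic mosaicism**: per-cell log-normal multipliers with unit mean;
  the coefficient of variation (default 0.3) is a declared convention —
  no quantitative jitter distribution is published for this process.
* **Configurations** redistribute the jittered units (totals preserved):
  the mix defaults to mostly C2/C1 with minor C3–C6, again a declared
  convention since only the configurations' existence is documented.
* **Micro-rearrangement**: probability per cell is a scaled logistic of
  expansion size, p(s) = p_max/(1+exp(−slope(s − midpoint))), defaults
  p_max 0.12, midpoint 12 kb, slope 0.8/kb. A plain 2-parameter logistic
  cannot be ≈ 0.10 at 14 kb with a 12-kb midpoint and positive slope, so
  the scale parameter is a necessary addition; the defaults give ≈ 10%
  rearranged alleles at a 14-kb mean and < 3% at 4 kb, reproducing the
  association of rearrangements with the largest expansions. Rearranged
  cells emit grammar-violating combing fibers and, on the long-read side,
  translocation-like fusion reads (right flank replaced by foreign
  sequence), so detection sensitivity is measurable.
* **Read errors**: substitution/insertion/deletion 0.03/0.03/0.04 per
  base, a nanopore-like 10% combined rate. Short reads are emitted
  error-free (PCR-free Illumina error is negligible at these scales).
* **Combing measurements**: flank probes at fixed lengths, Gaussian
  signal noise (SD 0.3 kb), a 0.8-kb detection limit below which R/W
  signals vanish, and a small truncated-fiber fraction. The unstained
  offset between the blue probe and the repeat (2.5 kb) sets the
  normal-allele Y scale, matching a control distribution of
  Y ~ Normal(2.5, 0.5).
* **Phenotype**: seizure onset = 45 − 2.5 × TTTCA-kb + Normal(0, 5) years
  (truncated at 10); tremor onset independent of size. The slope encodes
  the inverse TTTCA–onset relationship the correlation stage must detect.

All randomness flows from one explicit seed per emitter through an
isolated RNG scope; identical seeds give byte-identical outputs.

What a green synthetic test does **not** establish: real base-caller error
is context-dependent rather than i.i.d.; real somatic mosaicism need not
be log-normal; combing signal noise may scale with length; the synthetic
locus flanks are fixed random stand-ins for the true genomic flanks. The
synthetic world validates the measurement chains' correctness and
calibration, not the biology.

## Numerical conventions and degenerate inputs

Empty sequences decompose to an empty structure (not an error); a read
with no recoverable anchor raises a locus-not-found error; genotyping with
no informative reads returns an explicit no-coverage result; an individual
without normal combing alleles has no baseline and errors by name;
zero-variance correlation cells are flagged NA rather than propagating
NaN. Physical haplotype spans use the end − start convention, which is
what reproduces the printed 190.8 kb span of the 10301295–10492095 core
haplotype.

## Known limitations

* The sequence-space unit counts are a different estimator from
  signal-space long-read tools; they are validated against synthetic
  truth, not against published per-read counts.
* Translocation-type rearrangements are detected only as anchor asymmetry
  (fusion reads lose the right anchor); breakpoint assembly is out of
  scope.
* The combing configuration taxonomy and the incomplete-fiber convention
  are declared interpretations (see above).
* The dating model is the transparent Gamma/exponential model; the
  external tool's bias correction is not reproduced.
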