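---
title: "Methods: distance-constrained homotypic promoter models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-constrained homotypic promoter models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmscreen)
```

## The model

A predictive promoter model (PPM) here is a *framework*: a promoter is a
candidate target of HMX1 when the window around its transcription start
site carries at least one **admissible pair** of HMX1 binding sites. Its
ingredients, all tunable:

| parameter | default | meaning |
|---|---|---|
| `upstream` / `downstream` | 250 / 200 nt | window `[-250, +200]` around the TSS; `+1` is the TSS base, signed coordinates skip 0 |
| motif tier | `ppm` | `ppm`: two canonical `CAAGTG` sites; `ls`: at least one canonical, the other a standalone core `CAAG`; `vls`: any two sites |
| `min_distance` / `max_distance` | 90 / 190 nt | admissible start-to-start spacing of the pair |
| `min_pairs` | 1 | pairs required for a window to fit |

The window default covers the proximal promoter and the approximate median
eukaryotic 5′ UTR, the two TSS-proximal regions where binding sites and
homotypic clusters concentrate. Orientation is recorded but never filters:
both sites may sit on either strand. The 90–190 nt spacing is the
framework derived (`derive_distance_range()`, rounding the observed
extremes outward to 10 nt) from the spacings observed in the two-motif
promoters of the positive training set. The original HMX1 study states the
window once as `[-250, +250]` and elsewhere consistently as `[-250, +200]`;
the package defaults to the latter and leaves both bounds configurable, so
either reading is reproducible.

### Sites, pairs and tier nesting

Scanning reports every exact occurrence of the forward and
reverse-complement motif strings, including overlaps; `N` never matches, so
soft-masked or gappy assemblies degrade gracefully. Raw hits are collapsed
to **physical sites** before pairing: every canonical hit is a site, and a
core hit is a site only when its span overlaps no canonical hit's span (a
`CAAGTG` necessarily contains a `CAAG`; counting both would let one
physical site act as two pair members). Tier composition is cumulative —
`ppm` pairs require two canonical sites, `ls` pairs at least one, `vls`
pairs any two — which makes the fits monotone by construction:
`fits(ppm) ⇒ fits(ls) ⇒ fits(vls)`. This reading is the one consistent
with the strictly nested tier sensitivities of the validation table; a
strict "the core must avoid every canonical span" rule would paradoxically
make a two-canonical promoter fail the *relaxed* tier.

### The distance measure

Pair distance defaults to **start-to-start** (5′-most base to 5′-most
base). "Space between the motifs" is ambiguous between this and the
end-to-start gap; start-to-start is chosen because it is well defined
across the 6-nt and 4-nt motifs, keeps tier relaxation monotone, and
reproduces both published combinatorial maxima (below). The end-to-start
gap is available as `pair_constraint(measure = "gap")` for sensitivity
analysis. One known wrinkle: start-to-start distances of *mixed-length*
pairs shift by the 2-nt length difference on the opposite strand, so LS/VLS
fits at the exact distance boundaries are not perfectly strand-symmetric;
canonical (equal-length) pairs are.

### Pair-combination combinatorics

With `k` sites in one window, at most `C(k,2)` pairs exist, but the spacing
constraint caps how many can be admissible *simultaneously*: equality holds
exactly when `(k-1) * min_distance <= max_distance`. Under the default
constraint three sites can realise all 3 pairs (e.g. gaps 90/90), while
four sites realise at most 5 of 6 — the outer pair must span at least
270 nt > 190. `max_simultaneous_pairs()` proves these maxima by
enumerating subsets of candidate pairs and testing each for realisability
as an integer difference-constraint system (Floyd–Warshall negative-cycle
detection); this is exact — every placement's pair set is such a subset and
every feasible subset is witnessed by an integral placement — and avoids
the infeasible brute force over all nucleotide positions.

## Statistics

Validation counts, per tier, the genes of each training set with at least
one fitting promoter window (ANY-window semantics over alternative
promoters, matching gene-level reporting of sequence-level screens). From
the 2×2 table it reports:

- **fold enrichment** — ratio of fit rates, positive over negative set;
  reported rounded half away from zero to one decimal (99.55% → 99.6%,
  matching how the published table rounds). An empty negative cell is
  flagged infinite rather than raised as an error.
- **Fisher's exact test** — two-sided by the sum of all equally-or-less
  likely tables at fixed margins (ties within 1e-7 relative tolerance), via
  `stats::fisher.test`; the suite cross-checks it against a full
  hypergeometric enumeration.
- **sensitivity / specificity** — with exact Clopper–Pearson binomial
  intervals from beta quantiles. Exact intervals differ by up to ~0.1
  percentage point from the MedCalc values the original study printed
  (2.1–26.5 vs 2.2–26.6 for 3/30); the package reports the exact interval.
- **χ² with Yates correction** — for pathway over-representation of a
  selection against a gene universe (default 25,504 genes), with the
  correction floored at zero when `|O-E| < 0.5` and a zero-expected-cell
  error that points to Fisher's exact test instead.

The VLS fold is reported as the direct ratio of the two rates; the original study
prints 1.0/1.01 where its own printed rates give 63.3/59.3 ≈ 1.07,
presumably from unrounded internal values, and that discrepancy cannot be
reconciled from the printed numbers.

## Genome-wide selection

`screen_genome()` reports one hit per gene with a fitting window, carrying
the evidence of its best window (most qualifying pairs, ties broken by
canonical site count, then window id). Two filters sharpen the raw screen:

- **conservation** — `conserved_intersection()` keeps ortholog pairs hit in
  both species' screens. Only *presence* of an admissible pair is required;
  neither position nor orientation must match, deliberately looser than
  phylogenetic footprinting.
- **co-occurrence** — `cooccurrence_select()` keeps hits with ≥ 3 canonical
  sites forming ≥ 2 admissible pairs (both thresholds configurable), ranked
  by pair count, then site count, then symbol.

Negative training sets are sampled from the universe *excluding* the
positive genes; the exclusion is not stated in the original study but avoids label
contamination and is negligible at the published scale (30 of 25,504).

## The synthetic-data generators

Every generator is a pure function of `(config, seed)` (`withr::with_seed`;
sub-generators use fixed small offsets of the seed), producing byte-stable
FASTA/TSV-compatible objects. Defaults are the study conditions: a
30-gene positive set of which 3 carry a planted two-motif structure, a
2,000-promoter negative set, a DE table with 146 genes at FDR < 0.1
(70 up / 76 down) containing 30 at FDR < 0.01 (14 up / 16 down), planted
pair distances uniform on [90, 190] nt, 10 conserved planted genes, 10
multi-site promoters (nine with three sites forming two admissible pairs
and one with four sites forming three, the co-occurrence selection
classes), and a 135-gene pathway holding 3 of the 10 selected genes in a
25,504-gene universe — which reconstructs the *computation shape* of the
published 56.6-fold pathway enrichment: the study does not print its
pathway size, and `(3/10)/(135/25504) = 56.7`. The synthetic genome holds
2,500 genes, one 700-nt contig each — large enough for the negative set
while keeping a full pipeline run under half a minute; the published
genome-wide counts (157 mouse, 100 human, 10 conserved genes) are
database-version-dependent and are not reproduction targets.

Background sequence is uniform iid by default, with an optional first-order
Markov transition matrix to emulate dinucleotide bias; real promoters have
CpG islands, repeats and composition gradients that neither captures, so
passing tests demonstrate correctness of the machinery and calibration
under the stated null, not performance on real genomes. Planting writes
oriented motif strings at exact offsets and **rejects placements that
create canonical sites not present before** (bounded retries), so truth
tables are exact; residual chance `CAAG` cores are permitted — they affect
only the relaxed tiers, consistent with the core motif's weak specificity.
When exact planted counts are needed (training-set construction,
planted-truth recovery), background promoters are additionally
rejection-sampled not to fit the planted tier; `exact = FALSE` keeps the
raw background for null-rate work. Planted promoters start from a
canonical-free substrate for the same reason.

Under the uniform null the strict model fits roughly 0.7% of 450-nt
windows (10,000-window simulation in the acceptance suite) — the same
order as the 0.5% observed on real random promoters.

## Numerical and design choices

- Signed promoter coordinates skip zero (…, −1, +1, …) as in standard
  interval labels; internal arithmetic is 0-based with one conversion
  function (`offset_to_signed()` / `signed_to_offset()`).
- The TSS base is `+1`, i.e. included in the downstream segment, the
  conventional reading of "+200" as transcribed bases.
- Motifs must lie entirely inside the window; edge-spanning hits are never
  counted, and windows overhanging a contig raise an error rather than
  truncate silently.
- Matching is case-insensitive and exact; no position-weight-matrix or
  IUPAC-degenerate scanning (no PWM is available for this factor).
- The 20-replicate parameter-recovery check uses per-replicate exact
  binomial prediction intervals on both contingency components at
  Bonferroni level `1 - 0.05/40`, so the joint test keeps ≥ 95% coverage
  without tuning.
- Pipeline reports embed the verbatim parameter set and seed and carry no
  timestamps, so a configuration fully determines the report bytes.

## Limitations

Only TSS-proximal windows are scanned — intronic or distal enhancer
clusters are reachable solely through user-supplied custom windows. Exact
string matching cannot express binding degeneracy beyond the two fixed
tiers. The statistics assume promoters are exchangeable units;
co-regulation, shared ancestry and compositional heterogeneity of real
promoter sets violate that silently. And a model validated on a
differential-expression contrast inherits that contrast's secondary
effects: genes responding indirectly dilute the positive set, so the
reported sensitivity is, if anything, an underestimate.
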