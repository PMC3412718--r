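---
title: "Reconstructing GlnR/TnrA-type regulons by footprinting and Similar Motif Scoring"
author: "regulonSMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing GlnR/TnrA-type regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonSMS)
```

## The biological problem

Nitrogen metabolism in low-GC Gram-positive bacteria is controlled by a
small set of regulators — GlnR (active at nitrogen excess) and, in Bacilli,
TnrA (active at limitation) — that bind near-identical palindromic
operators with consensus **TGTNA-N7-TNACA**. The operator characteristically
sits 3–6 nt upstream of a TTGAC −35 promoter element. Because the two
proteins read almost the same sites, regulon membership cannot be assigned
from a single genome; it has to be inferred comparatively, by asking which
gene families carry a credible site in their upstream region across many
species. This package implements that comparative reconstruction as a
reusable pipeline and pairs it with a synthetic-genome benchmark whose
ground truth is known exactly.

## The model and its assumptions

**Motif model.** A binding motif is a position frequency matrix (PFM): the
fraction `f_N(j)` of each nucleotide `N` at each position `j = 1..i` of an
aligned, equal-length site collection. No background model and no
log-odds transformation are used: the scoring statistic is deliberately the
raw frequency sum.

**Similar Motif Scoring (SMS).** A window `w` of length `i` scores
`raw(w) = Σ_j f_{w[j]}(j)`. Dividing by `i` gives a *similarity* in [0, 1];
dividing instead by the highest attainable sum `Σ_j max_N f_N(j)` gives the
*relative similarity*, which reaches 1 exactly when the window picks a
column-maximal nucleotide at every position. Relative similarity is the
selection statistic: it is monotone under single-position degradations and
directly comparable across matrices of different sharpness. Non-ACGT
characters (including N) contribute 0 by convention, so ambiguous genome
positions can only lower a score.

**Footprinting.** Orthologous upstream regions of the anchor operon (the
regulator's own *glnRA*-like operon, whose regulatory association is
conserved in every species that has the regulator) are searched for the
degenerate seed pattern; the best match per genome, preferring
promoter-anchored windows (3′ end 3–6 nt upstream of an exact TTGAC), is
collected. One site per genome keeps species weighting equal. Genomes
without an admissible window are dropped with a message; fewer than
`minGenomes` (default 4) usable genomes aborts the build, since a matrix
from fewer sites is too noisy to scan with.

**Selection criteria.** An operon is a predicted target when its best site
has (i) relative similarity at or above 0.87 and (ii) lies entirely within
the 250-nt window upstream of the leader's translation start. The published
cut-off is written as ">87%"; at a 2-digit printed precision the boundary
convention is arbitrary, and this implementation includes the boundary
(`relative >= 0.87`), documented here once. A stricter 0.89 preset
(`pipelineConfig(preset = "high_confidence")`) mirrors the cut-off under
which the large majority of experimentally validated sites is still
recovered while trimming borderline calls.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `window` | 250 nt | upstream search window; regulatory sites of this family concentrate within 250 nt of the start |
| `threshold` | 0.87 (0.89 preset) | relative-similarity cut-off, boundary inclusive |
| `operonGap` | 150 nt | same-strand intergenic gap merged into one operon; a common prokaryotic heuristic, exposed because the choice shifts which leader a site is attributed to |
| `minConservedSpecies` | 3 | species support needed to call an association conserved; the source analyses phrase this both as "at least three" and "more than three" species — the inclusive reading is the default and the knob is exposed |
| `maxMismatches` (seed) | 2 | mismatch budget at the 10 defined pattern positions; tolerates the drift observed in a few species while rejecting background |
| `pseudocount` | 0 | raw frequencies by default, so absent nucleotides contribute exactly 0; a Laplace pseudocount is available for scans across distant taxa |

Distances are measured from the site's 3′-most base to the first base of
the start codon (distance 1 = immediately adjacent), and the whole site
must fit inside the window — a conservative, reproducible reading of a
window defined only as "between 250 and 0 bases upstream".

## Design choices where the design was open

* **Coordinates.** All internal ranges are `GRanges` (1-based closed), the
  Bioconductor convention, so GFF3 needs no conversion and range arithmetic
  goes through IRanges. Exported BED uses the BED convention.
* **Both-strand scanning** is on by default. The operator is palindromic at
  all ten defined positions — any exact forward match is an exact reverse
  match — but sampled sites and divergon geometry break the symmetry, so
  both orientations are scored and a forward-only mode is kept for exact
  reproduction experiments.
* **Upstream windows are never clipped** at the 3′ end of the nearest
  upstream gene: footprint alignments in this family are fixed-window, and
  clipping would silently change scores between annotation versions. A
  truncation flag marks contig-edge clipping.
* **Divergons annotate, never filter.** A site inside both head-to-head
  windows is reported for both operons with a `divergon:` note. Which
  partner the repressor actually acts on is a biological question the score
  cannot answer.
* **E-value gap direction.** The published clustering rule pairs an
  in-group below 1e−30 with a "separation < e−15"; the only reading under
  which the groups are separated is a gap of ≥ 15 orders of magnitude, and
  that is what `evalueGapCluster` computes (`separationLog10`). Narrow gaps
  set `cleanSeparation = FALSE` — a review flag, not a failure — preserving
  the manual-inspection spirit of the original procedure. An e-value of 0
  is stored as 1e−200 to keep log10 arithmetic finite.
* **Ranks** are computed per genome over qualifying operons, on scores
  rounded to 2 decimals, with ties sharing the lower rank — matching the
  "score (rank)" presentation convention of this literature.
* **Whitelisting** relaxes only the distance criterion (extended window,
  default 600 nt) for loci with experimentally verified distant sites; the
  score criterion always applies.

## The synthetic benchmark: what it emulates, what it does not

`simulateGenome` builds an i.i.d. background contig at GC 0.40 (typical of
these organisms), lays 300–900 nt genes separated by 250–450 nt intergenic
stretches (alternating strands by default, so divergons and convergent
pairs occur), samples sites column-wise from a planting PFM, writes them
into upstream windows with the site 3′ edge uniform at 20–200 nt from the
start, and plants the anchor construct — site, 3–6 nt spacer, TTGAC —
upstream of gene 1. Placements are collision-checked and redrawn; all draws
derive from the seed, and identical seeds give byte-identical FASTA/GFF3.

The default planting matrix (`sitePFM()`) holds the consensus
`TGTCAGAATTATTAACA` at fraction 0.95 per position. This emulates a
high-information motif whose site-to-site dispersion comes from sampling;
in real GlnR operators the N7 spacer is much less conserved than the
flanks, so the benchmark is *easier* at spacer positions than nature.
Consequently the recovery results below demonstrate pipeline correctness —
coordinate bookkeeping, strand handling, scoring, thresholds, aggregation —
not expected sensitivity on real genomes. The background is i.i.d. rather
than Markov: the SMS statistic itself uses no background model, so nothing
richer is needed for fidelity, but genome-scale false-positive rates on
real sequence (with its repeats and compositional structure) will differ.

The end-to-end benchmark (`plantedRegulonBenchmark`) uses the all-plus
gene layout: upstream windows are then pairwise disjoint, so each planted
site belongs to exactly one operon and "false conserved family" is
well-defined. Under the alternating layout a site planted in a shared
divergon interval is — correctly — assigned to both partners, which is
exercised in the unit tests instead.

## Numerical conventions and degenerate inputs

* Frequency columns must sum to 1 within 1e−9; the cached maximum
  attainable score is validated against the profile at construction.
* Scanner ties break deterministically: higher relative score, then
  smaller distance to start, then + strand, then smaller offset.
* A region shorter than the motif yields an empty scan, not an error; a
  leader abutting the contig edge yields an empty, truncated region.
* Report writers sort on fixed keys and format scores to 2 decimals;
  re-running on identical inputs is byte-identical.

## Problem sizes used by the checks

The shipped checks run at desk scale, chosen as the package's own test
design: 200 random matrices (length ≤ 8) against brute-force enumeration
of all 4^i windows; 10 replicates of a 10-species, 12-family panel
(30 genes per genome) for end-to-end recovery; 20 replicates of 20 genomes
for footprint consensus recovery; 100 simulated hit tables for cluster
recovery; 20 background-only genomes of 200 genes for the false-positive
bound. Typical full-suite runtime is a couple of minutes on one core.

## Known limitations

* Operon inference is a gap heuristic, not a transcription-unit model;
  the gap default is exposed precisely because predictions depend on it.
* The pipeline consumes tabular homology hits; it does not run the
  homology search itself, and tree-based orthology (needed for families
  whose e-value landscape does not separate, e.g. large ABC-transporter
  substrate-binding families) is out of scope — externally curated
  memberships can be supplied as ortholog groups.
* No p-value or E-value calibration of SMS scores is provided; the
  statistic ranks candidates and thresholds are conventions validated
  against experimental site collections, not significance levels.
* Validation against real genome panels requires downloading those genomes
  and is intentionally outside the shipped checks.
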