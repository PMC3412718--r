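# regulonSMS

Comparative reconstruction of bacterial transcription-factor regulons,
modelled on the nitrogen regulators **GlnR** and **TnrA** of low-GC
Gram-positive bacteria (Bacilli, Streptococci, Lactobacilli). The package is
aimed at microbial comparative genomicists who want to rebuild a regulon
across a panel of genomes from nothing more than genome sequences,
annotations and tabular homology hits — and at method developers who need a
fully synthetic, truth-known benchmark for binding-site pipelines.

## What it does

GlnR and TnrA bind near-identical palindromic operators with consensus
**TGTNA-N7-TNACA**, typically 3–6 nt upstream of a TTGAC −35 promoter
element. The pipeline:

1. **Phylogenetic footprinting** (`footprintFamily`): in each genome, the
   upstream region of the universally conserved regulator operon (the
   *glnRA*-like anchor) is searched for the degenerate seed pattern; one
   site per genome is collected into an aligned set and turned into a
   family-specific position frequency matrix (PFM)
   `f_N(j)`, `N ∈ {A,C,G,T}`, `j = 1..i`.
2. **Similar Motif Scoring** (`smsScore`, `scanRegion`): a candidate window
   `w` of length `i` scores

   `raw(w) = Σ_j f_{w[j]}(j)`,   `similarity = raw / i`,
   `relative = raw / max_attainable`,   `max_attainable = Σ_j max_N f_N(j)`

   so the relative similarity runs from 0 to 1 and is directly
   interpretable as closeness to the best window the matrix allows.
3. **Regulon prediction** (`predictRegulon`): a gene/operon is called a
   target when its best site has relative similarity ≥ 0.87 (preset
   `high_confidence`: 0.89) and lies entirely within 250 nt upstream of the
   leader's translation start. Operons come from an intergenic-gap rule;
   head-to-head gene pairs (divergons) sharing a regulatory interval are
   annotated on both sides.
4. **Ortholog grouping** (`evalueGapCluster`): homology hits cluster into a
   family when their e-values fall below 1e−30 and are separated from the
   background by ≥ 15 orders of magnitude; narrower gaps are flagged for
   review, mirroring manual list inspection.
5. **Cross-species aggregation** (`conservedAssociations`,
   `buildPresenceAbsence`): target families supported in ≥ 3 species are
   reported as conserved; family × genome copy counts render in the
   conventional `total(regulated)` cell syntax.

A seeded synthetic-genome generator (`simulateGenome`,
`simulateSpeciesPanel`, `simulateHitTable`) plants sites sampled from a
sharp PFM into upstream windows, writes the anchor construct
(site + 3–6 nt spacer + TTGAC), and emits truth tables, so every stage is
testable offline.

## Worked example

```r
library(regulonSMS)

## the SMS statistic on a toy alignment
pfm <- buildPFM(c("ACGT", "ACGA", "ACTT", "GCGT"))
maxAttainable(pfm)        # 3.25
smsScore(pfm, "GCTA")$relative
# [1] 0.5384615            (= 1.75 / 3.25)

## a 6-species synthetic panel with a 5-family planted regulon
spec  <- simulationSpec(seed = 42, geneStrands = "plus")
panel <- simulateSpeciesPanel(spec, nSpecies = 6, sharedFamilies = 5)

## footprint the anchor regions into a family PFM
regions <- lapply(panel$genomes, function(g) {
  ops <- inferOperons(g)
  extractUpstream(g, ops[ops$leader_gene == "g01", ])
})
fp <- footprintFamily(regions, seedPattern(), familyLabel = "demo")
fp$pfm
# FrequencyMatrix [demo]
#   length 17 , built from 6 site(s); max attainable score 16
#   consensus: TGTCAGAATTATTAACA

## predict each species' regulon and aggregate
preds <- lapply(panel$genomes, predictRegulon, pfm = fp$pfm)
head(preds$sp01[, c("operon_id", "leader_gene", "site_sequence",
                    "distance_to_start", "score", "rank")])
#   operon_id leader_gene     site_sequence distance_to_start  score rank
# 1    opn001         g01 TGTCAGAATTATTAACA                33 1.0000    1
# 2    opn002         g02 TGTCAGAATTATTAACA                80 1.0000    1
# 3    opn003         g03 TGTCAGAATTATTAACA               102 1.0000    1
# 4    opn004         g04 TATCAGAATTATTAACA                36 0.9375    4
# 5    opn005         g05 TGTCAGGCTTATTAACA               102 0.8750    5

conservedAssociations(preds, panel$familyMap)[, 1:4]
#   family n_supporting conserved            supporting_genomes
# 1 anchor            6      TRUE sp01,sp02,sp03,sp04,sp05,sp06
# 2  fam02            6      TRUE sp01,sp02,sp03,sp04,sp05,sp06
# ...
```

Scores are relative similarities: `1.0000` means the site selects the
matrix's best nucleotide at every position; tied 2-decimal scores share the
lower rank. `distance_to_start` is the site 3′ edge to the translation
start (1 = immediately adjacent).

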