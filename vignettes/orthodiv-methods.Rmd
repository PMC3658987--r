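---
title: "Methods: comparative transcriptome divergence between close species pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative transcriptome divergence between close species pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiv)
```

## The analysis

`orthodiv` implements a comparative evolutionary analysis of two closely
related species starting from assembled transcriptome contigs, of the kind
used to characterise recently radiated plant species pairs. The chain is:

1. **Orthology.** Reciprocal best match (RBM) between the two contig sets by
   exact local alignment, then *triangulation* through an outgroup proteome:
   a pair is kept only when both contigs have the same best-hit outgroup
   protein. Triangulation trades recall for precision — it removes
   lineage-specific genes and recent paralogs that RBM alone mis-pairs.
2. **Coding structure.** Using the anchoring protein as a guide, each contig
   is assigned a CDS (extended codon-by-codon to the initiator ATG and the
   terminal stop where the alignment reaches the protein termini) and,
   where the CDS boundaries are internal to the contig, 5' and 3' UTRs.
3. **Codon alignment and filters.** Ortholog CDSs are aligned at the
   protein level and back-translated so gaps stay on codon boundaries.
   Alignments are discarded when they contain an internal stop codon, have
   fewer than 150 aligned ungapped nucleotides, or show Ks > 0.1 (a guard
   against residual paralogs in a species pair whose orthologs sit near
   Ks ≈ 0.03).
4. **Rates.** Ka and Ks by Nei–Gojobori (1986) counting and by a
   kappa-corrected counting variant (the package default), K2P distances
   for CDS and UTR partitions, selection classes from omega = Ka/Ks.
5. **Dating.** The mean synonymous divergence K over kept pairs is read as
   a clock: T = K / 2r with r the synonymous substitution rate
   (default 1.5e-8 substitutions/site/year, a standard dicot value).
6. **Enrichment.** Ortholog pairs are split at omega = 0.5 into a
   fast-evolving test set and a reference set; GO terms with at least five
   pooled occurrences are tested for over-representation with a one-sided
   Fisher exact test at raw p < 0.05.
7. **Markers.** MISA-style perfect-SSR detection (motifs 2–6 nt, ≥ 5
   units), cross-species matching of same-class tracts through the pair
   alignment, tract (≥ 16 bp) and flank-conservation filters for marker
   candidates, and single-copy nuclear gene mining by translated search of
   a reference single-copy protein set against per-pair consensus
   sequences (span ≥ 600 nt, identity ≥ 0.75, reference introns ≥ 300 nt
   counted for intron-spanning primer design).

Every stage is validated closed-loop against a synthetic species-pair
generator with a recorded truth table.

## Substitution-rate estimators

**K2P.** Transition (P) and transversion (Q) proportions are counted over
shared sites (both bases in ACGT; gaps and N pairwise-deleted), and
`d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`. Saturated inputs (non-positive log
arguments) are flagged undefined and excluded from means.

**NG86 counting conventions.** Synonymous site fractions per codon position
are the fraction of the three possible single-nucleotide changes that are
synonymous, with changes creating a stop codon counted as nonsynonymous;
this makes S + N equal exactly 3 × (number of compared codons). Codon pairs
differing at several positions are scored by averaging over all minimal
substitution pathways with equal weights; pathway steps are classified by
translation, with the stop state treated as an ordinary twenty-first state.
Filtered alignments contain no internal stops, so this convention only
matters for pathway intermediates, where its effect at Ks ≈ 0.03 is
negligible; it is chosen because it is exactly testable by enumeration.
Proportions are corrected with the Jukes–Cantor formula; pS or pN ≥ 0.75
flags saturation. Codons containing a gap or N in either sequence are
skipped entirely (pairwise deletion).

**Kappa-corrected counting.** The transition/transversion rate ratio kappa
is estimated from the alignment and used to weight site counting
(transition changes weighted kappa against 1 for transversions, again
normalised so S + N = 3 × codons), and distances are corrected by applying
the K2P formula separately to the transition and transversion components of
pS and pN. Kappa is estimated at **four-fold degenerate third positions**
(codon pairs sharing a four-fold family prefix), where every change is
synonymous and the observed transition excess therefore reflects the
mutation process. Estimating kappa from all third positions — the obvious
alternative — is measurably biased upward in simulation (mean ≈ 3.3 when
the true kappa is 2) because selection removes transversions
preferentially; the four-fold estimator recovers the simulated value. When
the four-fold estimate is undefined (no transversions observed, common at
Ks ≈ 0.03 for a single pair), kappa falls back to 2.

**Method disagreement is expected.** With transition bias (kappa = 2),
NG86's unweighted site counting undercounts synonymous sites at two-fold
degenerate positions (1/3 of a site against kappa/(kappa+2) = 1/2), so its
mean Ks runs ~10–15% above the kappa-corrected value on the same data —
the textbook motivation for kappa-corrected counting. The two methods
agree (within ~2%) only when kappa = 1. Package tests assert a 5%
agreement bound at kappa = 2; that bound is not attainable for these
estimators and the corresponding check documents the measured ~12%
discrepancy rather than hiding it.

**Selection classes.** Pairs with no substitutions are `identical`; pairs
with only one substitution type are `single-type` (omega undefined —
reporting infinite or zero ratios would distort summaries); otherwise
`reference` (omega < 0.5), `candidate` (0.5 ≤ omega ≤ 1), `positive`
(omega > 1). For enrichment partitioning the boundary omega = 0.5 goes to
the reference set, making the test set strictly omega > 0.5.

**Classification noise inflates the fast fraction.** At Ks ≈ 0.027 a
typical pair carries only ~9 synonymous and ~7 nonsynonymous differences,
so estimated omega scatters widely around its true value. Thresholding a
noisy ratio at 0.5 is asymmetric: far more pairs with true omega ≈ 0.25
(87% of the mixture) leak above 0.5 than pairs at 0.8 (13%) leak below.
In simulation the classified fraction is ~0.18–0.21 against a planted
0.13. This is a property of threshold classification at this divergence,
not an estimator defect; consumers of the "candidate selection" fraction
should read it as an upper bound.

## The synthetic species pair

The generator is first-class, tested code; its defaults are the study
conditions.

* **Ancestor genes** (`generate_ancestor_set`): CDS lengths uniform on
  300–2400 nt (mean ≈ 1350 nt, a realistic plant CDS average; the lower
  bound stays above the 150-nt alignment filter), ATG start, single
  terminal stop, codons drawn from a base composition targeting GC = 41.3%
  (the transcriptome-typical value emulated here); 5' UTRs 30–150 nt and
  3' UTRs 50–250 nt.
* **Divergence** (`evolve_species_pair`): each gene draws a true pairwise
  Ks from a Gamma with mean 0.027 and sd 0.017 and a true omega from a
  mixture — 87% Gamma(shape 6) centred on 0.25, 13% at 0.8 — giving a mean
  omega ≈ 0.32 and ~13% of genes above 0.5. Each lineage applies per-site
  Bernoulli substitution attempts at probability Ks/2 on a codon grid with
  transition bias kappa = 2; stop-creating changes are rejected and
  nonsynonymous changes accepted with probability omega. Start and stop
  codons are held fixed (strong constraint; also keeps the truth CDS
  well-defined for closed-loop tests). A full continuous-time codon model
  is unnecessary this far from saturation, and the Bernoulli process is
  exactly analyzable: the expected kappa-weighted synonymous divergence
  equals the drawn Ks.
* **UTR rate**: UTRs evolve neutrally at `utr_rate_multiplier` × the
  synonymous per-site rate. The default is 0.8 — not a value above 1 —
  because the emulated pattern is UTR K2P ≈ 0.018–0.019 against CDS K2P
  ≈ 0.011 with Ks ≈ 0.027: UTRs diverge ~1.7× faster than the *CDS
  average* but ~0.7× the *synonymous* rate (they are under relaxed, not
  absent, constraint). At the defaults the simulated UTR/CDS divergence
  ratio lands at ~1.5–1.8.
* **Outgroup proteome** (`make_outgroup_proteome`): the translated
  ancestor with 15% of residues substituted. Triangulation only needs a
  common best-hit anchor, so divergence level is uncritical; 15% keeps
  anchors unambiguous while exercising mismatch handling.
* **Contigs** (`fragment_to_contigs`): windows of each transcript with 56%
  of mass on 200–500 nt (the short-read assembly excess) and the rest on
  500–1200 nt; strand flips with probability 0.25; 5% paralog copies
  (extra 10% per-site divergence, safely beyond the Ks > 0.1 filter) and
  5% orphans as orthology confounders.
* **SSRs** (`plant_ssrs`): motifs drawn from a composition ~82%
  dinucleotide (AG, AT, AC dominant) and ~14% trinucleotide (AAG leading),
  5–10 units, inserted at homologous UTR positions of both contigs with
  one guard base each side so the tract cannot extend into its flanks;
  a configurable fraction of pairs gains 1–2 extra units in one species
  (length polymorphism). Planting is restricted to UTR positions covered
  by both contig windows so the coding frame is never disrupted — which
  also means truncated-contig simulations carry few planted SSRs; SSR
  closed-loop tests therefore use full-length contigs.
* **GO annotations** (`emit_go_annotations`): every gene draws each of 40
  background terms at probability 0.08; genes with true omega > 0.5 carry
  each designated enriched term with odds multiplied by the enrichment
  strength (1 = null).

Seeds: one master seed; every stage derives a deterministic child seed, so
stages are independently reproducible and the whole simulation is
byte-identical under a fixed seed.

**What the simulator does not model:** expression levels and tissue
pooling, assembly errors and chimeric contigs, indels inside coding
sequence (indels arise only from contig truncation), compound/interrupted
SSRs, and GO-graph structure (terms are flat labels). Passing closed-loop
tests therefore demonstrates correctness of the pipeline's logic under
substitution-only divergence, not robustness to misassembly or annotation
error in real data.

## Alignment machinery and numerical choices

Local and global pairwise alignments use exact dynamic programming
(Smith–Waterman / Needleman–Wunsch with affine gaps, via Biostrings'
C implementation). Scoring defaults: nucleotide match +1 / mismatch −2,
gap open 5 / extend 2; protein BLOSUM62, gap open 11 / extend 1; UTR
alignment match +1 / mismatch −1 / linear gap 2. Since no database-size
statistics (E-values) are computed, hits are accepted on raw score and
length minima (60 nt / 20 aa by default, configurable).

All-vs-all search uses an exact-word prefilter: only pairs sharing at
least one 16-nt word (either strand) — or 6-aa word for translated search —
are aligned. At the simulated divergences true orthologs share many such
words (e.g. P ≈ 0.985^16 ≈ 0.79 per 16-mer at 1.5% nucleotide divergence,
across hundreds of windows), while unrelated full-length contigs
essentially never do; 12-nt/4-aa words, by contrast, are shared by chance
between most unrelated full-length sequences and give no pruning.
Prefiltered and exact searches are tested for equivalence on seeded cases,
and the prefilter can be disabled in the configuration.

Ranking ties anywhere (best hits, best frames, best anchors) break
deterministically by score, then alignment length, then lexicographic id,
so reruns are byte-identical.

CDS delimitation tolerates local-alignment trimming of up to three
terminal residues when deciding whether the alignment "reaches" a protein
terminus, and prefers the start codon implied by the count of unaligned
leading residues before falling back to the furthest upstream in-frame
ATG; without these two rules, random in-frame UTR ATGs and trimmed
diverged terminal residues misplace the CDS start for a measurable
fraction of genes (exact CDS recovery in simulation rises from ~70% to
100% of delimited full-length contigs).

Coordinates are 0-based half-open everywhere internally; only the GFF3
writer converts to 1-based inclusive.

## Enrichment test

The 2×2 table per GO term counts term-bearing ortholog pairs (a pair
carries the union of its two contigs' terms) in the test and reference
sets. The one-sided p-value is the exact hypergeometric upper tail
(`stats::dhyper` sum), equal by construction to full enumeration — the
test suite verifies this for all margins up to 30. Terms with pooled
frequency below five are skipped; the headline filter is raw p < 0.05 with
no multiplicity correction (a Benjamini–Hochberg column is provided but
deliberately not applied, mirroring how such scans are conventionally
reported); the boundary p = 0.05 is excluded. Under the null the scan's
significant-term rate sits *below* the nominal 5% because an exact
conditional test is conservative under discreteness; tests assert the
one-sided bound (rate ≤ alpha + 3σ) rather than a two-sided band around
alpha, which would demand anti-conservatism no valid exact test exhibits.

## SSR definitions

A reported tract is a maximal perfect run of a primitive motif (2–6 nt; a
motif that is itself a repetition of a shorter motif is reported at the
shorter length only, which also excludes homopolymers), with at least five
full units, reported at the leftmost start of its periodic run. Canonical
motif classes collapse rotations and reverse complements (AG → AG/CT,
AT → AT/TA, AAG → AAG/CTT). Five repeat units apply uniformly to all motif
lengths, and the marker tract threshold is ≥ 16 bp (both configurable).
Compound SSRs are reported as separate loci. Marker flank defaults —
50 aligned columns per side at ≥ 0.9 identity — are primer-design
practice values, exposed in the configuration; they are a declared choice,
not an inferred one.

## Problem sizes in tests and the acceptance script

Validation uses desk-scale problem sizes chosen to give stable statistics:
rate recovery on 500 simulated pairs, NG86-vs-enumeration on 100 random
300-codon alignments, Fisher enumeration for all margins ≤ 30 plus 200
null scans, SSR scanner equivalence on 500 random contigs, and orthology
closure on 60–70 full-length genes. The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities at these sizes
from a fresh simulation under the supplied seed.

## Known limitations

* The kappa-corrected counting method is a deliberate simplification of
  full iterative ML counting (no codon-frequency weighting, no iterative
  update of proportions); at Ks ≈ 0.03 the difference is well inside the
  recovery tolerances, but the method is not bit-compatible with external
  ML tools.
* Dating by T = K/2r inherits everything that is wrong with a strict
  molecular clock and a borrowed rate constant; the sd propagated onto T
  reflects the spread of Ks across genes, not calibration uncertainty.
* The fast-evolving fraction (omega > 0.5) is inflated by classification
  noise at low divergence (see above).
* Orthology is one-to-one by construction; gene families with recent
  expansions are reduced to at most one retained pair or dropped by
  triangulation.
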