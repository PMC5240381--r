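---
title: "truncmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{truncmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

In iCLIP and related protocols (eCLIP, irCLIP, BrdU-CLIP) reverse
transcription usually stops at the peptide that UV crosslinking leaves on
the RNA. A sequenced cDNA therefore carries two mechanistically distinct
coordinates:

* the **cDNA-start**, one nucleotide downstream of the crosslink site
  (for the majority, truncated, class of cDNAs), and
* the **cDNA-end**, the position at which the RNA fragment was cleaved
  before adapter ligation — a property of the fragmentation chemistry,
  not of protein binding.

A minority of cDNAs read through the crosslinked peptide; these often
acquire a deletion at the crosslink and, with 4SU-mediated crosslinking,
T-to-C transitions can appear. truncmap implements the analyses that
exploit this geometry: positional deletion/transition profiles,
crosslink-associated (CL) motif enrichment at cDNA-starts,
permutation-FDR crosslink clusters built from start counts, diagnostics
that separate binding signal from cDNA-end constraints, and metagene RNA
maps around exon–exon junctions and pyrimidine (Y-)tracts.

The central mechanistic claim the package is built to test is that
*non-coinciding cDNA-starts* (systematic offsets between the starts of
short and long cDNAs) arise from **constrained cDNA-ends** — biased or
non-RNase-I fragmentation concentrating the ends on few positions — and
not from readthrough cDNAs. When the realized length of a cDNA is
dictated by the distance from its crosslink to a preferred cleavage
position, short and long cDNAs necessarily start at different positions
even when every single cDNA truncates faithfully.

## Coordinates and containers

All transcript-space coordinates are 0-based; intervals are half-open
`[start, end)`. The cDNA-end is reported as the 0-based inclusive index
of the last transcribed nucleotide. On minus-strand genomic alignments
the cDNA-start maps to the highest genomic coordinate; all offsets are
kept in transcript orientation. Mutation positions in user-facing
summaries are 1-based ("a deletion at the 6th nucleotide"). Aligned
cDNAs live in a `data.table` of class `cdna_tbl` with list columns for
deletion and transition offsets; BAM input is parsed with Rsamtools,
with transitions computed natively from the read/reference comparison
(reference-T → read-C in transcript orientation — the same event the
protocol literature sometimes writes as C-to-T when viewed from the
cDNA strand).

## The simulator: a stated world

`sim_config()` fixes the generative model; its defaults are the
conditions the analyses assume:

* `truncation_rate = 0.85` — comparative CLIP/iCLIP analyses place
  truncation above 80% of cDNAs; 0.85 is the package's single pinned
  value.
* `cdna_length_dist` — support must start at 17 nt: shorter cDNAs are
  not isolated by the protocol and rarely map uniquely. The default,
  uniform on 17–60 nt, represents a healthy broad-length library.
* `readthrough_tail_mean = 10` — readthrough cDNAs extend a geometric
  tail upstream of the crosslink. No published value exists for this
  geometry; 10 nt places readthrough deletions mid-read for sub-40-nt
  cDNAs, consistent with the observed deletion mode near cDNA centres.
* `readthrough_deletion_rate = 0.8` — most, not all, readthrough events
  leave a deletion; the exact rate is unpublished and only its order of
  magnitude matters to any analysis here.
* 4SU mode: `true_transition_rate = 0.5` on readthrough crosslinks that
  sit on a reference T, `background_transition_rate = 0.05` per
  reference T. The background dominates by design: in 4SU iCLIP most
  transitions do *not* mark crosslinks, and the simulator reproduces
  that regime.
* `pcr_duplication` — each molecule receives `1 + Poisson(mean)` PCR
  copies sharing a UMI. UMIs are drawn *without replacement*, so
  collapse recovers molecule counts exactly and the conservation
  invariant (`molecules = collapsed + dropped_short + dropped_no_cut`)
  holds with equality. Real libraries have rare UMI collisions; the
  exactness of the bookkeeping was judged more valuable than emulating
  a negligible collision rate.

Cleavage is `uniform` (the desired length is realized), `positional`
(cleavage snaps to the nearest allowed position whose distance from the
crosslink lies within the support range of the length distribution;
molecules with no legal cut are dropped and counted) or `sequence`
(cleavage only after a given base). The positional model with sparse
cuts is the package's instrument for creating hard cDNA-end
constraints: with one or two cuts per site, realized length becomes a
function of crosslink position and non-coinciding starts appear with
*zero* readthrough cDNAs — the mechanism test at the heart of the
acceptance suite.

What the generator does **not** emulate: sequencing-error mutations
beyond the two modelled classes, fragment-length biases of sonication,
multi-mapping, expression-level heterogeneity beyond site placement, or
real genome annotation. A green test therefore establishes that an
algorithm recovers the stated mechanism, not that it is robust to every
artefact of real libraries.

## Numerical and procedural choices

**CL-motif definition.** A k-mer scores the number of cDNAs with an
occurrence covering the nucleotide at offset −1 from the cDNA-start
versus offset −10; k-mers with ratio above 1.5 are kept and the TTTT
tetramer is excluded (it is usually part of longer T-tracts and blurs
positional resolution). "Covering" means any of the k registers
overlapping the anchor nucleotide. Each collapsed record counts once, so
the set is invariant to PCR duplication.

**First-7-nt subdivision.** cDNAs with a mutation in their first 7
nucleotides are split by motif placement: a motif *in the mutation zone*
is an occurrence fully contained in offsets 0–9 (the 1st–10th
nucleotides); a motif *at position 0* is an occurrence covering the
cDNA-start nucleotide (typically extending upstream over the crosslink).
Both can hold at once; the `precedence` argument decides, matching the
two opposite orderings used for deletion-based and transition-based
analyses. Multi-mutation cDNAs are classified by their most-5' mutation,
consistent with truncation logic.

**Crosslink clusters.** Start counts are summed in a symmetric ±15-nt
window (±3 nt for the fine-grained variant). The null repositions each
region's starts uniformly within the enclosing annotated region
(count-preserving); whether the original analysis shuffled within genes
or chromosomes is unstated, so the shuffle domain is the supplied region
table and is the caller's choice. The empirical FDR of window height h is
`mean(shuffled positions ≥ h) / (observed positions ≥ h)`, forced
non-increasing in h; heights are integers, ties share an FDR. Cluster
boundaries are the span of FDR-passing start positions — not extended by
the window — so cluster-length stratification (">30 nt") reflects start
dispersion. Retained positions less than 21 nt apart merge. One caveat
discovered in testing: because merging can bridge two clusters when a
looser threshold retains an intermediate position, the *number* of
clusters is not monotone in the FDR threshold; the retained-position set
and total clustered span are, and that is what the property tests
assert.

**Peaks.** The peak is the position with the maximum count; ties resolve
to the position closest to the region's 5' boundary. Peaks below the
median peak count of the collection are discarded. cDNA-end peaks at
junctions are searched at offsets −20..+25 from the first nucleotide of
the downstream exon, on junctions whose upstream exon is longer than
100 nt and in the top half by collapsed-cDNA coverage.

**End-constraint score.** `log2(end count at peak / mean end count at
offsets +5..+25)`. The 21-position flank mean includes zero-count
positions — otherwise the score would be biased upward at low depth —
and a zero flank yields a flagged `NA`, never infinity. The score is
exactly invariant to scaling all counts.

**Offset heatmap.** The short-versus-long start heatmap accumulates
comparison-bin start counts at offsets ±40 from every reference-bin
(>39 nt) start position, weighted by the reference count, then
normalises each row to 1. Per-row normalisation (rather than global) is
pinned here; the upstream tool this diagnostic emulates does not
document its choice.

**RNA maps.** The junction map uses
`RNAmap[n] = (cDNAs[n]/sum(cDNAs)) × length(mRNAs)/count(junctions)`,
so a uniform library converges to 1 at every offset; first and last
junctions per transcript are excluded. The Y-tract map MaxCount-
normalises each site within ±120 nt (removing per-site abundance
exactly), averages across sites anchored at the tract 3' end, and
divides by the mean over 50–100 nt downstream. Smoothing uses a
Gaussian kernel with sd = window/2 (windows 5 and 10 nt respectively),
truncated at 3 sd and applied as mass redistribution, so totals are
preserved to ~1e-9; the exact kernel of the original plotting package
is not published, so this one is pinned and recorded in the output
metadata.

**Pentamer discovery.** Occurrences in ±10-nt windows around start
peaks are compared with mononucleotide-shuffled window sequences;
`z = (obs − mean_bg)/sd_bg`. The z-score construction behind the
published "z > 299" threshold is not specified, so the threshold is a
parameter and the published 69-pentamer list is treated as
documentation, not a target. k-mers with zero background variance are
reported separately rather than given infinite scores.

**Cluster motif heatmap.** Length-sorted clusters are chunked into rows
of 300; within a row the left half of the coordinate is anchored at
cluster starts and the right half at cluster ends (boundary at half the
row's median length). The original figure's anchoring is only partially
described; this two-sided reading keeps both boundaries sharp across
rows.

**Pipeline.** One global seed fans out to per-stage child seeds
(seed+1 for reads, seed+2 for permutations). Configuration is JSON via
jsonlite — not YAML — because no YAML parser is part of the package's
pinned dependency environment; the resolved configuration is written
next to the outputs and reruns to byte-identical tables.

## What the tests establish

The acceptance suite is property-based: truncation fidelity at 50,000
molecules; planted-tetramer recovery in 20/20 seeds with a quiet null;
the Fig.-2-style contrast between no-deletion cDNAs (motif at the
start) and deletion-bearing cDNAs (motif inside the read); FDR
calibration on uniform nulls and ≥95% recovery of planted clusters; and
the central mechanism test — with zero readthrough, sparse cuts produce
off-zero offset-matrix modes and end-constraint scores more than 2 log2
units above the unconstrained world, while uniform cleavage keeps the
modal mass at offset 0. The printed percentages of the original study
(e.g. the 56/13/31% deletion split) depend on its real libraries and
are deliberately not asserted.

## Known limitations

* Transcriptome-space, plus-strand simulation; genome-space minus-strand
  handling is exercised only through the BAM loader.
* The cluster null is uniform within regions; structured nulls
  (expression-matched, dinucleotide-preserving) are out of scope.
* RNA secondary structure is not modelled or predicted; externally
  computed pairing probabilities can be aggregated but not produced.
* Insertions in reads are ignored (not part of the modelled mutation
  classes).
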