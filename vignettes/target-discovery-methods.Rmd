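---
title: "Methods: chromatin-gated discovery of direct TF targets"
author: "fostarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-gated discovery of direct TF targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fostarget)
```

## The scientific question

A transcription factor (TF) that is induced in a disease state — here
c-Fos in rod photoreceptors of the oxygen-induced retinopathy (OIR)
mouse — may drive pathology through a small set of direct transcriptional
targets. Candidate direct targets must satisfy two independent lines of
evidence:

1. **Chromatin evidence.** The TF binds the gene's promoter region in the
   disease state, and the promoter is in an active configuration there:
   a TF CUT&Tag peak, an H3K27ac peak (active enhancer/promoter) and an
   H3K4me3 peak (active promoter) all fall within ±1.0 kb of the
   transcription start site (TSS), while the repressive mark H3K27me3 does
   not. We call this boolean filter the *active-promoter gate*.
2. **Expression evidence.** Within the relevant cell type (rods), cells
   expressing the TF differ from cells not expressing it: the gene is a
   differentially expressed gene (DEG) between TF⁺ and TF⁻ rods, in the
   disease condition only.

The candidate set is the intersection of the condition-exclusive versions
of both: genes gated *only* in OIR, expressed in OIR rods, and
differentially expressed *only* in OIR. A separate promoter-dissection
engine then formalizes the follow-up experiment on an individual
candidate: scanning its promoter for AP-1/TRE motifs and reasoning over
luciferase reporter deletion constructs to localize the essential
promoter sub-region.

## Coordinate model

All interval logic uses 0-based half-open coordinates (the BED
convention); GTF input/output is converted at the boundary. The TSS is
`start` for a `+` strand gene and `end - 1` for a `-` strand gene. The
promoter window around a TSS is the closed ±w neighbourhood, realized as
the half-open interval `[tss - w, tss + w + 1)` — `2w + 1` bp, clipped at
the chromosome start. A gene carries a mark when **any** peak of that
mark overlaps its window by at least 1 bp; peaks are unstranded, and each
mark is evaluated independently (the gate does not require a single
shared peak interval, only co-occurrence of marks near the same TSS).
Overlap is computed with an interval index (`GenomicRanges`), and the
test suite holds it equal to a brute-force all-pairs oracle.

## Condition-exclusive set algebra

"Gated only in OIR" is implemented as *exclusive membership*: an element
of the focal set belonging to no other set in the same ledger. For the
two-condition ledgers used here this is an ordinary set difference, but
the definition generalizes to any number of conditions, and the report
machinery asserts the subset chain

`candidates ⊆ expressed_filtered ⊆ gate_focal_only ⊆ gate_focal`

on every run. The expression filter is applied after the gate
exclusivity and before the DEG intersection — chromatin evidence first,
then the requirement that the gene is detectable at all, then the
functional contrast. Reports store the sets themselves, not just their sizes, with a
config hash and input digests, so every printed cardinality is a derived
view of auditable data.

## Single-cell stage

Counts are normalized per cell to 10,000 (CP10K) and log1p-transformed;
zero-count cells are dropped with a warning. Cell typing is deterministic
marker scoring: per cell and type, the mean normalized expression over
the type's marker genes; the label is the argmax, with cells left
`unassigned` when the top score beats the runner-up by less than
`min_score_margin` (default 0.1 on the log1p CP10K scale — exact ties are
always unassigned). We deliberately replace clustering-plus-embedding
typing with marker scoring: the upstream analysis only needs rods
isolated, and a deterministic rule is reproducible and testable.

TF⁺ cells are those with raw TF count ≥ 1 (configurable); "expressed"
means detected in ≥ 1% of the relevant cells. Neither threshold has a
canonical published value; both are standard sparse-data conventions and
are exposed in `deg_config()`.

### The DEG test

Per gene we use the two-sided Mann-Whitney (Wilcoxon rank-sum) test —
the standard distribution-free two-group statistic for sparse,
non-normal expression values — with
Benjamini-Hochberg q-values and a log2 fold change of group mean CP10K
with a pseudocount of 1. A gene is a DEG when `q < 0.05` and
`|log2FC| ≥ 0.25`. Implementation choices:

* both groups ≤ 8 cells: exact enumeration of the rank-sum null over all
  `choose(nA+nB, nA)` labelings, which remains valid under ties because
  midranks are exchangeable under the permutation null;
* larger groups: normal approximation with the standard tie correction of
  the rank-sum variance and no continuity correction;
* a variance of zero (all values identical) yields p = 1.

The suite cross-checks the large-sample path against `stats::wilcox.test`
on tie-free data, the exact path against a brute-force permutation
oracle, and BH against an independently written step-up procedure. Under
a simulated global null the raw p < 0.05 fraction sits at its nominal
level (measured 0.04–0.06 across seeds).

## Promoter motif and reporter-construct engine

The TRE (AP-1) consensus TGA(C/G)TCA expands to the two 7-mers `TGACTCA`
and `TGAGTCA`, which are reverse complements of one another: each genomic
TRE is therefore reported once, with strand `+` when the forward strand
reads `TGACTCA` and `-` when it reads `TGAGTCA`. The *half site* is the
invariant 4-mer `TGAC` (reverse-strand reading `GTCA`); there is no
universal definition of an AP-1 half site, and this choice keeps the
half site inside every full TRE and contains the experimentally mutated
bases (TGAC→TTAC). The word list is configurable. Half sites inside a full TRE are annotated `embedded`. `N`
bases never match.

Reporter constructs live in TSS-relative coordinates (negative =
upstream, half-open intervals). A construct is the promoter span minus a
deletion, with a measured activity label. The essential region is

> (intersection of retained intervals over active constructs) −
> (union of retained intervals over inactive constructs).

Whenever this is non-empty, predicting a construct "active iff it retains
the whole essential region" reproduces the input labels exactly — actives
retain a superset of the intersection, and the subtraction step makes the
essential region disjoint from every inactive construct. (With
adversarial designs the subtraction can empty the region; inference then
fails loudly rather than returning an unfalsifiable answer.) Applied to
the five-construct series for the Adam17 promoter (full 1.1 kb
active; constructs deleting the proximal 0.3 kb or 0.5 kb inactive;
constructs retaining the proximal 0.5 kb or 0.3 kb active), the engine
returns `[-300, 0)` — the proximal 0.3 kb that carries the functional
half site:

```{r constructs}
constructs <- adam17_reporter_constructs()
infer_essential_region(constructs)
vapply(constructs, predict_activity, character(1),
       essential = infer_essential_region(constructs))
```

## The synthetic-data generator

The generator (`sim_config()`, `simulate_bundle()`) emulates the
workflow's inputs at desk scale; its defaults are the package's fixed
study conditions.

* **Genome and annotation.** 1,000 non-overlapping genes on 3 toy
  chromosomes of 3 Mb, gene footprints 1–4 kb, random strands, and a
  minimum intergenic gap of 2 kb. The gap guarantees that a peak planted
  in one gene's ±1 kb window can never touch a neighbour's window — the
  toy genome deliberately has no bidirectional promoters, so gate
  evidence is attributable to single genes. Real genomes violate this;
  on real data neighbouring genes can share gate evidence and candidates
  must be interpreted accordingly.
* **Peaks.** Planted 400 bp peaks centred uniformly within ±w/2 of the
  TSS for every gate-active gene (activation marks) and repressed decoy
  (all four marks); partial decoys get only two of the three activation
  marks; uniform Poisson background peaks (2×10⁻⁶ per bp per track,
  ~6 per Mb) on every track including IgG.
* **Counts.** Negative binomial (size 2) with per-gene log-normal
  baseline means (median 1 count per cell, ~1,700 counts per cell over
  1,000 genes); 600 cells per condition, 70% rods with three minor types
  at 10% each; 5 markers per type boosted 10-fold in the owning type.
  The TF is bimodal in rods: planted positives draw `1 + NB`, negatives
  exactly 0 (50% positive in OIR rods, 10% in normal rods).
* **Planted DEGs.** 20 direct targets (up-regulated 4-fold in TF⁺ OIR
  rods, gate-active only in OIR) plus 30 DEG-only decoys, half of them
  down-regulated. Planted-DEG baselines are drawn from 0.3–1.2 counts,
  and the down-regulated genes' baselines are rescaled so the expected
  library mass they lose in TF⁺ cells equals the mass the up-regulated
  genes add. Without this mass balance, TF status confounds per-cell
  library size, and per-cell normalization converts the composition
  shift into a global rank shift that a Wilcoxon test at hundreds of
  cells per group flags across the whole transcriptome — an artifact
  worth remembering when interpreting real TF⁺/TF⁻ comparisons, where
  composition is *not* guaranteed balanced.
* **Promoters.** Random sequences with TRE full/half sites planted at
  recorded positions; an iterative repair loop re-draws single background
  bases until no accidental motif words remain outside planted
  footprints (never touching a planted footprint; bounded at 200 passes),
  so scans recover exactly the planted sites.

Each component draws from its own seed sub-stream (fixed offsets from the
bundle seed), so bundles are byte-deterministic and components
independently reproducible.

### What passing the recovery tests does and does not show

On default bundles the pipeline recovers planted targets with
sensitivity and precision ≥ 0.9 (exactly, at the measured seeds), and
with background peaks off and an 8-fold effect, recovery is exact. This
validates the *logic* of the chain — every boolean term of the gate, the
exclusivity algebra, the DEG thresholds — under conditions where truth is
known. It does not validate peak calling (consumed as input), marker
choice on real tissue, or gate assignment in genomes with overlapping
promoter windows. Reproducing gene counts published for the real retinal
datasets would additionally require the original raw data, the upstream
peak-calling pipeline, and DEG settings that were never published; that
is out of scope — the package ships the machinery, not those numbers.

## Numerical and design choices

* Ranking of candidates: descending |log2FC|, ties lexicographic by gene
  id — no ranking is prescribed by the evidence, so determinism wins.
* Duplicate peaks are tolerated; gating is idempotent under duplication.
* Gene ids are the join key everywhere; duplicate ids are fatal at parse
  time, duplicate display names are allowed.
* Peak files: BED3 and 10-column narrowPeak are accepted; extra
  narrowPeak columns are ignored. `end ≤ start` is a hard error.
* The MatrixMarket dialect stores genes × cells on disk (the common
  single-cell convention); the in-memory orientation is cells × genes.
* Problem sizes in the test suite (160-gene bundles for unit tests,
  1,000-gene bundles for acceptance-grade checks, 2,000 cells for the
  law-of-large-numbers check) were chosen to make every stochastic
  assertion stable at its stated threshold while keeping the default
  suite fast.

## Known limitations

* The gate treats marks as independent presence/absence near the TSS; it
  does not require overlapping peak intervals, model peak strength, or
  consider distal enhancers beyond ±w.
* Marker scoring assumes marker genes are informative and reasonably
  exclusive; it has no doublet or ambient-RNA model.
* The generator's NB model has no gene–gene correlation, batch structure
  or dropout beyond NB sampling; its promoter model has no GC or
  dinucleotide structure.
* Exact Mann-Whitney enumeration is limited to groups of ≤ 8 cells by
  design; beyond that the tie-corrected normal approximation is used.
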