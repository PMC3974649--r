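---
title: "Detecting and classifying gross chromosomal rearrangements in the chrV marker-loss assays"
author: "gcrsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying gross chromosomal rearrangements in the chrV marker-loss assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcrsig)
```

## The assay and what this package computes

The *S. cerevisiae* chromosome V marker-loss (GCR) assays select cells that
have simultaneously lost a `CAN1/URA3` counter-selectable cassette placed on
the left arm of chrV while keeping the most telomeric essential gene,
`PCM1`. A hygromycin-resistance marker, `hph`, sits telomeric of the
cassette, so whether a rearranged isolate keeps or loses `hph` is a
one-plate structural readout: interstitial deletions and
`URA3/ura3-52`-resolved inverted duplications keep it, de novo telomere
additions and most translocations do not. Four evidence streams are used to
type each isolate: paired-end sequencing (junction calls and junction
sequence), aCGH-style copy-number tracks, MLPA peak areas, and an
AscI/PFGE size-and-probe pattern. `gcrsig` implements all four analysis
arms, the integrating classifier, and the cohort statistics (G-test of
marker retention, Mann-Whitney rate comparisons, Lea-Coulson fluctuation
rates), driven by a synthetic-data generator so every stage is testable
without external data.

## The model assay chromosome

`buildAssayChromosome()` emits a synthetic chromosome whose *topology*,
repeat homology and motif content — not its literal sequence — carry the
assay logic. The analysis depends only on those properties, so a
pseudo-random backbone with recognizable marker tracts suffices and no
reference genome download is needed. The layout places, telomere to
centromere: a TG1-3 telomeric seed, `hph`, the first AscI site, the
cassette with `URA3` telomeric of `CAN1`, the GCR breakpoint region (bounded
by the cassette and `PCM1`), `PCM1`, the `VMA8`/`BUD16`/`GEA2` probe genes,
`ura3-52`, and `CEN5`; a second hph-homologous tract and `MCM3` lie between
the two AscI sites so that the internal AscI fragment hybridizes to both
Southern probes, as the wild-type digest requires. Two layout facts deserve
comment:

* `URA3` is telomeric of `CAN1` within the cassette. Inverted duplications
  are resolved by homologous recombination between the cassette `URA3` and
  `ura3-52`, and the recaptured telomeric fragment must retain `hph` but
  lose `CAN1` (the event is selected on canavanine); only this internal
  order makes both true simultaneously.
* `ura3-52` stores its URA3-homology core and a Ty-consensus tract in
  *inverted* orientation. The duplicated segment of a fold-back product is
  an inverted copy, so storing the homology inverted on the reference makes
  the fused product co-oriented and seamless — the sequence-level
  consequence of how these chromosomes are drawn mechanistically.

Coordinates are 1-based inclusive throughout the R API, the native
convention of `GRanges`/`Biostrings`; BED and bedGraph exports are 0-based
half-open as those formats require. The default length is 580 kb
(chrV-like); tests and the worked examples use 50 kb scaled layouts, which
keep marker tract sizes fixed in bp while scaling positions.

## Rearrangement constructors and deterministic truth

Each constructor edits the reference *locally* before building the product,
so truth labels are exact rather than sampled:

* **Interstitial deletions** plant the requested junction microhomology by
  copying the m terminal bases of the retained telomeric flank over the m
  bases preceding the centromeric breakpoint, then place mismatch guards
  one base beyond each end (inside the deleted interval, so the product is
  untouched). Annotation therefore recovers breakpoints and microhomology
  exactly, with no rejection sampling.
* **Inverted duplications** follow the hairpin mechanism: the loop template
  is a reference interval, a priming-homology inverted repeat is planted
  immediately telomeric of it (guarded at length + 1), and the product is
  `captured fragment + reverse complement of [arm start, resolution
  anchor] + [loop, right telomere]`. The resolution argument selects the
  captured fragment: `URA3/ura3-52` recaptures the hph-containing end
  through the cassette URA3 (hph retained), `Ty/Ty` captures a
  Ty-capped donor (hph lost), `none` captures nothing. Loop ends are made
  non-complementary so palindrome arms stop exactly at the loop.
* **De novo telomeres** prefix an irregular TG1-3 seed (a TG/TGG/TGGG
  mixture — enough irregularity to exercise the detector without modelling
  telomerase); **translocations** prefix an arbitrary donor. Both guard
  the retained base so the mapped junction side ends exactly at the truth
  coordinate.

At the 580 kb default, inverted duplications drawn in the breakpoint region
produce 4-19 kb deletions spanning the cassette and 80-100 kb duplications
ending at `ura3-52`, the extents observed in the assay.

## Read simulation, mapping and junction calling

The library model defaults to a 600 bp (sd 60) insert, 100 bp error-free
reads, 50-fold coverage; duplicates are exact copies of earlier pairs,
matching coordinate-based deduplication semantics. Reads are mapped back to
the reference by exact matching on both strands (`matchPDict`); a read is
*uniquely mapping* iff it has exactly one genome-wide hit, which the SAM
writer encodes as MAPQ 42 versus 0, and the SAM reader applies as a
MAPQ >= 20, non-secondary dialect. Exact matching is the correct aligner
for error-free simulated reads and keeps the pipeline deterministic and
in-process; reads that span a novel junction match nowhere and surface as
the half-mapped pairs the method depends on. A mismatch-tolerant mapper is
deliberately out of scope.

Calling proceeds as: deduplicate; estimate the insert distribution from
convergent uniquely-mapped pairs (median and MAD of the outer span; the
concordance cutoff is median + 10 MAD, configurable — at the default
library this is roughly 1.2 kb, so the Gaussian insert tail contributes no
discordant pairs under the null); greedily single-linkage-cluster the
discordant pairs in coordinate order, requiring matching orientations and
start coordinates within one cutoff on both sides. Fold-back geometry
(both sides on one target, same orientation) is kept as a distinct call
geometry with a lower default support floor (2 versus 3), because
palindromic junctions amplify and sequence poorly and yield fewer pairs.
Cluster significance is a Poisson tail test of the support count against a
genome-wide chimeric-pair background rate estimated from the data
(alpha = 0.01); the original method says only "statistically significant",
so the test is our choice and both knobs are exposed.

Junction-sequencing reads — unmapped mates whose partner maps beside a
call, in that side's orientation — are assembled by greedy exact-overlap
layout (minimum overlap 20 bp, both orientations tried, lexicographic
tie-breaks) followed by per-column majority consensus. De novo telomere
additions produce *no* junction-defining pairs at all (one side of the
junction is unmappable), so the pipeline falls back to one-sided
recruitment anchored at the copy-number terminal-deletion boundary and
hands the assembled consensus to the same annotator.

## Junction annotation

`locateJunction()` finds the maximal exact prefix and suffix matches of the
consensus on either strand (anchor 15 bp); their overlap on the consensus
is the microhomology and a gap is the non-templated insert — the two are
mutually exclusive, and when a split is ambiguous the microhomology
description is preferred, matching the colon notation of junction reports.
Because assembly emits an arbitrary strand, annotation canonicalizes
orientation (re-annotating the reverse complement when all placed sides
map to the minus strand) so reported breakpoints are strand-independent.
`detectFoldback()` aligns the consensus to its own reverse complement
(`findPalindromes`), reports the unpaired centre as the loop, and takes as
priming homology the maximal inverted repeat flanking the loop that is
*templated by the reference* — distinguishing the few bases that primed
the hairpin from the arbitrarily long palindrome the product itself
carries. The fold-back centre is reported as the loop-template midpoint;
the geometry, not the initiating break, is what the data constrain. TG1-3
conformity is scored by greedy TG/TGG/TGGG tiling with a 90% threshold
over at least 15 nt; a side whose placement is shorter than 40 exact bases
does not veto telomere detection, because a fresh telomere seed can match
the reference telomere tracts weakly by chance.

## Copy number, PFGE and classification

aCGH probes are simulated one per window from the truth record's interval
accounting (haploid semantics: duplication = log2 + 1, deletion = floor at
-4), with windows over the `hph`/`CAN1` insertions unprobed, as on a
native-genome array. Segmentation thresholds (duplicated >= +0.58,
deleted <= -1.0) sit midway between copy states under noise; runs shorter
than 3 probes are absorbed into the larger neighbour and boundaries fall at
probe midpoints. One scaled-layout artifact is worth knowing: at 50 kb the
deletion flanking an inverted duplication is mostly unprobed (it largely
covers the omitted cassette windows), so its probe run can fall under the
3-probe floor and be absorbed into the adjacent duplication; classification
is unaffected because junction evidence dominates, but deletion extents for
inverted duplications are better resolved at full scale. MLPA areas are
proportional to copy number with multiplicative noise (default cv 0.05);
analysis normalizes by the median control/sample ratio over declared
copy-neutral reference probes and calls amplification at ratio >= 1.5 (the
1-vs-2-copy midpoint) and deletion at <= 0.3. The in-silico AscI digest
cuts at every `GGCGCGCC`, reports boolean probe hybridization per fragment,
and classes chromosome size against the reference with a ±2% gel-resolution
band.

`classifyGcr()` integrates the streams with junction evidence taking
precedence (it is base-resolution): fold-back junction or
breakpoint-anchored duplication with a larger chromosome implies an
inverted duplication; a deletion junction with no duplication and a
similar-or-smaller chromosome an interstitial deletion (at test scale a
cassette-spanning deletion can exceed the ±2% band, so "similar" alone
would be wrong — hph retention and junction geometry still separate it
from telomere additions and translocations); telomere-addition junctions a
de novo telomere; distant or strand-inconsistent junctions a
translocation; more than one repeat-bounded duplication a complex event;
and contradictory evidence (duplication with a wild-type-like size) is
left unclassified with notes. hph status is read from the genome directly
— the synthetic proxy for growth on hygromycin.

## Statistics

Marker retention is tested with the maximum-likelihood G-test against the
wild-type retention distribution (2 of 27) as the expected proportions:
G = 2 sum O ln(O/E), one degree of freedom, no Williams correction — this
exact convention reproduces all five published retention p-values
computable from printed counts at one significant figure, which is why no
correction is applied. Rate comparisons use the two-tailed Mann-Whitney U
(exact by enumeration for small tie-free samples, otherwise the normal
approximation with tie correction; significance at 0.01 as the assay
literature uses). Fluctuation rates use the Lea-Coulson method of the
median — solve median/m - ln m = 1.24, rate = m / cells per culture — with
an all-zero median handled at 0.5 and flagged as an upper bound, the "<"
convention of the rate tables. Reported retention percents follow the
printed convention: integer at >= 1%, one significant figure below 1%
(so 15 of 2435 prints as 0.6%). Fold increases are ratios rounded to two
significant figures. Absolute published rates are not recomputable
(cells-per-culture are not printed), so the package tests ratios and
estimator recovery on simulated experiments instead.

## Worked example

```{r example, eval = FALSE}
chrom <- buildAssayChromosome(length = 50000, seed = 1)
iso <- applyInvertedDuplication(chrom, dsb = 4000, foldback = 4200,
                                loop = 30, primingHomology = 5)
res <- runIsolate(iso, libraryModel(seed = 7), id = "demo")
res$classification
res$annotations[[1]]$foldback
```

A full cohort run (`runCohort`) draws truth-labelled isolates per class,
analyses each end-to-end, and summarises classifications against truth, the
duplication-by-hph two-way table and the retention row; the configuration
seed fans out to per-stage seeds so identical configs give byte-identical
summaries.

## What the simulations do and do not show

The generator emulates the assay's feature topology, the four product
architectures with parameters in the observed ranges (loops 25-44 nt,
priming homologies 3-9 bp, 0-5 bp deletion microhomology — the generator
accepts wider ranges since rarer values may occur), a 600 bp paired-end
library, and probe-level noise. It does not emulate sequencing error,
mapping ambiguity of a real repeat-rich genome (Ty homology is a single
consensus tract, and donor disambiguation among identical repeats is not
attempted), selection dynamics on the assay media, or
telomerase-independent survivors. Green end-to-end tests therefore
demonstrate the correctness of the pipeline's logic and conventions, not
its robustness to real-data noise; insert-size estimation, the
concordance cutoff and the significance test are the components that would
absorb most real-data differences, and all are exposed as parameters.
Analysis problem sizes (50 kb chromosome, 50-fold coverage, 20-isolate
cohorts, 200-replicate estimator studies) were chosen as the smallest at
which every stage operates in its intended regime.
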