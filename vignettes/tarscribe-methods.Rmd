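---
title: "Methods: TAR discovery and digital expression analysis with tarscribe"
author: "tarscribe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAR discovery and digital expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarscribe)
```

# Overview

`tarscribe` implements a post-alignment analysis of bulk RNA-seq and
small-RNA sequencing built around simple, explicit counting rules rather
than model fitting: transcriptionally active regions (TARs) from per-base
coverage, novel transcript units from paired-end linking in intergenic
space, alternative-splicing (AS) classification from validated splice
junctions, gene-boundary extensions from read-through coverage, an exact
two-library test for differential expression, a hypergeometric GO
enrichment, a small-RNA annotation cascade with known-miRNA matching, and
a positional join of differentially expressed (DE) genes to GWAS hits.
The design assumes one sequencing library per condition (no replicates),
a non-stranded protocol, and uniquely mapped reads as the only evidence.

All internal coordinates are 0-based half-open; conversion to and from
the 1-based conventions of GTF happens only in the readers and writers.
Coverage, interval complements and overlap queries are delegated to
GenomicRanges/IRanges; connected components to igraph; binomial and
hypergeometric tail probabilities to the `stats` distribution functions.

# TARs and novel transcript units

A **TAR** is a maximal run of bases each covered by at least
`min_depth = 2` uniquely mapped reads (multi-position reads are excluded
everywhere; spliced reads contribute depth on their aligned blocks only).
TARs joined by at least one read pair — mate 1 overlapping one TAR and
mate 2 the other, both mates uniquely mapped — are connected into a
**transcript unit** (connected components of the linking relation;
unlinked TARs become single-exon units). The text the procedure derives
from does not say whether linking pairs had to be unique on both mates;
we require it, consistent with the unique-read coverage rule.

A unit is a **putative novel transcript unit** when

* its span lies wholly within **intergenic space** — the genome minus
  gene spans padded by `margin = 200` bp on each side;
* its longest contiguous covered run (depth ≥ 1) is ≥ `min_len = 150` bp
  ("continuous mapping length", read literally as the longest contiguous
  covered stretch); and
* its average coverage is ≥ 2, averaged over the covered (member-TAR)
  bases of the span rather than the span including mate-pair gaps, so
  the statistic is insensitive to the gap length between linked TARs.

Novel units are finally clustered into transcriptionally active regions
by single-linkage merging of spans with inter-span gaps ≤ 3 kb; the gap
comparison is inclusive, reading "± 3 kb" as a tolerance. Filtering is
applied at the unit level after linking, following the order of the
source procedure (units located in intergenic regions are the novel
candidates).

# Splice junctions and AS classification

A junction is the gap between consecutive blocks of a spliced read; gaps
shorter than 20 bp are treated as putative indels, not introns (a
standard convention; the source text is silent). A junction is
**validated** when supported by ≥ 2 uniquely mapped reads with ≥ 5
aligned bases on both sides of the splice; the overhang criterion is
evaluated on the maximum over supporting reads, reading the requirement
as a property of the junction's support.

Validated junctions are assigned to genes by containment of the gap in
the gene span, and four AS models are classified:

* **Exon skipping (ES)** — a junction joining the boundaries of two
  non-adjacent annotated exons; one event per skipped exon.
* **A5SS / A3SS** — two junctions sharing one boundary and differing at
  the other. The varying side is resolved against the gene strand (the
  donor is the 5' side of the transcribed intron), so a shared-donor
  pair is A3SS on a plus-strand gene and A5SS on a minus-strand gene.
  Pairs whose two varying boundaries are both annotated exon boundaries
  are excluded: two annotated junctions sharing an anchor describe exon
  skipping, not alternative splice-site use.
* **Intron retention (IR)** — an annotated intron with every base at
  depth ≥ 2, both flanking exons expressed (mean depth ≥ 2), and no
  validated junction whose gap contains the whole intron. The source
  text gives no operational IR rule; this is the minimal coverage-based
  definition consistent with the TAR logic, and it is documented here as
  this package's rule rather than asserted as the original one.

Events pool across samples on the identity key (gene, type,
coordinates), giving per-gene distinct-event counts and the
multi-event distribution.

# Gene boundaries

A read-supported gene model attaches to a gene every TAR that overlaps
its span (coverage-contiguous read-through is part of that TAR by
maximality) or is linked to an overlapping TAR by a mate pair. A TAR
attachable to two genes goes to the nearer span end; ties are left
unassigned. The 5'/3' extension is the distance from the annotated to
the extended boundary, strand-mirrored on minus-strand genes, and is
measured to the farthest contiguous covered base — the evidence is read
support only, not a model of the true transcription start or end. All
extensions ≥ 1 bp are reported; summaries bin at ≥ 50 bp.

# Differential expression and enrichment

Expression is RPKM: reads per kilobase of flattened exon (union of all
transcripts' exons per gene — "exon region in a gene" is gene-level) per
million uniquely mapped reads. Reads are assigned to the gene whose
flattened exons they overlap most; ties are unassigned.

The two-library test is the exact conditional test on a count pair:
given $x + y$, under the null $y \sim \mathrm{Binomial}(x+y,\;
n_2/(n_1+n_2))$ with $n_1, n_2$ the library totals. The two-sided p
doubles the smaller tail and caps at 1 — the source analysis calls both
directions while the underlying test is defined one-sided. A pair with
$x = y = 0$ carries no evidence and returns p = 1; such genes are
excluded from testing, and genes zero in exactly one library receive a
half-count continuity floor for the log2 ratio only, keeping the ratio
finite without perturbing the exact test. Multiple testing uses the
Benjamini–Hochberg step-up (the standard referent where only "FDR" is
stated), and a gene is significant when FDR ≤ 0.001 and |log2 ratio|
≥ 1. For miRNAs the small-RNA rule applies instead: raw p < 0.01 (no
FDR) and |log2 fc| ≥ 1 on TPM-normalised counts.

GO enrichment is the upper-tail hypergeometric test per term,
Bonferroni-corrected over the tested terms (at least one background and
one DE gene), significance at corrected p ≤ 0.05. The background
universe is configurable and defaults to all annotated genes; the
original choice is unstated.

# Small RNA

Tag tables (sequence, count) are cleaned by exact 3'-adapter-prefix
trimming and restricted to 18–30 nt. The annotation cascade assigns each
tag exactly one category in a fixed priority order — rRNA > tRNA >
scRNA/snRNA/snoRNA > repeat > exon > intron > unannotated — because the
source names the categories but not their precedence; structural RNA is
excluded first, matching common practice, and determinism requires a
fixed order. Excluded categories are removed before miRNA analysis.
Known-miRNA matching allows at most two substitutions, evaluated with up
to 2 nt of terminal offset between tag and mature sequence (isomiR
tolerance; mature-length variation is ubiquitous). Ties between mature
miRNAs split the count and are flagged. Quantities are TPM on the
clean-read total.

# GWAS integration

Per trait, only the most significant SNP (minimum Bonferroni-corrected
P; ties keep all) is used. A significant DE gene is a positional
candidate when the minimum distance from any base of its span to the SNP
is ≤ 2.5 Mb, inclusive — "within 2.5 Mb around" is read as a region, and
gene spans are long, so the anchor is the nearest span base rather than
a midpoint. Optional knockout-phenotype annotations attach by gene id.

# The synthetic-data generator

The generator defines the package's reference study conditions and emits
machine-readable planted truth for every stage. Defaults: a 1 Mb
single-chromosome genome; 20 non-overlapping genes of 2–8 exons
(exons 120–300 bp, introns 100–400 bp) separated well beyond the 200 bp
margins; 50 intergenic novel units (single parts of 300–800 bp, or two
parts of 250–400 bp linked only by mate pairs); ten planted events of
each AS type; ten boundary-extended genes (60–500 bp per end); 90 bp
paired-end reads with a 200 bp insert at 10× expressed depth — read
length, insert size and depth scale match the sequencing design the
analysis was built for. The two-library count experiment spans 2,000
genes with a baseline Poisson mean of 50 and 10% of genes planted at
|log2 fc| = 1.5 (one library's rate multiplied by 2^±1.5), matching the
exact test's own Poisson sampling assumption. Small-RNA tags (default
10,000 draws) mix mature-derived tags (Zipf-skewed abundance, 0–2
substitutions; the top-ranked mature sequence is pinned to the canonical
22 nt) with category-derived substrings under a 22 nt-modal length
profile whose 20–23 nt mass exceeds 84%.

Reads are emitted directly as alignments (BED12/SAM), not FASTQ: the
mapping stage is out of scope, so simulating sequence would test nothing
this package computes. Read starts are Poisson, uniform within each
expressed feature's transcript; spliced reads arise from the
transcript-to-genome mapping. Planted features carry **construction
guarantees**: AS events receive at least four constructed junction reads
with generous overhangs (both junctions of an A5SS/A3SS pair); planted
retained introns are double-tiled together with both flanking exons, and
boundary extensions double-tiled to their full length, so every base
reaches the TAR depth; two-part units receive explicit linking pairs. A
configurable fraction of reads is re-emitted as multi-mapping decoys
that every stage must ignore.

What the generator does **not** emulate: sequencing error and quality
strings, GC and positional bias, stranded protocols, overlapping genes,
isoform mixtures within a gene, replicate-level biological variance
(counts are exactly Poisson), and genuine repeat structure. Passing
recovery tests therefore demonstrates that the counting rules are
implemented exactly and are mutually consistent — not that they are
robust to real-data artefacts the source analysis itself did not model.

# Numerical and degenerate-input choices

Zero-length inputs (no genes, no reads, all-zero coverage) return empty
results rather than errors; an annotation-free chromosome is wholly
intergenic. Ties are never broken arbitrarily: tied read assignments are
dropped with a message, tied TAR-to-gene attachments are left unassigned,
tied mature-miRNA matches split counts. The clustering and window rules
are inclusive at their thresholds (gap = 3000 merges; distance = 2.5 Mb
keeps). p-values live in (0, 1] by construction; the doubled-tail p is
capped at 1.

# Problem sizes and verification

The test suite and the acceptance script exercise the reference
conditions above: exact-test enumeration over all pair sums to 200 at
library ratios 1, 2 and 5; 10,000 null Poisson(50) pairs; a 2,000-gene
DE experiment; one 1 Mb genome with 50 planted units, 40 planted AS
events and ~13 planted extensions; 100 random coverage tracks against a
per-base scan oracle; 10,000 small-RNA tags; and a doubled end-to-end
pipeline run compared by checksum. These sizes give stable statistics
(binomial standard errors well inside the asserted bands) while keeping
a full run in the order of a minute on one core.

# Known limitations

* No replicate-aware dispersion: the exact test treats each library as
  one Poisson draw per gene, anti-conservative for biological replicates.
* Junction discovery consumes spliced alignments; it does not align
  reads to junction libraries itself.
* The IR rule cannot distinguish retention from overlapping independent
  transcription, and the boundary rule cannot distinguish read-through
  from an unannotated downstream gene; both inherit the source
  analysis's evidence model.
* Alternative first/last exons and mutually exclusive exons are not
  classified, and hairpin-based novel-miRNA prediction and ncRNA
  homology classification are out of scope.
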