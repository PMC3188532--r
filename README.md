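# tarscribe

Post-alignment transcriptome analysis for bulk RNA-seq and small-RNA
sequencing, for researchers who want the classical counting-rule
pipeline — transcriptionally active regions, novel transcript units,
alternative-splicing classification, exact two-library differential
expression — as tested, reusable R functions rather than one-off scripts.

## What it computes

Starting from a gene annotation (GTF/BED12) and aligned reads (BED12
blocks or minimal SAM), with uniquely mapped reads as the only evidence:

* **TARs** — maximal runs of bases with per-base depth ≥ 2.
* **Novel transcript units** — TARs connected by mate pairs, lying wholly
  in intergenic space (gene spans padded by 200 bp), with continuous
  covered length ≥ 150 bp and average coverage ≥ 2; clustered into
  regions at a ±3 kb gap.
* **Splice junctions and AS events** — junctions validated by ≥ 2 reads
  with ≥ 5 bp overhangs on both sides, classified into A5SS, A3SS, exon
  skipping and intron retention against the annotation.
* **Gene-boundary extensions** — contiguous read support past annotated
  5'/3' ends, attached by coverage or mate pairs.
* **Differential expression** — RPKM quantification and the exact
  conditional test on a count pair: given x + y, under the null
  y ~ Binomial(x + y, n₂/(n₁+n₂)); two-sided p doubles the smaller
  tail. Significance at BH-FDR ≤ 0.001 and |log₂ ratio| ≥ 1; GO
  enrichment by upper-tail hypergeometric test with Bonferroni
  correction.
* **Small RNA** — 18–30 nt tag cleaning, an annotation filter cascade,
  known-miRNA matching with ≤ 2 substitutions (2 nt terminal-offset
  tolerance), TPM, and miRNA DE at raw p < 0.01 and |log₂ fc| ≥ 1.
* **GWAS integration** — significant DE genes within 2.5 Mb of each
  trait's most significant SNP become positional candidates.

A seeded synthetic-data generator (`generate_dataset()`) emits a toy
genome, spliced paired-end alignments, count tables and small-RNA tags
with machine-readable planted truth for every stage; the methods
vignette (`vignettes/tarscribe-methods.Rmd`) documents every rule,
default and design decision.

## Worked example

```r
library(tarscribe)

cfg <- simulation_config(seed = 1)          # 1 Mb genome, 20 genes,
ds  <- generate_dataset(cfg)                # 50 planted novel units, ...

cs    <- setNames(cfg$genome_length, cfg$chrom)
cov   <- compute_coverage(ds$alignments, cs)
tars  <- call_tars(cov, min_depth = 2)
units <- link_tars(tars, ds$alignments, cov)
novel <- filter_novel_units(units, define_intergenic(ds$annotation, 200, cs))
head(novel$units, 3)
#>   unit_id chrom start   end n_exons n_linking_pairs avg_coverage max_run
#> 1 TU00001  chr1  3606  4283       1               0    12.754801     677
#> 2 TU00002  chr1 21258 21995       2               2    14.532884     303
#> 3 TU00003  chr1 46532 47320       2               2     9.172249     361
```

149 TARs collapse into 70 transcript units, of which exactly the 50
planted intergenic units pass the novelty filters (the rest is gene-body
transcription); `TU00002` is a two-part unit whose parts are joined by
two mate pairs, with average depth 14.5 over covered bases and a longest
contiguous covered run of 303 bp.

```r
ev <- classify_events(validate_junctions(extract_junctions(ds$alignments)),
                      ds$annotation, cov)
table(ev$type)
#> A3SS A5SS   ES   IR
#>   10   10   10   10

de <- call_de(ds$counts$counts_a, ds$counts$counts_b)
head(de[de$significant, c("gene_id", "x", "y", "log2_ratio", "p", "q")], 3)
#>    gene_id   x   y log2_ratio            p            q
#> 4    g0004 151  49   1.607371 4.896919e-13 1.570612e-11
#> 9    g0009  60 150  -1.338252 2.644933e-10 3.833237e-09
#> 12   g0012  61 148  -1.295040 9.567328e-10 1.267196e-08
```

All forty planted AS events are recovered with their planted types, and
195 of the 2,000 genes are called differentially expressed (104 up), all
of them planted: e.g. `g0004` with counts 151 vs 49 gives a normalised
log₂ ratio of 1.61 with q ≈ 1.6 × 10⁻¹¹, far below the 0.001 FDR
threshold.

The whole pipeline, with every output file checksummed into a run
manifest, is one call (or `Rscript inst/scripts/tarscribe.R run --seed 1
--out run/` from a shell):

```r
manifest <- run_pipeline(pipeline_config(seed = 1, outdir = "run"))
```

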