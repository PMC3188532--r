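# Shared fixture builders; everything is generated in code at test time.

# alignment table from a compact block spec:
# list(list(id, mate, blocks = matrix(start, end), unique), ...)
make_aln <- function(reads, chrom = "chr1") {
  rows <- lapply(reads, function(r) {
    bl <- r$blocks
    data.frame(read_id = r$id, mate = if (is.null(r$mate)) 1L else r$mate,
               chrom = chrom, start = bl[, 1], end = bl[, 2],
               block = seq_len(nrow(bl)),
               unique = if (is.null(r$unique)) TRUE else r$unique,
               stringsAsFactors = FALSE)
  })
  alignment_blocks(do.call(rbind, rows))
}

blk <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# a three-exon plus-strand gene used across splicing tests
three_exon_gene <- function(strand = "+") {
  gene_annotation(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                       end = 600L, strand = strand, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g1", chrom = "chr1",
                       start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
                       stringsAsFactors = FALSE))
}

# coverage track from an explicit depth vector (0-based base i = depth[i+1])
cov_track <- function(depth, chrom = "chr1") {
  stats::setNames(list(S4Vectors::Rle(as.numeric(depth))), chrom)
}

# transcript_units object built directly from a span table
make_units <- function(df) {
  df$unit_id <- sprintf("TU%05d", seq_len(nrow(df)))
  members <- data.frame(unit_id = df$unit_id, chrom = df$chrom,
                        start = df$start, end = df$end,
                        mean_depth = df$avg_coverage, stringsAsFactors = FALSE)
  structure(list(units = df, members = members), class = "transcript_units")
}

# memoised heavyweight fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached_dataset <- function(seed = 101) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_dataset(simulation_config(seed = seed))
  .fixture_cache[[key]]
}

cached_pipeline_run <- function(seed, tag) {
  key <- paste0("run", seed, tag)
  if (is.null(.fixture_cache[[key]])) {
    outdir <- file.path(tempdir(), paste0("tarscribe_", seed, "_", tag))
    manifest <- run_pipeline(pipeline_config(seed = seed, outdir = outdir))
    .fixture_cache[[key]] <- list(manifest = manifest, outdir = outdir)
  }
  .fixture_cache[[key]]
}

# reciprocal-overlap matching of interval sets (match = ro >= min_ro)
reciprocal_matches <- function(a, b, min_ro = 0.5) {
  vapply(seq_len(nrow(a)), function(i) {
    ov <- pmax(0, pmin(a$end[i], b$end) - pmax(a$start[i], b$start))
    any(ov / (a$end[i] - a$start[i]) >= min_ro & ov / (b$end - b$start) >= min_ro)
  }, logical(1))
}
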