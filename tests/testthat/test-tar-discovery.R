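test_that("coverage counts unique-read blocks only, gaps excluded", {
  aln <- make_aln(list(
    list(id = "a", blocks = blk(10, 100)),
    list(id = "b", blocks = blk(10, 100)),
    list(id = "c", blocks = blk(200, 240, 440, 490)),   # spliced 40M200N50M
    list(id = "d", blocks = blk(10, 100), unique = FALSE)))
  cov <- compute_coverage(aln, c(chr1 = 1000L))
  d <- as.numeric(cov$chr1)
  expect_equal(d[11:100], rep(2, 90))       # two unique reads, not three
  expect_equal(d[241:440], rep(0, 200))     # no depth on the splice gap
  expect_equal(d[201:240], rep(1, 40))
  expect_equal(sum(d), 2 * 90 + 40 + 50)
})

test_that("coverage conserves total aligned bases over random reads", {
  set.seed(7)
  reads <- lapply(seq_len(1000), function(i) {
    s <- sample(0:9000, 1)
    list(id = paste0("r", i), blocks = blk(s, s + sample(30:90, 1)))
  })
  aln <- make_aln(reads)
  cov <- compute_coverage(aln, c(chr1 = 10000L))
  expect_equal(sum(as.numeric(cov$chr1)), sum(aln$end - aln$start))
})

test_that("coverage rejects blocks beyond the chromosome end", {
  aln <- make_aln(list(list(id = "a", blocks = blk(990, 1100))))
  expect_error(compute_coverage(aln, c(chr1 = 1000L)), "beyond chromosome end")
})

test_that("call_tars returns exactly the maximal depth runs", {
  cov <- cov_track(c(0, 0, 3, 3, 1, 2, 2, 0))
  tars <- call_tars(cov, min_depth = 2)
  expect_equal(tars$start, c(2L, 5L))
  expect_equal(tars$end, c(4L, 7L))
  expect_equal(tars$mean_depth, c(3, 2))

  expect_equal(nrow(call_tars(cov_track(rep(0, 50)))), 0L)

  uni <- call_tars(cov_track(rep(5, 100)))
  expect_equal(uni$start, 0L)
  expect_equal(uni$end, 100L)
})

test_that("call_tars agrees with the per-base scan oracle on random tracks", {
  set.seed(11)
  for (i in seq_len(100)) {
    depth <- stats::rpois(500, lambda = stats::runif(1, 0.5, 4))
    got <- call_tars(cov_track(depth), min_depth = 2)
    want <- tar_oracle(depth, 2)
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
    expect_equal(got$mean_depth, want$mean_depth)
  }
})

test_that("mate pairs link TARs into units; chains form one component", {
  # three TARs with depth-2 coverage; pairs link A-B and B-C
  reads <- list()
  for (tar in list(c(100, 300), c(1000, 1200), c(2000, 2200)))
    for (r in 1:2)
      reads[[length(reads) + 1L]] <- list(id = sprintf("c%d_%d", tar[1], r),
                                          blocks = blk(tar[1], tar[2]))
  reads <- c(reads,
    list(list(id = "p1", mate = 1L, blocks = blk(150, 240)),
         list(id = "p1", mate = 2L, blocks = blk(1000, 1090)),
         list(id = "p2", mate = 1L, blocks = blk(1100, 1190)),
         list(id = "p2", mate = 2L, blocks = blk(2000, 2090))))
  aln <- make_aln(reads)
  cov <- compute_coverage(aln, c(chr1 = 3000L))
  tars <- call_tars(cov, 2)
  expect_gte(nrow(tars), 3L)
  units <- link_tars(tars, aln, cov)
  expect_equal(nrow(units$units), 1L)
  expect_equal(units$units$n_exons, 3L)
  expect_equal(units$units$n_linking_pairs, 2L)

  # without the pairs: three single-exon units (union-find oracle: no edges)
  aln2 <- make_aln(reads[1:6])
  cov2 <- compute_coverage(aln2, c(chr1 = 3000L))
  units2 <- link_tars(call_tars(cov2, 2), aln2, cov2)
  expect_equal(nrow(units2$units), 3L)
  expect_true(all(units2$units$n_exons == 1L))
})

test_that("non-unique mates never link TARs", {
  reads <- list()
  for (tar in list(c(100, 300), c(1000, 1200)))
    for (r in 1:2)
      reads[[length(reads) + 1L]] <- list(id = sprintf("c%d_%d", tar[1], r),
                                          blocks = blk(tar[1], tar[2]))
  reads <- c(reads,
    list(list(id = "p1", mate = 1L, blocks = blk(150, 240), unique = FALSE),
         list(id = "p1", mate = 2L, blocks = blk(1000, 1090), unique = FALSE)))
  aln <- make_aln(reads)
  cov <- compute_coverage(aln, c(chr1 = 2000L))
  units <- link_tars(call_tars(cov, 2), aln, cov)
  expect_equal(nrow(units$units), 2L)
})

test_that("intergenic space is the complement of margin-padded gene spans", {
  ann <- gene_annotation(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       start = c(1000L, 5000L), end = c(2000L, 6000L),
                       strand = "+"),
    exons = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       start = c(1000L, 5000L), end = c(2000L, 6000L)))
  ig <- define_intergenic(ann, margin = 200, chrom_sizes = c(chr1 = 10000L))
  expect_equal(ig$start, c(0L, 2200L, 6200L))
  expect_equal(ig$end, c(800L, 4800L, 10000L))

  none <- gene_annotation(
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character()),
    exons = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer()))
  expect_equal(define_intergenic(none, 200, c(chr1 = 5000L)),
               data.frame(chrom = "chr1", start = 0L, end = 5000L))

  # genes 300 bp apart: padded spans overlap, no gap between them
  close <- gene_annotation(
    genes = data.frame(gene_id = c("a", "b"), chrom = "chr1",
                       start = c(1000L, 2300L), end = c(2000L, 3000L),
                       strand = "+"),
    exons = data.frame(gene_id = c("a", "b"), chrom = "chr1",
                       start = c(1000L, 2300L), end = c(2000L, 3000L)))
  ig2 <- define_intergenic(close, 200, c(chr1 = 5000L))
  expect_false(any(ig2$start >= 2000L & ig2$end <= 2300L))
})

test_that("novel-unit filters apply the length, coverage and overlap rules", {
  ig <- data.frame(chrom = "chr1", start = c(0L, 3000L), end = c(2000L, 9000L))
  u <- make_units(data.frame(
    chrom = "chr1",
    start = c(100L, 1999L, 3100L, 3500L),
    end = c(400L, 2600L, 3300L, 3800L),
    n_exons = 1L, n_linking_pairs = 0L,
    avg_coverage = c(3, 3, 3, 1.9),
    max_run = c(150L, 300L, 149L, 300L), stringsAsFactors = FALSE))
  kept <- filter_novel_units(u, ig, min_len = 150, min_avg_cov = 2)
  # unit 1: within intergenic, run 150 -> kept (boundary)
  # unit 2: leaves intergenic space by 1 bp region boundary -> rejected
  # unit 3: run 149 -> rejected; unit 4: avg 1.9 -> rejected
  expect_equal(kept$units$start, 100L)
})

test_that("unit clustering merges gaps up to and including 3 kb", {
  u <- make_units(data.frame(
    chrom = "chr1", start = c(0L, 2000L, 6000L), end = c(200L, 2300L, 6100L),
    n_exons = 1L, n_linking_pairs = 0L, avg_coverage = 3,
    max_run = 200L, stringsAsFactors = FALSE))
  reg <- cluster_units(u, gap = 3000)
  expect_equal(reg$start, c(0L, 6000L))
  expect_equal(reg$end, c(2300L, 6100L))
  expect_equal(reg$n_units, c(2L, 1L))
  expect_equal(sum(reg$n_units), nrow(u$units))   # membership conserved

  # gap exactly 3000: merged (inclusive rule)
  u2 <- make_units(data.frame(
    chrom = "chr1", start = c(0L, 3200L), end = c(200L, 3400L),
    n_exons = 1L, n_linking_pairs = 0L, avg_coverage = 3,
    max_run = 200L, stringsAsFactors = FALSE))
  expect_equal(nrow(cluster_units(u2, gap = 3000)), 1L)
  expect_equal(nrow(cluster_units(u2, gap = 2999)), 2L)

  one <- make_units(data.frame(chrom = "chr1", start = 5L, end = 100L,
                               n_exons = 1L, n_linking_pairs = 0L,
                               avg_coverage = 2, max_run = 95L,
                               stringsAsFactors = FALSE))
  expect_equal(nrow(cluster_units(one)), 1L)
})

test_that("TAR invariants hold on random coverage: maximality and depth", {
  set.seed(23)
  for (i in seq_len(20)) {
    depth <- stats::rpois(400, 1.5)
    tars <- call_tars(cov_track(depth), min_depth = 2)
    for (r in seq_len(nrow(tars))) {
      s <- tars$start[r]; e <- tars$end[r]
      expect_true(all(depth[(s + 1):e] >= 2))
      if (s > 0) expect_lt(depth[s], 2)
      if (e < length(depth)) expect_lt(depth[e + 1], 2)
    }
  }
})
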