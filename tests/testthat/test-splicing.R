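test_that("junction extraction counts supporting unique reads and overhangs", {
  aln <- make_aln(list(
    list(id = "a", blocks = blk(1000, 1040, 1240, 1290)),
    list(id = "b", blocks = blk(995, 1040, 1240, 1300)),
    list(id = "c", blocks = blk(1000, 1040, 1240, 1290), unique = FALSE)))
  jn <- extract_junctions(aln)
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$n_reads, 2L)                 # non-unique read not counted
  expect_equal(jn$donor_end, 1040L)
  expect_equal(jn$acceptor_start, 1240L)
  expect_equal(jn$max_overhang_left, 45L)      # max over supporting reads
  expect_equal(jn$max_overhang_right, 60L)
})

test_that("gaps below the minimum intron length are not junctions", {
  aln <- make_aln(list(list(id = "a", blocks = blk(100, 150, 160, 200))))
  expect_equal(nrow(extract_junctions(aln, min_intron = 20)), 0L)
  aln2 <- make_aln(list(list(id = "a", blocks = blk(100, 150, 170, 200))))
  expect_equal(nrow(extract_junctions(aln2, min_intron = 20)), 1L)
})

test_that("per-junction counts match a hash-count oracle on simulated reads", {
  set.seed(31)
  sites <- data.frame(d = seq(1000, 10000, by = 1000),
                      a = seq(1000, 10000, by = 1000) + 500)
  draws <- sample(nrow(sites), 500, replace = TRUE)
  reads <- lapply(seq_along(draws), function(i) {
    s <- sites[draws[i], ]
    lft <- sample(10:60, 1); rgt <- sample(10:60, 1)
    list(id = paste0("r", i), blocks = blk(s$d - lft, s$d, s$a, s$a + rgt))
  })
  jn <- extract_junctions(make_aln(reads))
  oracle <- table(draws)
  expect_equal(nrow(jn), length(oracle))
  got <- jn$n_reads[match(sites$d[as.integer(names(oracle))], jn$donor_end)]
  expect_equal(got, as.integer(oracle))
})

test_that("junction validation needs 2 reads and 5 bp on both sides", {
  jn <- data.frame(chrom = "chr1",
                   donor_end = c(100L, 200L, 300L),
                   acceptor_start = c(500L, 600L, 700L),
                   n_reads = c(1L, 2L, 3L),
                   max_overhang_left = c(50L, 5L, 4L),
                   max_overhang_right = c(50L, 5L, 50L))
  v <- validate_junctions(jn, min_reads = 2, min_overhang = 5)
  expect_equal(v$donor_end, 200L)   # 1 read rejected; 4 bp overhang rejected
})

test_that("a junction bridging non-adjacent exons is exon skipping", {
  ann <- three_exon_gene()
  jn <- data.frame(chrom = "chr1", donor_end = 200L, acceptor_start = 500L,
                   n_reads = 3L, max_overhang_left = 40L,
                   max_overhang_right = 40L)
  cov <- cov_track(rep(0, 700))
  ev <- classify_events(jn, ann, cov)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "ES")
  expect_equal(c(ev$start, ev$end), c(300L, 400L))   # the skipped exon
})

test_that("junction pairs sharing a donor are A3SS on + and A5SS on -", {
  jn <- data.frame(chrom = "chr1", donor_end = c(200L, 200L),
                   acceptor_start = c(300L, 320L), n_reads = 3L,
                   max_overhang_left = 40L, max_overhang_right = 40L)
  cov <- cov_track(rep(0, 700))
  ev_plus <- classify_events(jn, three_exon_gene("+"), cov)
  expect_equal(ev_plus$type, "A3SS")
  expect_equal(c(ev_plus$start, ev_plus$end), c(300L, 320L))
  ev_minus <- classify_events(jn, three_exon_gene("-"), cov)
  expect_equal(ev_minus$type, "A5SS")
})

test_that("two annotated junctions sharing an anchor are not called A5SS/A3SS", {
  # donor of exon1 to acceptors of exon2 and exon3: the second junction is
  # the skipping junction; no alternative-splice-site call should appear
  jn <- data.frame(chrom = "chr1", donor_end = c(200L, 200L),
                   acceptor_start = c(300L, 500L), n_reads = 3L,
                   max_overhang_left = 40L, max_overhang_right = 40L)
  ev <- classify_events(jn, three_exon_gene(), cov_track(rep(0, 700)))
  expect_equal(sort(unique(ev$type)), "ES")
})

test_that("a fully covered annotated intron with no spanning junction is IR", {
  depth <- rep(0, 700)
  depth[101:400] <- 3          # exon1 + intron1 + exon2 covered
  depth[501:600] <- 3          # exon3 covered
  cov <- cov_track(depth)
  ann <- three_exon_gene()
  no_jn <- data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer(), n_reads = integer(),
                      max_overhang_left = integer(),
                      max_overhang_right = integer())
  ev <- classify_events(no_jn, ann, cov)
  ir <- ev[ev$type == "IR", ]
  expect_equal(nrow(ir), 1L)
  expect_equal(c(ir$start, ir$end), c(200L, 300L))   # intron1 only

  # the same intron with a validated spanning junction is not retained
  jn <- data.frame(chrom = "chr1", donor_end = 200L, acceptor_start = 300L,
                   n_reads = 2L, max_overhang_left = 10L,
                   max_overhang_right = 10L)
  ev2 <- classify_events(jn, ann, cov)
  expect_equal(nrow(ev2[ev2$type == "IR", ]), 0L)

  # a one-base hole in the intron breaks the IR call
  depth2 <- depth; depth2[250] <- 1
  ev3 <- classify_events(no_jn, ann, cov_track(depth2))
  expect_equal(nrow(ev3[ev3$type == "IR", ]), 0L)
})

test_that("junctions outside every gene are reported separately", {
  jn <- data.frame(chrom = "chr1", donor_end = 5000L, acceptor_start = 5300L,
                   n_reads = 3L, max_overhang_left = 40L,
                   max_overhang_right = 40L)
  ev <- classify_events(jn, three_exon_gene(), cov_track(rep(0, 6000)))
  expect_equal(nrow(ev), 0L)
  expect_equal(nrow(attr(ev, "unassigned")), 1L)
})

test_that("classification is invariant to junction input order", {
  ds <- cached_dataset(101)
  cfg <- ds$config
  cov <- compute_coverage(ds$alignments,
                          stats::setNames(cfg$genome_length, cfg$chrom))
  vj <- validate_junctions(extract_junctions(ds$alignments))
  ev1 <- classify_events(vj, ds$annotation, cov)
  set.seed(3)
  vj2 <- vj[sample(nrow(vj)), , drop = FALSE]
  ev2 <- classify_events(vj2, ds$annotation, cov)
  attr(ev1, "unassigned") <- attr(ev2, "unassigned") <- NULL
  rownames(ev1) <- rownames(ev2) <- NULL
  expect_equal(ev1, ev2)
})

test_that("pooling removes redundancy and counts per-gene events", {
  e1 <- data.frame(gene_id = "g1", type = "ES", chrom = "chr1", start = 300L,
                   end = 400L, coordinates = "chr1:300-400", evidence = "x",
                   sample = "liver", stringsAsFactors = FALSE)
  e2 <- e1; e2$sample <- "muscle"
  e3 <- e1; e3$sample <- "af"
  e4 <- data.frame(gene_id = "g1", type = "A3SS", chrom = "chr1", start = 500L,
                   end = 520L, coordinates = "chr1:500-520", evidence = "y",
                   sample = "liver", stringsAsFactors = FALSE)
  pooled <- pool_events(list(e1, rbind(e2, e4), e3))
  expect_equal(nrow(pooled$events), 2L)   # same ES in 3 tissues pooled to 1
  expect_equal(pooled$events$n_samples[pooled$events$type == "ES"], 3L)
  expect_equal(pooled$per_gene$n_events, 2L)
})

test_that("pooled counts equal a set-union oracle on random event multisets", {
  set.seed(13)
  base <- expand.grid(gene_id = sprintf("g%02d", 1:6),
                      type = c("ES", "IR", "A5SS", "A3SS"),
                      start = c(100L, 900L), stringsAsFactors = FALSE)
  base$chrom <- "chr1"; base$end <- base$start + 100L
  base$coordinates <- sprintf("chr1:%d-%d", base$start, base$end)
  base$evidence <- "e"
  sets <- lapply(c("s1", "s2", "s3"), function(sm) {
    d <- base[sample(nrow(base), 25, replace = TRUE), , drop = FALSE]
    d$sample <- sm
    d
  })
  pooled <- pool_events(sets)
  all <- do.call(rbind, sets)
  oracle <- unique(all[, c("gene_id", "type", "coordinates")])
  expect_equal(nrow(pooled$events), nrow(oracle))
  oracle_per_gene <- table(oracle$gene_id)
  expect_equal(pooled$per_gene$n_events[match(names(oracle_per_gene),
                                              pooled$per_gene$gene_id)],
               as.integer(oracle_per_gene))
})
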