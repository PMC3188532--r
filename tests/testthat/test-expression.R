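test_that("RPKM follows the count / exonic-kb / million-mapped identity", {
  ann <- gene_annotation(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 0L,
                       end = 1000L, strand = "+"),
    exons = data.frame(gene_id = "g1", chrom = "chr1", start = 0L, end = 1000L))
  reads <- lapply(1:10, function(i) list(id = paste0("r", i),
                                         blocks = blk(10 * i, 10 * i + 90)))
  expr <- quantify(make_aln(reads), ann, total_mapped = 1e6)
  expect_equal(expr$count, 10L)
  expect_equal(expr$rpkm, 10)
  # direct formula evaluation at another operating point
  expect_equal(250 / (2500 / 1000) / (8.5e6 / 1e6), 11.7647, tolerance = 1e-4)
  # zero reads
  expr0 <- quantify(make_aln(list(list(id = "far", blocks = blk(5000, 5090)))),
                    ann, total_mapped = 1e6)
  expect_equal(expr0$rpkm, 0)
})

test_that("reads are assigned to the gene with the larger exon overlap", {
  ann <- gene_annotation(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       start = c(0L, 1000L), end = c(1050L, 2000L),
                       strand = "+"),
    exons = data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                       start = c(0L, 1000L), end = c(1050L, 2000L)))
  # "bigger": 90 bp in gA vs 20 bp in gB -> gA; "tie": 70 bp in each
  aln <- make_aln(list(list(id = "bigger", blocks = blk(930, 1020)),
                       list(id = "tie", blocks = blk(980, 1070))))
  expect_message(expr <- quantify(aln, ann, total_mapped = 100), "tied")
  expect_equal(expr$count[expr$gene_id == "gA"], 1L)
  expect_equal(expr$count[expr$gene_id == "gB"], 0L)
  expect_equal(attr(expr, "n_assigned"), 1L)
})

test_that("assignment conserves reads: counts sum to assigned reads", {
  ds <- cached_dataset(101)
  expr <- quantify(ds$alignments, ds$annotation)
  expect_equal(sum(expr$count), attr(expr, "n_assigned"))
})

test_that("the exact test matches tail enumeration and handles zeros", {
  expect_equal(audic_claverie_p(0, 0, 1e6, 1e6), 1)
  expect_equal(audic_claverie_p(5, 15, 1e6, 1e6), ac_oracle(5, 15, 1e6, 1e6),
               tolerance = 1e-12)
  # library-ratio cases
  for (r in c(1, 2, 5)) {
    for (xy in list(c(0, 7), c(3, 3), c(20, 5), c(50, 50))) {
      expect_equal(audic_claverie_p(xy[1], xy[2], 1e6, r * 1e6),
                   ac_oracle(xy[1], xy[2], 1e6, r * 1e6), tolerance = 1e-10)
    }
  }
})

test_that("the exact test is symmetric under library swap", {
  set.seed(17)
  for (i in seq_len(500)) {
    x <- sample(0:100, 1); y <- sample(0:100, 1)
    n1 <- sample(1e5:1e7, 1); n2 <- sample(1e5:1e7, 1)
    expect_equal(audic_claverie_p(x, y, n1, n2),
                 audic_claverie_p(y, x, n2, n1), tolerance = 1e-12)
  }
})

test_that("bh_fdr matches the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(19)
  for (i in 1:20) {
    p <- stats::runif(sample(3:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))   # monotone in sorted-p order
  }
})

test_that("DE calls honour both the FDR and fold-change thresholds", {
  a <- data.frame(gene_id = c("flat", "de", "dead"),
                  count = c(100L, 400L, 0L), stringsAsFactors = FALSE)
  b <- data.frame(gene_id = c("flat", "de", "dead"),
                  count = c(100L, 100L, 0L), stringsAsFactors = FALSE)
  res <- call_de(a, b, n1 = 1e7, n2 = 1e7)
  expect_false("dead" %in% res$gene_id)       # zero in both: excluded
  expect_false(res$significant[res$gene_id == "flat"])
  de_row <- res[res$gene_id == "de", ]
  expect_true(de_row$significant)
  expect_equal(de_row$log2_ratio, 2)
  expect_equal(de_row$direction, "up")
  expect_equal(de_row$p, ac_oracle(400, 100, 1e7, 1e7), tolerance = 1e-10)
  expect_lt(de_row$p, 0.001)
})

test_that("swapping libraries negates ratios and preserves p and q", {
  set.seed(29)
  ids <- sprintf("g%03d", 1:50)
  a <- data.frame(gene_id = ids, count = stats::rpois(50, 40))
  b <- data.frame(gene_id = ids, count = stats::rpois(50, 40))
  r1 <- call_de(a, b, n1 = 1e6, n2 = 2e6)
  r2 <- call_de(b, a, n1 = 2e6, n2 = 1e6)
  m <- match(r1$gene_id, r2$gene_id)
  expect_equal(r1$log2_ratio, -r2$log2_ratio[m], tolerance = 1e-12)
  expect_equal(r1$p, r2$p[m], tolerance = 1e-12)
  expect_equal(r1$q, r2$q[m], tolerance = 1e-12)
})

test_that("mismatched gene universes are an error", {
  a <- data.frame(gene_id = c("g1", "g2"), count = c(1L, 2L))
  b <- data.frame(gene_id = c("g1", "g3"), count = c(1L, 2L))
  expect_error(call_de(a, b), "gene universe")
})

test_that("GO enrichment matches direct hypergeometric enumeration", {
  # N=100 background, K=10 in term, n=10 DE, k=5 in term
  background <- sprintf("g%03d", 1:100)
  term_genes <- background[1:10]
  de <- c(background[1:5], background[51:55])
  g2g <- data.frame(gene_id = term_genes, term_id = "T1",
                    category = "biological process", stringsAsFactors = FALSE)
  res <- go_enrichment(de, g2g, background)
  oracle <- sum(vapply(5:10, function(i)
    choose(10, i) * choose(90, 10 - i) / choose(100, 10), numeric(1)))
  expect_equal(res$p_hyper, oracle, tolerance = 1e-12)
  expect_equal(res$k, 5L)
  expect_equal(res$p_bonferroni, res$p_hyper)   # one tested term

  # k = 0 -> term untested
  g2g0 <- data.frame(gene_id = background[90:95], term_id = "T2",
                     category = "molecular function", stringsAsFactors = FALSE)
  expect_equal(nrow(go_enrichment(background[1:5], g2g0, background)), 0L)

  # Bonferroni multiplies by the number of tested terms
  g2g2 <- rbind(g2g, data.frame(gene_id = background[c(1, 60)], term_id = "T3",
                                category = "cellular component"))
  res2 <- go_enrichment(de, g2g2, background)
  expect_equal(res2$p_bonferroni, pmin(1, res2$p_hyper * 2))
})

test_that("miRNA DE uses a raw p threshold and requires both conditions", {
  a <- data.frame(mirna_id = c("m1", "m2", "m3"),
                  count = c(100L, 300L, 187L), stringsAsFactors = FALSE)
  b <- data.frame(mirna_id = c("m1", "m2", "m3"),
                  count = c(100L, 100L, 100L), stringsAsFactors = FALSE)
  res <- mirna_de(a, b, n1 = 1e6, n2 = 1e6)
  expect_false(res$significant[res$mirna_id == "m1"])
  expect_true(res$significant[res$mirna_id == "m2"])
  m3 <- res[res$mirna_id == "m3", ]                 # |log2fc| = 0.90 < 1
  expect_lt(m3$p, 0.01)
  expect_lt(abs(m3$log2_ratio), 1)
  expect_false(m3$significant)
})
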