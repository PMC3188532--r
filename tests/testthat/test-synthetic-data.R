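test_that("generation is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 9, n_genes = 6, n_novel_units = 4,
                           as_events_per_type = 2, n_boundary_extensions = 2,
                           count_genes = 100, genome_length = 2e5)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("degenerate configurations behave: no genes, infeasible genome", {
  cfg0 <- simulation_config(seed = 1, n_genes = 0, n_novel_units = 2,
                            as_events_per_type = 0, n_boundary_extensions = 0,
                            genome_length = 5e4)
  gen <- generate_annotation(cfg0)
  expect_equal(nrow(gen$annotation$genes), 0L)
  expect_equal(nrow(gen$truth$as_events), 0L)

  cfg_small <- simulation_config(seed = 1, n_genes = 1000, genome_length = 1e5)
  expect_error(generate_annotation(cfg_small), "genome_length too small")
})

test_that("genes are disjoint with margins realisable and 2-8 exons", {
  gen <- generate_annotation(simulation_config(seed = 21))
  g <- gen$annotation$genes
  o <- order(g$start)
  expect_true(all(g$start[o][-1] - g$end[o][-nrow(g)] > 400))
  n_ex <- table(gen$annotation$exons$gene_id)
  expect_true(all(n_ex >= 2 & n_ex <= 8))
  # planted novel units stay clear of the 200 bp margins
  tr <- gen$truth$novel_units
  for (i in seq_len(nrow(tr)))
    expect_true(all(tr$end[i] <= g$start - 200 | tr$start[i] >= g$end + 200))
})

test_that("expressed gene bodies reach the configured depth within 20%", {
  cfg <- simulation_config(seed = 25, n_genes = 4, n_novel_units = 0,
                           as_events_per_type = 0, n_boundary_extensions = 0,
                           depth_mean = 20, genome_length = 2e5)
  gen <- generate_annotation(cfg)
  aln <- simulate_alignments(gen$annotation, gen$truth, cfg)
  cov <- compute_coverage(aln, stats::setNames(cfg$genome_length, cfg$chrom))
  ex <- gen$annotation$exons
  # interior exonic bases (transcript ends ramp over one read length)
  depths <- unlist(lapply(seq_len(nrow(ex)), function(i)
    as.numeric(S4Vectors::window(cov[[cfg$chrom]], ex$start[i] + 1L, ex$end[i]))))
  expect_gt(mean(depths), 0.8 * cfg$depth_mean)
  expect_lt(mean(depths), 1.2 * cfg$depth_mean)
})

test_that("zero depth means zero reads", {
  cfg <- simulation_config(seed = 2, n_genes = 2, n_novel_units = 0,
                           as_events_per_type = 0, n_boundary_extensions = 0,
                           depth_mean = 0, frac_multi = 0, genome_length = 1e5)
  gen <- generate_annotation(cfg)
  aln <- simulate_alignments(gen$annotation, gen$truth, cfg)
  expect_equal(nrow(aln), 0L)
})

test_that("planted AS events come with guaranteed junction support", {
  ds <- cached_dataset(101)
  jn <- extract_junctions(ds$alignments)
  tr <- ds$truth$as_events
  for (r in which(tr$type == "ES")) {
    ex <- ds$annotation$exons[ds$annotation$exons$gene_id == tr$gene_id[r], ]
    ex <- ex[order(ex$start), ]
    k <- match(tr$start[r], ex$start)          # the skipped exon
    hit <- jn$donor_end == ex$end[k - 1] & jn$acceptor_start == ex$start[k + 1]
    expect_true(any(hit & jn$n_reads >= 2 & jn$max_overhang_left >= 5 &
                      jn$max_overhang_right >= 5))
  }
})

test_that("planted fold changes reproduce in the count tables", {
  cfg <- simulation_config(seed = 33, count_genes = 2000, de_fraction = 0.1,
                           de_log2fc = 2)
  sim <- simulate_counts(cfg)
  # de_fraction 0 with equal libraries: means agree
  cfg0 <- simulation_config(seed = 33, count_genes = 2000, de_fraction = 0)
  sim0 <- simulate_counts(cfg0)
  expect_equal(mean(sim0$counts_a$count), mean(sim0$counts_b$count),
               tolerance = 0.05)
  # planted log2fc = 2: mean count ratio across up-planted genes near 4
  up <- sim$truth_de$gene_id[sim$truth_de$log2fc > 0]
  x <- sim$counts_a$count[match(up, sim$counts_a$gene_id)]
  y <- sim$counts_b$count[match(up, sim$counts_b$gene_id)]
  expect_gt(mean(x / pmax(y, 1)), 3.5)
  expect_lt(mean(x / pmax(y, 1)), 4.6)
  # library-size scaling affects the second library's rates
  siml <- simulate_counts(simulation_config(seed = 34, count_genes = 3000,
                                            de_fraction = 0),
                          lib_sizes = c(1e6, 2e6))
  expect_gt(sum(siml$counts_b$count) / sum(siml$counts_a$count), 1.8)
})

test_that("small-RNA tags are 18-30 nt with the planted 22 nt mode", {
  ds <- simulate_small_rna(simulation_config(seed = 37), n_tags = 10000)
  lens <- nchar(ds$tags$sequence)
  expect_true(all(lens >= 18 & lens <= 30))
  ld <- length_distribution(ds$tags)
  expect_equal(ld$mode, 22L)
  expect_gt(ld$frac_20_23, 0.84)
  # all-mature mixture with no substitutions matches the db exactly
  pure <- simulate_small_rna(simulation_config(seed = 38),
                             mature_db = simulate_mature_db(5, 39),
                             n_tags = 200, mixture = c(miRNA = 1),
                             mirna_sub_probs = c(1, 0, 0))
  mdb <- chartr("U", "T", toupper(pure$mature_db))
  expect_true(all(pure$tags$sequence %in% mdb))
  # with the default substitution rates every tag is still within 2 subs
  noisy <- simulate_small_rna(simulation_config(seed = 38),
                              mature_db = simulate_mature_db(5, 39),
                              n_tags = 200, mixture = c(miRNA = 1))
  expect_true(all(vapply(noisy$tags$sequence, function(s)
    any(vapply(mdb, function(m) match_oracle_exactish(s, m), logical(1))),
    logical(1))))
})
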