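# Seeded generator for a toy genome with machine-readable planted truth:
# annotated multi-exon genes, intergenic novel transcription, paired-end
# spliced alignments realising all four AS models, boundary read-through,
# Poisson two-library counts with planted fold changes, and 18-30 nt
# small-RNA tags. Reads are emitted directly as alignments (the mapping
# stage is not part of this package's scope), under a Poisson read-start
# model uniform within each expressed feature.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: a 1 Mb
#' single-chromosome genome, 90 bp paired-end reads with a 200 bp insert,
#' 10x expressed depth, 50 intergenic novel units of at least 300 bp, ten
#' planted events of each alternative-splicing type, ten boundary-extended
#' genes (60-500 bp), and a two-library count experiment of 2,000 genes
#' with 10% planted at |log2 fold change| 1.5 around a mean count of 50.
#'
#' @param seed integer RNG seed; every generator stage derives its stream
#'   from it.
#' @param genome_length chromosome length in bp.
#' @param n_genes number of annotated genes.
#' @param n_novel_units number of planted intergenic novel units.
#' @param read_length read length in bp.
#' @param fragment_size paired-end insert size in bp.
#' @param depth_mean expected per-base depth over expressed features.
#' @param as_events_per_type planted events per AS type.
#' @param n_boundary_extensions genes with planted boundary read-through.
#' @param de_fraction proportion of count-experiment genes planted as DE.
#' @param de_log2fc planted |log2 fold change|.
#' @param count_genes genes in the two-library count experiment.
#' @param count_mean baseline Poisson mean count per gene.
#' @param frac_multi fraction of reads re-emitted as multi-mapping decoys.
#' @param chrom chromosome name.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome_length = 1e6, n_genes = 20,
                              n_novel_units = 50, read_length = 90,
                              fragment_size = 200, depth_mean = 10,
                              as_events_per_type = 10,
                              n_boundary_extensions = 10,
                              de_fraction = 0.1, de_log2fc = 1.5,
                              count_genes = 2000, count_mean = 50,
                              frac_multi = 0.02, chrom = "chr1") {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              n_novel_units = as.integer(n_novel_units),
              read_length = as.integer(read_length),
              fragment_size = as.integer(fragment_size),
              depth_mean = depth_mean,
              as_events_per_type = as.integer(as_events_per_type),
              n_boundary_extensions = as.integer(n_boundary_extensions),
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              count_genes = as.integer(count_genes), count_mean = count_mean,
              frac_multi = frac_multi, chrom = chrom)
  with(cfg, {
    stopifnot(genome_length > 0, n_genes >= 0, n_novel_units >= 0,
              read_length > 0, fragment_size >= read_length,
              depth_mean >= 0, as_events_per_type >= 0,
              n_boundary_extensions >= 0, de_fraction >= 0, de_fraction <= 1,
              count_genes >= 0, count_mean >= 0, frac_multi >= 0)
  })
  structure(cfg, class = c("simulation_config", "list"))
}

#' Generate a synthetic annotation with planted truth
#'
#' Genes are non-overlapping multi-exon models separated by well over
#' 400 bp so 200 bp intergenic margins are realisable; planted novel
#' units, AS events and boundary extensions are laid out so they are
#' mutually consistent and each recoverable from the reads that
#' [simulate_alignments()] emits.
#'
#' @param config a [simulation_config()].
#' @return list with elements `annotation` (a [gene_annotation]) and
#'   `truth` (list of class `planted_truth`: `novel_units`, `as_events`,
#'   `extensions`, plus internal layout used by the read simulator).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  ch <- config$chrom
  n_g <- config$n_genes

  # gene structures
  genes <- vector("list", n_g)
  for (i in seq_len(n_g)) {
    n_ex <- sample(2:8, 1)
    ew <- sample(120:300, n_ex, replace = TRUE)
    iw <- if (n_ex > 1) sample(100:400, n_ex - 1, replace = TRUE) else integer(0)
    genes[[i]] <- list(exon_w = ew, intron_w = iw,
                       strand = sample(c("+", "-"), 1),
                       span = sum(ew) + sum(iw))
  }

  # boundary extensions (drawn before layout so space is reserved)
  ext <- data.frame(gene = integer(), which_end = character(),
                    length = integer(), stringsAsFactors = FALSE)
  if (config$n_boundary_extensions > 0) {
    if (config$n_boundary_extensions > n_g)
      stop("n_boundary_extensions exceeds n_genes")
    picked <- sample(n_g, config$n_boundary_extensions)
    for (g in picked) {
      mode <- sample(c("5'", "3'", "both"), 1, prob = c(0.4, 0.4, 0.2))
      ends <- if (mode == "both") c("5'", "3'") else mode
      for (e in ends)
        ext <- rbind(ext, data.frame(gene = g, which_end = e,
                                     length = sample(60:500, 1),
                                     stringsAsFactors = FALSE))
    }
  }
  ext_left <- ext_right <- rep(0L, n_g)   # genomic-side extension lengths
  for (r in seq_len(nrow(ext))) {
    g <- ext$gene[r]
    left <- (ext$which_end[r] == "5'") == (genes[[g]]$strand == "+")
    if (left) ext_left[g] <- ext$length[r] else ext_right[g] <- ext$length[r]
  }

  # novel unit structures (some two-part, linked only by mate pairs)
  n_u <- config$n_novel_units
  units <- vector("list", n_u)
  for (i in seq_len(n_u)) {
    if (stats::runif(1) < 0.3) {
      pw <- sample(250:400, 2, replace = TRUE)
      gap <- sample(120:180, 1)
      units[[i]] <- list(part_w = pw, gap = gap, span = sum(pw) + gap)
    } else {
      units[[i]] <- list(part_w = sample(300:800, 1), gap = integer(0))
      units[[i]]$span <- units[[i]]$part_w
    }
  }

  # sequential layout of shuffled features with clearances
  clear_gene <- 350L; clear_unit <- 250L
  feat <- c(lapply(seq_len(n_g), function(i) list(kind = "gene", idx = i,
              res = clear_gene + ext_left[i] + genes[[i]]$span + ext_right[i] + clear_gene)),
            lapply(seq_len(n_u), function(i) list(kind = "unit", idx = i,
              res = clear_unit + units[[i]]$span + clear_unit)))
  feat <- feat[sample(length(feat))]
  total_res <- sum(vapply(feat, `[[`, numeric(1), "res"))
  leftover <- config$genome_length - total_res
  if (leftover < 0)
    stop("genome_length too small for the requested features; ",
         "increase genome_length (need > ", total_res, " bp)")
  cuts <- sort(sample.int(leftover + 1L, length(feat), replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts))
  pos <- 0L
  gene_rows <- exon_rows <- list()
  unit_rows <- list()
  for (k in seq_along(feat)) {
    pos <- pos + gaps[k]
    f <- feat[[k]]
    if (f$kind == "gene") {
      g <- f$idx
      s <- pos + clear_gene + ext_left[g]
      starts <- s + cumsum(c(0L, head_pairsum(genes[[g]]$exon_w, genes[[g]]$intron_w)))
      ends <- starts + genes[[g]]$exon_w
      gid <- sprintf("gene%04d", g)
      gene_rows[[g]] <- data.frame(gene_id = gid, chrom = ch, start = starts[1],
                                   end = ends[length(ends)],
                                   strand = genes[[g]]$strand,
                                   stringsAsFactors = FALSE)
      exon_rows[[g]] <- data.frame(gene_id = gid, chrom = ch,
                                   start = starts, end = ends,
                                   stringsAsFactors = FALSE)
    } else {
      u <- f$idx
      s <- pos + clear_unit
      if (length(units[[u]]$gap)) {
        p1 <- c(s, s + units[[u]]$part_w[1])
        p2s <- s + units[[u]]$part_w[1] + units[[u]]$gap
        parts <- data.frame(start = c(s, p2s),
                            end = c(p1[2], p2s + units[[u]]$part_w[2]))
      } else {
        parts <- data.frame(start = s, end = s + units[[u]]$part_w)
      }
      unit_rows[[u]] <- data.frame(unit_id = sprintf("NU%03d", u), chrom = ch,
                                   start = min(parts$start), end = max(parts$end),
                                   n_parts = nrow(parts),
                                   part_starts = paste(parts$start, collapse = ","),
                                   part_ends = paste(parts$end, collapse = ","),
                                   stringsAsFactors = FALSE)
    }
    pos <- pos + f$res
  }
  ann <- if (n_g > 0)
    gene_annotation(do.call(rbind, gene_rows), do.call(rbind, exon_rows))
  else gene_annotation(
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character()),
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer()))
  novel_units <- if (n_u > 0) do.call(rbind, unit_rows) else
    data.frame(unit_id = character(), chrom = character(), start = integer(),
               end = integer(), n_parts = integer(), part_starts = character(),
               part_ends = character(), stringsAsFactors = FALSE)

  # AS event assignment: claim free introns per gene
  as_req <- rep(c("ES", "A5SS", "A3SS", "IR"), each = config$as_events_per_type)
  free <- lapply(seq_len(n_g), function(g)
    rep(TRUE, max(0L, length(genes[[g]]$exon_w) - 1L)))
  as_rows <- list()
  for (type in sample(as_req)) {
    placed <- FALSE
    for (g in sample(seq_len(max(n_g, 1L)))) {
      if (n_g == 0) break
      gid <- sprintf("gene%04d", g)
      ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      n_in <- nrow(ex) - 1L
      if (type == "ES") {
        cand <- which(vapply(seq_len(max(0L, n_in - 1L)), function(k)
          free[[g]][k] && free[[g]][k + 1L], logical(1)))
        if (!length(cand)) next
        k <- sample(rep(cand, 2L), 1L)   # rep() guards length-1 sample()
        free[[g]][c(k, k + 1L)] <- FALSE
        as_rows[[length(as_rows) + 1L]] <- data.frame(
          gene_id = gid, type = "ES", chrom = ch,
          start = ex$start[k + 1L], end = ex$end[k + 1L],
          intron = k, stringsAsFactors = FALSE)
      } else {
        cand <- which(free[[g]])
        if (!length(cand)) next
        k <- sample(rep(cand, 2L), 1L)
        free[[g]][k] <- FALSE
        if (type == "IR") {
          as_rows[[length(as_rows) + 1L]] <- data.frame(
            gene_id = gid, type = "IR", chrom = ch,
            start = ex$end[k], end = ex$start[k + 1L],
            intron = k, stringsAsFactors = FALSE)
        } else {
          # varying side in genomic terms: A5SS varies the donor (5' side
          # of the transcribed intron) = genomic left on +, right on -
          strand <- ann$genes$strand[ann$genes$gene_id == gid]
          left_varies <- (type == "A5SS") == (strand == "+")
          delta <- 30L
          if (left_varies) {
            b_ann <- ex$end[k]; b_alt <- b_ann - delta
          } else {
            b_ann <- ex$start[k + 1L]; b_alt <- b_ann + delta
          }
          as_rows[[length(as_rows) + 1L]] <- data.frame(
            gene_id = gid, type = type, chrom = ch,
            start = min(b_ann, b_alt), end = max(b_ann, b_alt),
            intron = k, stringsAsFactors = FALSE)
        }
      }
      placed <- TRUE
      break
    }
    if (!placed && length(as_req))
      stop("could not place all AS events; increase n_genes")
  }
  as_events <- if (length(as_rows)) do.call(rbind, as_rows) else
    data.frame(gene_id = character(), type = character(), chrom = character(),
               start = integer(), end = integer(), intron = integer(),
               stringsAsFactors = FALSE)

  ext$gene_id <- sprintf("gene%04d", ext$gene)
  truth <- structure(list(novel_units = novel_units,
                          as_events = as_events,
                          extensions = ext[, c("gene_id", "which_end", "length")],
                          de_genes = NULL),
                     class = "planted_truth")
  list(annotation = ann, truth = truth)
}

# interleave exon and intron widths into cumulative offsets of exon starts
head_pairsum <- function(exon_w, intron_w) {
  if (!length(intron_w)) return(numeric(0))
  exon_w[-length(exon_w)] + intron_w
}

#' Simulate paired-end spliced alignments realising the planted truth
#'
#' Expressed features receive fragments under a Poisson read-start model
#' (uniform within the feature's transcript); spliced reads across exon
#' junctions arise from the transcript-to-genome mapping. Planted AS
#' events additionally receive constructed junction reads (at least four,
#' with generous overhangs); planted retained introns and boundary
#' extensions receive a deterministic double tiling so every base reaches
#' the TAR depth; two-part novel units receive explicit linking mate
#' pairs. A fraction of reads is re-emitted as multi-mapping decoys
#' (unique = FALSE).
#'
#' @param ann the generated [gene_annotation].
#' @param truth the `planted_truth` from [generate_annotation()].
#' @param config the [simulation_config()].
#' @return An [alignment_blocks] table.
#' @export
simulate_alignments <- function(ann, truth, config) {
  set.seed(config$seed + 1L)
  rl <- config$read_length; fl <- config$fragment_size
  ch <- config$chrom
  out <- list()
  counter <- new.env(parent = emptyenv()); counter$n <- 0L

  next_id <- function() {
    counter$n <- counter$n + 1L
    sprintf("r%07d", counter$n)
  }
  emit <- function(blocks1, blocks2 = NULL, unique = TRUE) {
    id <- next_id()
    b1 <- data.frame(read_id = id, mate = 1L, chrom = ch, strand = ".",
                     start = blocks1$start, end = blocks1$end,
                     block = seq_len(nrow(blocks1)), unique = unique,
                     mismatches = 0L, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <<- b1
    if (!is.null(blocks2)) {
      b2 <- data.frame(read_id = id, mate = 2L, chrom = ch, strand = ".",
                       start = blocks2$start, end = blocks2$end,
                       block = seq_len(nrow(blocks2)), unique = unique,
                       mismatches = 0L, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <<- b2
    }
  }
  # map transcript interval [a, b) onto genomic blocks of `segments`
  tx2blocks <- function(segments, a, b) {
    w <- segments$end - segments$start
    offs <- cumsum(c(0L, w))
    rows <- list()
    for (s in seq_len(nrow(segments))) {
      lo <- max(a, offs[s]); hi <- min(b, offs[s + 1L])
      if (hi > lo)
        rows[[length(rows) + 1L]] <- data.frame(
          start = segments$start[s] + (lo - offs[s]),
          end = segments$start[s] + (hi - offs[s]))
    }
    do.call(rbind, rows)
  }
  merge_contiguous <- function(seg) {
    seg <- seg[order(seg$start), , drop = FALSE]
    keep_s <- seg$start[1]; rows <- list(); cur_e <- seg$end[1]
    for (i in seq_len(nrow(seg))[-1]) {
      if (seg$start[i] <= cur_e) cur_e <- max(cur_e, seg$end[i])
      else { rows[[length(rows) + 1L]] <- c(keep_s, cur_e)
             keep_s <- seg$start[i]; cur_e <- seg$end[i] }
    }
    rows[[length(rows) + 1L]] <- c(keep_s, cur_e)
    m <- do.call(rbind, rows)
    data.frame(start = m[, 1], end = m[, 2])
  }
  sample_feature <- function(segments, depth) {
    segments <- merge_contiguous(segments)
    txlen <- sum(segments$end - segments$start)
    if (txlen >= fl && depth > 0) {
      n <- stats::rpois(1, depth * txlen / (2 * rl))
      if (n > 0) {
        starts <- sample.int(txlen - fl + 1L, n, replace = TRUE) - 1L
        for (s in starts)
          emit(tx2blocks(segments, s, s + rl),
               tx2blocks(segments, s + fl - rl, s + fl))
      }
    } else if (txlen >= rl && depth > 0) {
      n <- stats::rpois(1, depth * txlen / rl)
      if (n > 0) {
        starts <- sample.int(txlen - rl + 1L, n, replace = TRUE) - 1L
        for (s in starts) emit(tx2blocks(segments, s, s + rl))
      }
    }
  }
  tile_cover2 <- function(start, end) {
    if (end - start < rl) { start <- end - rl }
    starts <- unique(c(seq(start, end - rl, by = rl - 10L), end - rl))
    for (rep_i in 1:2) for (s in starts)
      emit(data.frame(start = s, end = s + rl))
  }

  genes <- ann$genes
  ext <- truth$extensions
  ir <- truth$as_events[truth$as_events$type == "IR", , drop = FALSE]

  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    seg <- ex[, c("start", "end")]
    # retained introns join their flanking exons in the expressed form
    for (r in which(ir$gene_id == gid))
      seg <- rbind(seg, data.frame(start = ir$start[r], end = ir$end[r]))
    # boundary read-through extends the expressed form past the annotation
    for (r in which(ext$gene_id == gid)) {
      left <- (ext$which_end[r] == "5'") == (genes$strand[gi] == "+")
      if (left)
        seg <- rbind(seg, data.frame(start = genes$start[gi] - ext$length[r],
                                     end = genes$start[gi]))
      else
        seg <- rbind(seg, data.frame(start = genes$end[gi],
                                     end = genes$end[gi] + ext$length[r]))
    }
    sample_feature(seg, config$depth_mean)
    # deterministic tilings: retained introns (with both flanking exons,
    # so the expressed-flank condition holds even for weakly covered
    # terminal exons) and extensions reach depth 2 throughout
    for (r in which(ir$gene_id == gid)) {
      k_left <- max(which(ex$end <= ir$start[r]))
      k_right <- min(which(ex$start >= ir$end[r]))
      tile_cover2(ex$start[k_left], ex$end[k_right])
    }
    for (r in which(ext$gene_id == gid)) {
      left <- (ext$which_end[r] == "5'") == (genes$strand[gi] == "+")
      if (left) tile_cover2(genes$start[gi] - ext$length[r], genes$start[gi] + 50L)
      else tile_cover2(genes$end[gi] - 50L, genes$end[gi] + ext$length[r])
    }
  }

  # constructed junction reads for planted junction-based events
  jn_reads <- function(donor_end, acceptor_start, mate_anchor) {
    for (r in 1:4) {
      lft <- 45L - 5L * (r - 1L); rgt <- 45L + 5L * (r - 1L)
      b1 <- data.frame(start = c(donor_end - lft, acceptor_start),
                       end = c(donor_end, acceptor_start + rgt))
      b2 <- data.frame(start = mate_anchor, end = mate_anchor + rl)
      emit(b1, b2)
    }
  }
  ev <- truth$as_events
  for (r in seq_len(nrow(ev))) {
    gid <- ev$gene_id[r]
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    k <- ev$intron[r]
    if (ev$type[r] == "ES") {
      # junction from exon k's end to exon k+2's start skips exon k+1
      jn_reads(ex$end[k], ex$start[k + 2L], ex$start[k + 2L])
    } else if (ev$type[r] %in% c("A5SS", "A3SS")) {
      d_ann <- ex$end[k]; a_ann <- ex$start[k + 1L]
      if (ev$end[r] == d_ann) {           # varying boundary on the left
        jn_reads(ev$start[r], a_ann, a_ann)          # alternative junction
      } else {                             # varying boundary on the right
        jn_reads(d_ann, ev$end[r], ev$end[r])        # alternative junction
      }
      jn_reads(d_ann, a_ann, a_ann)                  # annotated junction
    }
  }

  # novel units: per-part coverage plus explicit linking pairs
  nu <- truth$novel_units
  for (r in seq_len(nrow(nu))) {
    ps <- as.integer(strsplit(nu$part_starts[r], ",")[[1]])
    pe <- as.integer(strsplit(nu$part_ends[r], ",")[[1]])
    for (p in seq_along(ps))
      sample_feature(data.frame(start = ps[p], end = pe[p]), config$depth_mean)
    if (length(ps) > 1L) {
      for (p in seq_len(length(ps) - 1L)) for (dup in 1:2)
        emit(data.frame(start = pe[p] - rl, end = pe[p]),
             data.frame(start = ps[p + 1L], end = ps[p + 1L] + rl))
    }
  }

  aln <- do.call(rbind, out)
  if (is.null(aln)) return(alignment_blocks(empty_alignment_df()))
  # multi-mapping decoys: duplicated records flagged non-unique
  if (config$frac_multi > 0 && nrow(aln)) {
    recs <- unique(aln$read_id)
    n_multi <- floor(config$frac_multi * length(recs))
    if (n_multi > 0) {
      pick <- sample(recs, n_multi)
      dup <- aln[aln$read_id %in% pick & aln$mate == 1L, , drop = FALSE]
      dup$read_id <- paste0("m", dup$read_id)
      dup$unique <- FALSE
      aln <- rbind(aln, dup)
    }
  }
  aln$mismatches <- stats::rbinom(nrow(aln), 2L, 0.05)
  alignment_blocks(aln)
}

#' Simulate a two-library gene count experiment with planted fold changes
#'
#' Counts are Poisson with gene-specific rates: baseline `count_mean` for
#' null genes; planted DE genes have the rate in one library (direction
#' random) multiplied by `2^de_log2fc`. Library-size ratios scale the
#' second library's rates.
#'
#' @param config a [simulation_config()].
#' @param gene_ids optional gene universe; default `g0001 ...` of size
#'   `config$count_genes`.
#' @param lib_sizes optional pair of target library totals; only their
#'   ratio matters.
#' @return list with `counts_a`, `counts_b` (data.frames `gene_id`,
#'   `count`) and `truth_de` (data.frame `gene_id`, `log2fc` signed:
#'   positive = up in library A).
#' @export
simulate_counts <- function(config, gene_ids = NULL, lib_sizes = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%04d", seq_len(config$count_genes))
  n <- length(gene_ids)
  lam <- rep(config$count_mean, n)
  rate_a <- lam; rate_b <- lam
  n_de <- round(config$de_fraction * n)
  truth_de <- data.frame(gene_id = character(), log2fc = numeric(),
                         stringsAsFactors = FALSE)
  if (n_de > 0) {
    idx <- sample(n, n_de)
    up <- sample(c(TRUE, FALSE), n_de, replace = TRUE)
    rate_a[idx[up]] <- lam[idx[up]] * 2^config$de_log2fc
    rate_b[idx[!up]] <- lam[idx[!up]] * 2^config$de_log2fc
    truth_de <- data.frame(gene_id = gene_ids[idx],
                           log2fc = ifelse(up, config$de_log2fc,
                                           -config$de_log2fc),
                           stringsAsFactors = FALSE)
  }
  if (!is.null(lib_sizes)) rate_b <- rate_b * lib_sizes[2] / lib_sizes[1]
  list(counts_a = data.frame(gene_id = gene_ids, count = stats::rpois(n, rate_a),
                             stringsAsFactors = FALSE),
       counts_b = data.frame(gene_id = gene_ids, count = stats::rpois(n, rate_b),
                             stringsAsFactors = FALSE),
       truth_de = truth_de)
}

#' Simulate a mature miRNA reference
#'
#' @param n number of mature sequences.
#' @param seed RNG seed.
#' @param len_range mature lengths (default 20-23 nt).
#' @return named character vector (`mir001 ...`).
#' @export
simulate_mature_db <- function(n = 30, seed = 1L, len_range = 20:23) {
  set.seed(seed)
  lens <- sample(len_range, n, replace = TRUE)
  # the most abundant mature miRNA in animal libraries is canonically 22 nt;
  # downstream abundance weights rank the db in order, so pin the first
  if (n >= 1 && 22L %in% len_range) lens[1] <- 22L
  seqs <- vapply(lens, function(L)
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  stats::setNames(seqs, sprintf("mir%03d", seq_len(n)))
}

# read-mass length profile for non-miRNA small-RNA tags: modal 22 nt,
# most mass in 20-23 nt (matches typical animal small-RNA libraries)
SRNA_LEN_PROBS <- local({
  p <- c(0.010, 0.020, 0.100, 0.180, 0.350, 0.160, 0.060, 0.040, 0.030,
         0.020, 0.015, 0.010, 0.005)
  names(p) <- 18:30
  p / sum(p)
})

#' Simulate a clean small-RNA tag table with planted categories
#'
#' Tags are 18-30 nt; a configurable fraction is drawn from the mature
#' reference with 0-2 substitutions; the remainder is drawn as substrings
#' of per-category reference sequences (rRNA-like, tRNA-like, exon,
#' intron, ...) or as unannotated random sequence, with lengths from a
#' 22 nt-modal profile.
#'
#' @param config a [simulation_config()] (supplies the seed).
#' @param mature_db named character vector of mature sequences; default
#'   simulated from the seed.
#' @param n_tags number of tag draws (distinct draws are collapsed).
#' @param mixture named numeric vector of category proportions (must
#'   include `miRNA`; remaining names from the cascade categories or
#'   `unannotated`).
#' @param mirna_sub_probs probabilities of 0, 1 and 2 substitutions on
#'   miRNA-derived tags.
#' @return list with `tags` (data.frame `sequence`, `count`), `truth`
#'   (data.frame `sequence`, `category`), `category_refs` (named list),
#'   `mature_db`.
#' @export
simulate_small_rna <- function(config, mature_db = NULL, n_tags = 5000,
                               mixture = c(miRNA = 0.50, rRNA = 0.10,
                                           tRNA = 0.08, snoRNA = 0.04,
                                           snRNA = 0.03, scRNA = 0.02,
                                           "repeat" = 0.05, exon = 0.08,
                                           intron = 0.05,
                                           unannotated = 0.05),
                               mirna_sub_probs = c(0.6, 0.3, 0.1)) {
  set.seed(config$seed + 3L)
  if (is.null(mature_db)) mature_db <- simulate_mature_db(30, config$seed + 4L)
  if (!length(mature_db)) stop("mature_db is empty")
  mixture <- mixture / sum(mixture)
  # skewed (Zipf-like) mature-miRNA abundance, as in real libraries where
  # a handful of miRNAs dominate the clean reads
  mir_w <- 1 / seq_along(mature_db)
  mir_w <- mir_w / sum(mir_w)
  cats <- setdiff(names(mixture), c("miRNA", "unannotated"))
  rand_seq <- function(L) paste0(sample(c("A", "C", "G", "T"), L,
                                        replace = TRUE), collapse = "")
  category_refs <- stats::setNames(
    lapply(cats, function(cat) vapply(1:5, function(i) rand_seq(400), character(1))),
    cats)
  draw_cat <- sample(names(mixture), n_tags, replace = TRUE, prob = mixture)
  seqs <- character(n_tags); truth_cat <- character(n_tags)
  for (i in seq_len(n_tags)) {
    cat <- draw_cat[i]
    if (cat == "miRNA") {
      m <- mature_db[[sample.int(length(mature_db), 1, prob = mir_w)]]
      m <- chartr("U", "T", toupper(m))
      nmm <- sample(0:2, 1, prob = mirna_sub_probs)
      if (nmm > 0) {
        pos <- sample(nchar(m), nmm)
        for (p in pos) {
          alt <- setdiff(c("A", "C", "G", "T"), substr(m, p, p))
          substr(m, p, p) <- sample(rep(alt, 2L), 1)
        }
      }
      seqs[i] <- m
    } else {
      L <- as.integer(sample(names(SRNA_LEN_PROBS), 1, prob = SRNA_LEN_PROBS))
      if (cat == "unannotated") {
        seqs[i] <- rand_seq(L)
      } else {
        ref <- category_refs[[cat]][sample.int(5, 1)]
        s <- sample.int(nchar(ref) - L + 1L, 1)
        seqs[i] <- substr(ref, s, s + L - 1L)
      }
    }
    truth_cat[i] <- cat
  }
  counts <- 1L + stats::rpois(n_tags, 2)
  agg <- tapply(counts, seqs, sum)
  tags <- data.frame(sequence = names(agg), count = as.integer(agg),
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  truth <- unique(data.frame(sequence = seqs, category = truth_cat,
                             stringsAsFactors = FALSE))
  truth <- truth[!duplicated(truth$sequence), , drop = FALSE]
  rownames(truth) <- NULL
  list(tags = tags, truth = truth, category_refs = category_refs,
       mature_db = mature_db,
       mirna_weights = stats::setNames(mir_w, names(mature_db)))
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Runs every generator stage under one seed; the count experiment is run
#' both over its own gene universe (`count_genes`) and over the annotated
#' genes (for the GWAS-integration demo), and a GWAS hit table is placed
#' so that some planted DE genes fall within the window of each trait's
#' top SNP.
#'
#' @param config a [simulation_config()].
#' @return list: `config`, `annotation`, `truth`, `alignments`, `counts`
#'   (count-universe experiment), `gene_counts` (annotation-universe
#'   experiment), `smallrna`, `gwas` (data.frame `snp_id`, `chrom`, `pos`,
#'   `p_corrected`, `trait`).
#' @export
generate_dataset <- function(config) {
  gen <- generate_annotation(config)
  aln <- simulate_alignments(gen$annotation, gen$truth, config)
  counts <- simulate_counts(config)
  gen$truth$de_genes <- counts$truth_de
  gene_counts <- if (nrow(gen$annotation$genes) > 0)
    simulate_counts(config, gene_ids = gen$annotation$genes$gene_id) else NULL
  srna <- simulate_small_rna(config)
  gwas <- simulate_gwas(gen$annotation, gene_counts, config)
  list(config = config, annotation = gen$annotation, truth = gen$truth,
       alignments = aln, counts = counts, gene_counts = gene_counts,
       smallrna = srna, gwas = gwas)
}

# GWAS hit table: per trait one strong SNP near a planted DE gene plus
# weaker background SNPs
simulate_gwas <- function(ann, gene_counts, config, n_traits = 3) {
  set.seed(config$seed + 5L)
  traits <- c("growth", "fatness", "meat_quality")[seq_len(n_traits)]
  rows <- list()
  de_ids <- if (!is.null(gene_counts) && nrow(gene_counts$truth_de))
    gene_counts$truth_de$gene_id else character(0)
  for (t in seq_along(traits)) {
    if (length(de_ids)) {
      gid <- sample(rep(de_ids, 2L), 1)
      g <- ann$genes[ann$genes$gene_id == gid, ]
      pos <- g$start + sample.int(max(1L, g$end - g$start), 1) - 1L
    } else {
      pos <- sample.int(config$genome_length, 1)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = sprintf("snp_%s_top", traits[t]), chrom = config$chrom,
      pos = pos, p_corrected = 10^-stats::runif(1, 4, 8), trait = traits[t],
      stringsAsFactors = FALSE)
    for (b in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = sprintf("snp_%s_bg%d", traits[t], b), chrom = config$chrom,
        pos = sample.int(config$genome_length, 1),
        p_corrected = stats::runif(1, 0.01, 1), trait = traits[t],
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
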