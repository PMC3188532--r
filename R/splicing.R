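# Splice-junction validation and alternative-splicing classification.
# A junction is the gap between consecutive blocks of a spliced read:
# [donor_end, acceptor_start) in 0-based half-open genomic coordinates
# (donor_end = end of the upstream-in-genome block). Only the four AS
# models A5SS, A3SS, ES and IR are classified.

#' Extract splice junctions from spliced alignments
#'
#' Each block gap of a uniquely mapped read increments its junction's
#' supporting-read count; the junction's overhangs are the maxima over
#' supporting reads of the flanking block lengths.
#'
#' @param aln an [alignment_blocks] table.
#' @param min_intron gaps shorter than this are ignored as putative indels
#'   rather than introns (default 20 bp).
#' @return data.frame with columns `chrom`, `donor_end`, `acceptor_start`,
#'   `n_reads`, `max_overhang_left`, `max_overhang_right`.
#' @export
extract_junctions <- function(aln, min_intron = 20) {
  u <- aln[aln$unique, , drop = FALSE]
  if (nrow(u) < 2L) return(empty_junction_df())
  u <- u[order(u$read_id, u$mate, u$block), , drop = FALSE]
  key <- paste(u$read_id, u$mate)
  i <- which(key[-1] == key[-length(key)])  # consecutive block pairs
  if (!length(i)) return(empty_junction_df())
  gapdf <- data.frame(chrom = u$chrom[i],
                      donor_end = u$end[i],
                      acceptor_start = u$start[i + 1L],
                      left = u$end[i] - u$start[i],
                      right = u$end[i + 1L] - u$start[i + 1L],
                      stringsAsFactors = FALSE)
  gapdf <- gapdf[gapdf$acceptor_start - gapdf$donor_end >= min_intron, , drop = FALSE]
  if (!nrow(gapdf)) return(empty_junction_df())
  k <- paste(gapdf$chrom, gapdf$donor_end, gapdf$acceptor_start, sep = "\r")
  agg <- lapply(split(gapdf, k), function(d) {
    data.frame(chrom = d$chrom[1], donor_end = d$donor_end[1],
               acceptor_start = d$acceptor_start[1], n_reads = nrow(d),
               max_overhang_left = max(d$left), max_overhang_right = max(d$right),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$chrom, res$donor_end, res$acceptor_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_junction_df <- function() {
  data.frame(chrom = character(), donor_end = integer(),
             acceptor_start = integer(), n_reads = integer(),
             max_overhang_left = integer(), max_overhang_right = integer(),
             stringsAsFactors = FALSE)
}

#' Validate splice junctions
#'
#' A junction is kept when supported by at least `min_reads` unambiguously
#' mapped reads and at least `min_overhang` bases are aligned on both sides
#' of the splice.
#'
#' @param junctions data.frame from [extract_junctions()].
#' @param min_reads minimum supporting reads (default 2).
#' @param min_overhang minimum bases on each side (default 5).
#' @return The validated subset, same columns.
#' @export
validate_junctions <- function(junctions, min_reads = 2, min_overhang = 5) {
  keep <- junctions$n_reads >= min_reads &
    junctions$max_overhang_left >= min_overhang &
    junctions$max_overhang_right >= min_overhang
  res <- junctions[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify alternative-splicing events
#'
#' Junctions are assigned to genes by containment of the junction gap in
#' the gene span; junctions outside any gene are returned separately in
#' attribute `"unassigned"`. Per gene:
#' \itemize{
#' \item ES — a validated junction joins two non-adjacent annotated exon
#'   boundaries; one event is emitted per skipped annotated exon.
#' \item A5SS/A3SS — two validated junctions share one boundary and differ
#'   at the other; the varying side is resolved against the gene strand
#'   (donor = 5' side of the transcribed intron).
#' \item IR — an annotated intron every base of which has depth >=
#'   `min_depth`, with both flanking exons expressed (mean depth >=
#'   `min_depth`) and no validated junction whose gap contains the intron.
#' }
#'
#' @param junctions validated junctions from [validate_junctions()].
#' @param ann a [gene_annotation].
#' @param coverage `RleList` from [compute_coverage()] (needed for IR).
#' @param min_depth per-base depth threshold for intron retention
#'   (default 2).
#' @param sample optional sample label attached to every event.
#' @return data.frame with columns `gene_id`, `type` (`A5SS`, `A3SS`, `ES`,
#'   `IR`), `chrom`, `start`, `end` (the defining interval: skipped exon,
#'   retained intron, or the range between the two varying boundaries),
#'   `coordinates` (canonical string key), `evidence`, `sample`.
#' @export
classify_events <- function(junctions, ann, coverage, min_depth = 2,
                            sample = NA_character_) {
  genes <- ann$genes
  events <- list()
  unassigned <- junctions[0, , drop = FALSE]
  if (nrow(junctions)) {
    jgr <- gr0(junctions$chrom, junctions$donor_end, junctions$acceptor_start)
    ggr <- gr0(genes$chrom, genes$start, genes$end)
    hit <- GenomicRanges::findOverlaps(jgr, ggr, type = "within")
    jgene <- rep(NA_integer_, nrow(junctions))
    jgene[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    unassigned <- junctions[is.na(jgene), , drop = FALSE]
  } else {
    jgene <- integer(0)
  }

  for (gi in seq_len(nrow(genes))) {
    gid <- genes$gene_id[gi]
    strand <- genes$strand[gi]
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    jn <- if (nrow(junctions)) junctions[!is.na(jgene) & jgene == gi, , drop = FALSE]
          else junctions
    chrom <- genes$chrom[gi]

    # ES: junction matching boundaries of two non-adjacent exons
    if (nrow(jn) && nrow(ex) >= 3) {
      for (r in seq_len(nrow(jn))) {
        i_d <- match(jn$donor_end[r], ex$end)
        i_a <- match(jn$acceptor_start[r], ex$start)
        if (!is.na(i_d) && !is.na(i_a) && i_a > i_d + 1L) {
          for (sk in (i_d + 1L):(i_a - 1L)) {
            events[[length(events) + 1L]] <- as_event(
              gid, "ES", chrom, ex$start[sk], ex$end[sk],
              sprintf("junction=%d-%d;reads=%d", jn$donor_end[r],
                      jn$acceptor_start[r], jn$n_reads[r]), sample)
          }
        }
      }
    }

    # A5SS / A3SS: pairs sharing one boundary, differing at the other.
    # Pairs whose varying boundaries are both annotated exon boundaries are
    # skipped: two annotated junctions sharing an anchor describe exon
    # skipping (handled above), not an alternative splice site.
    if (nrow(jn) >= 2) {
      for (shared in c("acceptor_start", "donor_end")) {
        varying <- if (shared == "acceptor_start") "donor_end" else "acceptor_start"
        annotated_vals <- if (varying == "donor_end") ex$end else ex$start
        for (grp in split(jn, jn[[shared]])) {
          vals <- sort(unique(grp[[varying]]))
          if (length(vals) < 2) next
          # varying boundary is on the genomic left iff varying == donor_end
          left_varies <- varying == "donor_end"
          type <- if (strand == "-") {
            if (left_varies) "A3SS" else "A5SS"
          } else {
            if (left_varies) "A5SS" else "A3SS"
          }
          for (a in seq_len(length(vals) - 1L)) for (b in (a + 1L):length(vals)) {
            if (all(c(vals[a], vals[b]) %in% annotated_vals)) next
            events[[length(events) + 1L]] <- as_event(
              gid, type, chrom, vals[a], vals[b],
              sprintf("anchor_%s=%d", shared, grp[[shared]][1]), sample)
          }
        }
      }
    }

    # IR: annotated intron fully covered, flanking exons expressed,
    # no validated junction containing it
    if (nrow(ex) >= 2 && chrom %in% names(coverage)) {
      cv <- coverage[[chrom]]
      for (k in seq_len(nrow(ex) - 1L)) {
        i_s <- ex$end[k]; i_e <- ex$start[k + 1L]
        if (i_e <= i_s) next
        if (min_in_window(cv, i_s, i_e) < min_depth) next
        if (mean_in_window(cv, ex$start[k], ex$end[k]) < min_depth) next
        if (mean_in_window(cv, ex$start[k + 1L], ex$end[k + 1L]) < min_depth) next
        spanned <- nrow(jn) > 0 &&
          any(jn$donor_end <= i_s & jn$acceptor_start >= i_e)
        if (!spanned) {
          events[[length(events) + 1L]] <- as_event(
            gid, "IR", chrom, i_s, i_e, sprintf("intron_depth>=%g", min_depth), sample)
        }
      }
    }
  }

  res <- if (length(events)) do.call(rbind, events) else
    as_event(character(0), character(0), character(0), integer(0), integer(0),
             character(0), character(0))
  res <- unique(res)
  res <- res[order(res$gene_id, res$type, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unassigned") <- unassigned
  res
}

as_event <- function(gene_id, type, chrom, start, end, evidence, sample) {
  data.frame(gene_id = gene_id, type = type, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             coordinates = if (length(gene_id))
               sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
             else character(0),
             evidence = evidence, sample = sample, stringsAsFactors = FALSE)
}

min_in_window <- function(cv, start, end) {
  if (end <= start) return(Inf)
  min(S4Vectors::window(cv, start = start + 1L, end = end))
}
mean_in_window <- function(cv, start, end) {
  if (end <= start) return(0)
  mean(S4Vectors::window(cv, start = start + 1L, end = end))
}

#' Pool alternative-splicing events across samples
#'
#' Events are deduplicated on the identity key (gene_id, type,
#' coordinates); the pooled table records in how many and which samples
#' each event was seen, plus per-gene distinct-event counts and the
#' distribution of events-per-gene.
#'
#' @param event_sets list of event data.frames from [classify_events()]
#'   (each carrying its `sample` label).
#' @return list with elements `events` (deduplicated, with `n_samples`,
#'   `samples`), `per_gene` (data.frame `gene_id`, `n_events`), and
#'   `multi_event_distribution` (table of genes by event count).
#' @export
pool_events <- function(event_sets) {
  all <- do.call(rbind, event_sets)
  if (is.null(all) || nrow(all) == 0L) {
    return(list(events = as_event(character(0), character(0), character(0),
                                  integer(0), integer(0), character(0), character(0)),
                per_gene = data.frame(gene_id = character(), n_events = integer(),
                                      stringsAsFactors = FALSE),
                multi_event_distribution = table(integer(0))))
  }
  key <- paste(all$gene_id, all$type, all$coordinates, sep = "\r")
  pooled <- do.call(rbind, lapply(split(all, key), function(d) {
    out <- d[1, c("gene_id", "type", "chrom", "start", "end", "coordinates",
                  "evidence"), drop = FALSE]
    out$n_samples <- length(unique(d$sample))
    out$samples <- paste(sort(unique(d$sample)), collapse = ",")
    out
  }))
  pooled <- pooled[order(pooled$gene_id, pooled$type, pooled$start), , drop = FALSE]
  rownames(pooled) <- NULL
  per_gene <- as.data.frame(table(pooled$gene_id), stringsAsFactors = FALSE)
  names(per_gene) <- c("gene_id", "n_events")
  list(events = pooled, per_gene = per_gene,
       multi_event_distribution = table(per_gene$n_events))
}
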