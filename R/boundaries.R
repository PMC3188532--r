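# Read-supported gene models and 5'/3' boundary extensions relative to the
# annotation. Evidence is coverage continuity and mate-pair links only; no
# TSS/TES modelling.

#' Build read-supported (potential) gene models
#'
#' A TAR is attached to a gene when it overlaps the gene span (coverage
#' contiguity with the gene body is subsumed: TARs are maximal runs, so a
#' depth-contiguous extension is part of the overlapping TAR itself) or when
#' it is linked to an overlapping TAR by a mate pair. A TAR attachable to
#' two genes goes to the gene with the nearer span end; on a tie it is left
#' unassigned and reported in attribute `"unassigned_tars"`.
#'
#' @param tars data.frame from [call_tars()].
#' @param aln an [alignment_blocks] table.
#' @param ann a [gene_annotation].
#' @param coverage `RleList` from [compute_coverage()] (passed through to
#'   the pair-linking step).
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `annotated_start`, `annotated_end`, `extended_start`, `extended_end`,
#'   `supported_by_pairs` (TRUE when a mate-pair link, rather than overlap
#'   alone, contributed to the extension).
#' @export
build_gene_models <- function(tars, aln, ann, coverage) {
  genes <- ann$genes
  res <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand,
                    annotated_start = genes$start, annotated_end = genes$end,
                    extended_start = genes$start, extended_end = genes$end,
                    supported_by_pairs = FALSE, stringsAsFactors = FALSE)
  if (nrow(tars) == 0L) { attr(res, "unassigned_tars") <- tars; return(res) }

  tgr <- gr0(tars$chrom, tars$start, tars$end)
  ggr <- gr0(genes$chrom, genes$start, genes$end)
  ov <- GenomicRanges::findOverlaps(tgr, ggr)
  tar_genes <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))

  # candidate assignments: (tar, gene, via_pair)
  cand <- data.frame(tar = as.integer(rep(names(tar_genes),
                                          lengths(tar_genes))),
                     gene = unlist(tar_genes, use.names = FALSE),
                     via_pair = FALSE)

  # mate-pair links between TARs (same relation as unit linking)
  units <- link_tars(tars, aln, coverage)
  mem <- units$members
  mem$tar <- match(paste(mem$chrom, mem$start, mem$end),
                   paste(tars$chrom, tars$start, tars$end))
  overlapping <- unique(cand$tar)
  for (uid in unique(mem$unit_id[mem$tar %in% overlapping])) {
    tars_in_unit <- mem$tar[mem$unit_id == uid]
    linked_only <- setdiff(tars_in_unit, overlapping)
    if (!length(linked_only)) next
    genes_hit <- unique(cand$gene[cand$tar %in% tars_in_unit])
    for (t in linked_only)
      cand <- rbind(cand, data.frame(tar = t, gene = genes_hit, via_pair = TRUE))
  }

  # resolve multi-gene TARs by distance to the nearer gene-span end
  unassigned <- integer(0)
  for (t in unique(cand$tar)) {
    rows <- cand[cand$tar == t, , drop = FALSE]
    gs <- unique(rows$gene)
    if (length(gs) > 1L) {
      d <- vapply(gs, function(g) {
        if (tars$end[t] <= genes$start[g]) genes$start[g] - tars$end[t]
        else if (tars$start[t] >= genes$end[g]) tars$start[t] - genes$end[g]
        else 0L
      }, numeric(1))
      if (sum(d == min(d)) > 1L) { unassigned <- c(unassigned, t); next }
      gs <- gs[which.min(d)]
    }
    g <- gs[1]
    via <- any(rows$via_pair[rows$gene == g])
    res$extended_start[g] <- min(res$extended_start[g], tars$start[t])
    res$extended_end[g] <- max(res$extended_end[g], tars$end[t])
    if (via) res$supported_by_pairs[g] <- TRUE
  }
  if (length(unassigned))
    message(length(unassigned), " TAR(s) equidistant between two genes left unassigned")
  attr(res, "unassigned_tars") <- tars[unassigned, , drop = FALSE]
  res
}

#' Detect 5'/3' gene-boundary extensions
#'
#' Compares each read-supported gene model with the annotation. On the +
#' strand the 5' extension is `annotated_start - extended_start` and the 3'
#' extension `extended_end - annotated_end`; strand-mirrored on -. Genes
#' extended at both ends emit two records.
#'
#' @param models data.frame from [build_gene_models()].
#' @param min_report minimum extension (bp) to report (default 1).
#' @return data.frame with columns `gene_id`, `which_end` (`"5'"`/`"3'"`),
#'   `extension_bp`, `supported_by_pairs`.
#' @export
detect_extensions <- function(models, min_report = 1) {
  left <- models$annotated_start - models$extended_start
  right <- models$extended_end - models$annotated_end
  minus <- models$strand == "-"
  ext5 <- ifelse(minus, right, left)
  ext3 <- ifelse(minus, left, right)
  rec <- function(which_end, bp) {
    keep <- bp >= min_report
    data.frame(gene_id = models$gene_id[keep],
               which_end = rep(which_end, sum(keep)),
               extension_bp = as.integer(bp[keep]),
               supported_by_pairs = models$supported_by_pairs[keep],
               stringsAsFactors = FALSE)
  }
  res <- rbind(rec("5'", ext5), rec("3'", ext3))
  res <- res[order(res$gene_id, res$which_end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarise boundary extensions
#'
#' @param extensions data.frame from [detect_extensions()].
#' @param min_bp bin threshold for the "at least `min_bp`" tally
#'   (default 50).
#' @return list with counts of genes extended at the 5' end, the 3' end,
#'   both ends (set intersection of the per-end gene sets), and per end the
#'   count with extension >= `min_bp`.
#' @export
summarise_extensions <- function(extensions, min_bp = 50) {
  g5 <- extensions$gene_id[extensions$which_end == "5'"]
  g3 <- extensions$gene_id[extensions$which_end == "3'"]
  list(n_5prime = length(unique(g5)),
       n_3prime = length(unique(g3)),
       n_both = length(intersect(unique(g5), unique(g3))),
       n_5prime_ge_min = length(unique(extensions$gene_id[
         extensions$which_end == "5'" & extensions$extension_bp >= min_bp])),
       n_3prime_ge_min = length(unique(extensions$gene_id[
         extensions$which_end == "3'" & extensions$extension_bp >= min_bp])))
}
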