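# Positional candidate genes: differentially expressed genes within a
# genomic window of each trait's most significant GWAS SNP.

#' Bonferroni correction
#'
#' @param pvalues numeric vector in (0, 1].
#' @param m number of tests (default `length(pvalues)`).
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  stopifnot(all(pvalues > 0), all(pvalues <= 1), m >= 1)
  pmin(1, pvalues * m)
}

#' Join significant DE genes to GWAS hits within a window
#'
#' Per trait only the most significant SNP (minimum corrected P; ties keep
#' all tied SNPs) is used. A gene-SNP pair is emitted when they share a
#' chromosome and the minimum distance from any base of the gene span to
#' the SNP position is at most `window` (inclusive; a SNP inside the span
#' has distance 0).
#'
#' @param de_genes data.frame of significant genes with columns `gene_id`,
#'   `chrom`, `start`, `end` and optionally `direction`; genes without a
#'   position (`NA` chrom) are skipped with a warning.
#' @param gwas_hits data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `p_corrected`, `trait`.
#' @param window distance in bp (default 2.5e6).
#' @return data.frame with columns `gene_id`, `snp_id`, `trait`,
#'   `distance_bp`, `p_corrected`, `de_direction`.
#' @export
proximity_join <- function(de_genes, gwas_hits, window = 2.5e6) {
  if (any(gwas_hits$p_corrected <= 0 | gwas_hits$p_corrected > 1))
    stop("corrected P values must lie in (0, 1]")
  unplaced <- is.na(de_genes$chrom) | is.na(de_genes$start)
  if (any(unplaced)) {
    warning(sum(unplaced), " gene(s) without a genomic position skipped")
    de_genes <- de_genes[!unplaced, , drop = FALSE]
  }
  # per-trait most significant SNP(s)
  top <- do.call(rbind, lapply(split(gwas_hits, gwas_hits$trait), function(d) {
    d[d$p_corrected == min(d$p_corrected), , drop = FALSE]
  }))
  out <- list()
  for (i in seq_len(nrow(top))) {
    same <- de_genes$chrom == top$chrom[i]
    if (!any(same)) next
    g <- de_genes[same, , drop = FALSE]
    dist <- ifelse(top$pos[i] < g$start, g$start - top$pos[i],
                   ifelse(top$pos[i] >= g$end, top$pos[i] - (g$end - 1L), 0L))
    keep <- dist <= window
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g$gene_id[keep], snp_id = top$snp_id[i], trait = top$trait[i],
      distance_bp = as.numeric(dist[keep]), p_corrected = top$p_corrected[i],
      de_direction = if (!is.null(g$direction)) g$direction[keep] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), snp_id = character(),
                      trait = character(), distance_bp = numeric(),
                      p_corrected = numeric(), de_direction = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$trait, res$distance_bp, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate candidate genes with knockout phenotypes
#'
#' Attaches free-text knockout-mouse phenotype annotations where present
#' and flags candidates whose phenotype text mentions the associated trait.
#'
#' @param candidates data.frame from [proximity_join()].
#' @param ko_table data.frame with columns `gene_id`, `phenotype`, or
#'   `NULL`/empty for no annotation.
#' @return `candidates` with added columns `ko_phenotype` and
#'   `trait_match`.
#' @export
annotate_candidates <- function(candidates, ko_table = NULL) {
  res <- candidates
  if (is.null(ko_table) || nrow(ko_table) == 0L) {
    res$ko_phenotype <- rep("", nrow(res))
    res$trait_match <- rep(FALSE, nrow(res))
    return(res)
  }
  res$ko_phenotype <- ko_table$phenotype[match(res$gene_id, ko_table$gene_id)]
  res$ko_phenotype[is.na(res$ko_phenotype)] <- ""
  res$trait_match <- mapply(function(ph, tr) {
    nzchar(ph) && grepl(tr, ph, ignore.case = TRUE)
  }, res$ko_phenotype, res$trait, USE.NAMES = FALSE)
  res
}
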