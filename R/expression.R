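# Gene-level quantification and two-library digital differential
# expression. The DE statistic is the exact conditional test on a count
# pair: given x + y, y ~ Binomial(x + y, n2/(n1+n2)) under the null of
# equal per-read sampling rates, the count-based equivalent of comparing
# two Poisson rates; the two-sided p doubles the smaller tail.

#' Quantify gene expression (counts and RPKM)
#'
#' Uniquely mapped reads are assigned to a gene when their blocks overlap
#' the gene's flattened exons (union over transcripts); a read overlapping
#' exons of two genes goes to the gene with the larger overlap, ties are
#' left unassigned. RPKM = count / (exonic kb x million mapped reads),
#' with the mapped total defaulting to the number of uniquely mapped
#' records in the library.
#'
#' @param aln an [alignment_blocks] table.
#' @param ann a [gene_annotation].
#' @param total_mapped total uniquely mapped reads; default counts the
#'   unique records in `aln`.
#' @return data.frame with columns `gene_id`, `count`, `exon_len_bp`,
#'   `rpkm`; the number of assigned reads in attribute `"n_assigned"`.
#' @export
quantify <- function(aln, ann, total_mapped = NULL) {
  u <- aln[aln$unique, , drop = FALSE]
  recs <- unique(u[, c("read_id", "mate")])
  if (is.null(total_mapped)) total_mapped <- nrow(recs)
  flat <- flatten_exons(ann)
  exon_len <- tapply(GenomicRanges::width(flat), flat$gene_id, sum)
  res <- data.frame(gene_id = ann$genes$gene_id,
                    count = 0L,
                    exon_len_bp = as.integer(exon_len[ann$genes$gene_id]),
                    stringsAsFactors = FALSE)
  n_assigned <- 0L
  if (nrow(u) && length(flat)) {
    gr <- blocks_gr(u, unique_only = FALSE)
    hit <- GenomicRanges::findOverlaps(gr, flat)
    if (length(hit)) {
      ov_w <- GenomicRanges::width(GenomicRanges::pintersect(
        gr[S4Vectors::queryHits(hit)], flat[S4Vectors::subjectHits(hit)]))
      d <- data.frame(rec = paste(gr$read_id[S4Vectors::queryHits(hit)],
                                  gr$mate[S4Vectors::queryHits(hit)], sep = "\r"),
                      gene = flat$gene_id[S4Vectors::subjectHits(hit)],
                      w = ov_w, stringsAsFactors = FALSE)
      agg <- stats::aggregate(w ~ rec + gene, data = d, FUN = sum)
      maxw <- stats::ave(agg$w, agg$rec, FUN = max)
      is_top <- agg$w == maxw
      n_top <- stats::ave(as.numeric(is_top), agg$rec, FUN = sum)
      sel <- is_top & n_top == 1                 # tie -> unassigned
      n_assigned <- sum(sel)
      if (n_assigned < length(unique(agg$rec)))
        message(length(unique(agg$rec)) - n_assigned,
                " read(s) tied between genes left unassigned")
      tab <- table(agg$gene[sel])
      res$count[match(names(tab), res$gene_id)] <- as.integer(tab)
    }
  }
  res$rpkm <- res$count / (res$exon_len_bp / 1000) / (total_mapped / 1e6)
  attr(res, "n_assigned") <- n_assigned
  res
}

#' Audic-Claverie two-library p-value
#'
#' Exact conditional test for a count difference between two libraries:
#' given the pair sum, `y ~ Binomial(x + y, n2/(n1 + n2))` under the null;
#' the two-sided p doubles the smaller of the lower and upper tails at the
#' observed `y`, capped at 1. `x = y = 0` yields p = 1 (no evidence).
#'
#' @param x,y counts in libraries A and B (vectorised).
#' @param n1,n2 library totals (> 0).
#' @return p-values in (0, 1].
#' @export
audic_claverie_p <- function(x, y, n1, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0), all(x >= 0), all(y >= 0))
  n <- x + y
  pr <- n2 / (n1 + n2)
  lo <- stats::pbinom(y, n, pr)
  up <- stats::pbinom(y - 1, n, pr, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lo, up))
  p[n == 0] <- 1
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j>=i) p_(j) m / j`, capped at 1,
#' returned in input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' The log2 ratio is computed on library-size-normalised counts
#' `(x/n1)/(y/n2)`; genes with zero counts in both libraries are excluded
#' before testing, and a half-count continuity floor is applied to the
#' ratio only (the exact test is unaffected) when one library is zero.
#' A gene is significant when `q <= fdr_max` and `|log2_ratio| >=
#' min_abs_log2`.
#'
#' @param table_a,table_b data.frames with columns `gene_id`, `count`,
#'   sharing one gene universe.
#' @param n1,n2 library totals; default to the column sums.
#' @param fdr_max FDR threshold (default 0.001).
#' @param min_abs_log2 minimum |log2 ratio| (default 1).
#' @return data.frame with columns `gene_id`, `x`, `y`, `n1`, `n2`,
#'   `log2_ratio`, `p`, `q`, `significant`, `direction` (`"up"` = higher
#'   in library A).
#' @export
call_de <- function(table_a, table_b, n1 = NULL, n2 = NULL,
                    fdr_max = 0.001, min_abs_log2 = 1) {
  if (!setequal(table_a$gene_id, table_b$gene_id)) {
    diff <- union(setdiff(table_a$gene_id, table_b$gene_id),
                  setdiff(table_b$gene_id, table_a$gene_id))
    stop("count tables disagree on the gene universe: ",
         paste(utils::head(diff, 10), collapse = ", "))
  }
  if (is.null(n1)) n1 <- sum(table_a$count)
  if (is.null(n2)) n2 <- sum(table_b$count)
  x <- table_a$count
  y <- table_b$count[match(table_a$gene_id, table_b$gene_id)]
  keep <- !(x == 0 & y == 0)
  gene_id <- table_a$gene_id[keep]; x <- x[keep]; y <- y[keep]
  xf <- pmax(x, 0.5); yf <- pmax(y, 0.5)      # ratio floor only
  log2_ratio <- log2((xf / n1) / (yf / n2))
  p <- audic_claverie_p(x, y, n1, n2)
  q <- bh_fdr(p)
  res <- data.frame(gene_id = gene_id, x = x, y = y, n1 = n1, n2 = n2,
                    log2_ratio = log2_ratio, p = p, q = q,
                    significant = q <= fdr_max & abs(log2_ratio) >= min_abs_log2,
                    direction = ifelse(log2_ratio >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' GO-term enrichment of differentially expressed genes
#'
#' Upper-tail hypergeometric test of each term's DE-gene count against the
#' background, Bonferroni-corrected over the tested terms (terms with at
#' least one background and one DE gene).
#'
#' @param de_genes character vector of DE gene ids (subset of
#'   `background`).
#' @param gene2go data.frame with columns `gene_id`, `term_id` and
#'   optionally `category`.
#' @param background character vector: the gene universe.
#' @param alpha corrected-p significance threshold (default 0.05).
#' @return data.frame with columns `term_id`, `category`, `k`, `K`, `n`,
#'   `N`, `p_hyper`, `p_bonferroni`, `significant`.
#' @export
go_enrichment <- function(de_genes, gene2go, background, alpha = 0.05) {
  if (!all(de_genes %in% background)) stop("de_genes must be a subset of background")
  de_genes <- unique(de_genes)
  if (!length(de_genes))
    return(data.frame(term_id = character(), category = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p_hyper = numeric(), p_bonferroni = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  g2g <- unique(gene2go[gene2go$gene_id %in% background, , drop = FALSE])
  if (is.null(g2g$category)) g2g$category <- NA_character_
  N <- length(unique(background)); n <- length(de_genes)
  terms <- split(g2g, g2g$term_id)
  rows <- lapply(terms, function(d) {
    K <- length(unique(d$gene_id))
    k <- length(intersect(unique(d$gene_id), de_genes))
    if (K < 1 || k < 1) return(NULL)            # untested term
    data.frame(term_id = d$term_id[1], category = d$category[1],
               k = k, K = K, n = n, N = N,
               p_hyper = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(go_enrichment(character(0), gene2go, background, alpha))
  res <- do.call(rbind, rows)
  m <- nrow(res)
  res$p_bonferroni <- pmin(1, res$p_hyper * m)
  res$significant <- res$p_bonferroni <= alpha
  res <- res[order(res$p_hyper, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Differential expression of miRNAs between two libraries
#'
#' Same exact test as [call_de()], but following the small-RNA rule: the
#' raw p-value is thresholded (no FDR) and both `p < p_max` and
#' `|log2fc| >= min_abs_log2` (on TPM-normalised counts) are required.
#'
#' @param table_a,table_b data.frames with columns `mirna_id`, `count`.
#' @param n1,n2 clean-read totals of the two libraries.
#' @param p_max raw p threshold (default 0.01, strict `<`).
#' @param min_abs_log2 minimum |log2 fold change| (default 1).
#' @return data.frame with columns `mirna_id`, `x`, `y`, `tpm_a`, `tpm_b`,
#'   `log2_ratio`, `p`, `significant`.
#' @export
mirna_de <- function(table_a, table_b, n1, n2, p_max = 0.01, min_abs_log2 = 1) {
  if (!setequal(table_a$mirna_id, table_b$mirna_id))
    stop("miRNA tables disagree on the entity universe")
  x <- table_a$count
  y <- table_b$count[match(table_a$mirna_id, table_b$mirna_id)]
  keep <- !(x == 0 & y == 0)
  id <- table_a$mirna_id[keep]; x <- x[keep]; y <- y[keep]
  xf <- pmax(x, 0.5); yf <- pmax(y, 0.5)
  log2_ratio <- log2((xf / n1) / (yf / n2))
  p <- audic_claverie_p(x, y, n1, n2)
  res <- data.frame(mirna_id = id, x = x, y = y,
                    tpm_a = x * 1e6 / n1, tpm_b = y * 1e6 / n2,
                    log2_ratio = log2_ratio, p = p,
                    significant = p < p_max & abs(log2_ratio) >= min_abs_log2,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
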