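# Novel-transcript-unit discovery: per-base coverage -> TARs (maximal runs
# of depth >= 2) -> mate-pair linking into transcript units -> intergenic
# filtering -> +/-3 kb clustering into transcriptionally active regions.

#' Per-base read coverage from uniquely mapped reads
#'
#' Only uniquely mapped records contribute; multi-position reads are
#' excluded. Spliced reads contribute depth on their blocks only, not on
#' the gaps.
#'
#' @param aln an [alignment_blocks] table.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @return An `RleList` of per-base depths, one `Rle` per chromosome, each
#'   of the chromosome's length (index i holds the depth of 0-based base
#'   i-1).
#' @export
compute_coverage <- function(aln, chrom_sizes) {
  u <- aln[aln$unique, , drop = FALSE]
  bad <- setdiff(unique(u$chrom), names(chrom_sizes))
  if (length(bad)) stop("blocks on unknown chromosome(s): ", paste(bad, collapse = ", "))
  over <- u$end > chrom_sizes[u$chrom]
  if (any(over)) stop("alignment block beyond chromosome end on ",
                      paste(unique(u$chrom[over]), collapse = ", "))
  gr <- blocks_gr(u, unique_only = FALSE, seqlengths = chrom_sizes)
  GenomicRanges::coverage(gr)
}

#' Call transcriptionally active regions (TARs)
#'
#' A TAR is a maximal run of bases each covered by at least `min_depth`
#' uniquely mapped reads.
#'
#' @param coverage an `RleList` from [compute_coverage()].
#' @param min_depth minimum per-base depth (default 2).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `mean_depth`.
#' @export
call_tars <- function(coverage, min_depth = 2) {
  stopifnot(min_depth >= 1)
  out <- lapply(names(coverage), function(chrom) {
    v <- IRanges::slice(coverage[[chrom]], lower = min_depth, rangesOnly = FALSE)
    if (length(v) == 0L) return(NULL)
    data.frame(chrom = chrom,
               start = IRanges::start(v) - 1L,
               end = IRanges::end(v),
               mean_depth = as.numeric(IRanges::viewMeans(v)),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_depth = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Longest run of depth >= lower within [start, end) of one chromosome track.
longest_covered_run <- function(cov_chrom, start, end, lower = 1) {
  seg <- S4Vectors::window(cov_chrom, start = start + 1L, end = end)
  r <- IRanges::slice(seg, lower = lower, rangesOnly = TRUE)
  if (length(r) == 0L) 0L else max(IRanges::width(r))
}

#' Link TARs into transcript units with mate pairs
#'
#' Two TARs are linked when some read pair (both mates uniquely mapped) has
#' mate-1 blocks overlapping one TAR and mate-2 blocks overlapping the
#' other. Transcript units are the connected components of this relation;
#' an unlinked TAR becomes a single-exon unit.
#'
#' @param tars data.frame from [call_tars()].
#' @param aln an [alignment_blocks] table (mate identity required).
#' @param coverage the `RleList` used to call the TARs; supplies the unit's
#'   average coverage over member-TAR bases and its longest contiguous
#'   covered run (depth >= 1).
#' @return list of class `transcript_units` with elements `units`
#'   (data.frame: `unit_id`, `chrom`, `start`, `end`, `n_exons`,
#'   `n_linking_pairs`, `avg_coverage`, `max_run`) and `members`
#'   (data.frame: `unit_id` plus the member TAR rows).
#' @export
link_tars <- function(tars, aln, coverage) {
  n <- nrow(tars)
  empty <- list(units = data.frame(unit_id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   n_exons = integer(), n_linking_pairs = integer(),
                                   avg_coverage = numeric(), max_run = integer(),
                                   stringsAsFactors = FALSE),
                members = data.frame(unit_id = character(), chrom = character(),
                                     start = integer(), end = integer(),
                                     mean_depth = numeric(), stringsAsFactors = FALSE))
  if (n == 0L) return(structure(empty, class = "transcript_units"))
  tar_gr <- gr0(tars$chrom, tars$start, tars$end)

  # TAR hits per (read_id, mate), unique-on-both-mates pairs only
  u <- aln[aln$unique, , drop = FALSE]
  edges <- NULL
  pair_ids <- character(0)
  if (nrow(u)) {
    gr <- blocks_gr(u, unique_only = FALSE)
    hit <- GenomicRanges::findOverlaps(gr, tar_gr)
    if (length(hit)) {
      hdf <- unique(data.frame(read_id = gr$read_id[S4Vectors::queryHits(hit)],
                               mate = gr$mate[S4Vectors::queryHits(hit)],
                               tar = S4Vectors::subjectHits(hit),
                               stringsAsFactors = FALSE))
      m1 <- hdf[hdf$mate == 1L, c("read_id", "tar")]
      m2 <- hdf[hdf$mate == 2L, c("read_id", "tar")]
      pr <- merge(m1, m2, by = "read_id", suffixes = c("_1", "_2"))
      pr <- pr[pr$tar_1 != pr$tar_2, , drop = FALSE]
      if (nrow(pr)) {
        edges <- cbind(pmin(pr$tar_1, pr$tar_2), pmax(pr$tar_1, pr$tar_2))
        pair_ids <- pr$read_id
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  # deterministic unit ids ordered by (chrom, start of first member)
  ord <- order(tars$chrom, tars$start)
  comp_order <- unique(comp[ord])
  unit_of <- match(comp, comp_order)
  uids <- sprintf("TU%05d", seq_along(comp_order))

  units <- do.call(rbind, lapply(seq_along(comp_order), function(k) {
    rows <- which(unit_of == k)
    d <- tars[rows, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    span_s <- min(d$start); span_e <- max(d$end)
    npairs <- if (length(pair_ids))
      length(unique(pair_ids[unit_of[edges[, 1]] == k])) else 0L
    w <- d$end - d$start
    data.frame(unit_id = uids[k], chrom = d$chrom[1],
               start = span_s, end = span_e, n_exons = nrow(d),
               n_linking_pairs = npairs,
               avg_coverage = sum(d$mean_depth * w) / sum(w),
               max_run = longest_covered_run(coverage[[d$chrom[1]]], span_s, span_e),
               stringsAsFactors = FALSE)
  }))
  members <- do.call(rbind, lapply(seq_along(comp_order), function(k) {
    d <- tars[unit_of == k, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cbind(data.frame(unit_id = uids[k], stringsAsFactors = FALSE), d)
  }))
  rownames(units) <- rownames(members) <- NULL
  structure(list(units = units, members = members), class = "transcript_units")
}

#' @export
print.transcript_units <- function(x, ...) {
  cat(sprintf("transcript_units: %d units (%d TARs)\n",
              nrow(x$units), nrow(x$members)))
  invisible(x)
}

#' Intergenic regions of the genome
#'
#' The intergenic space runs from `margin` bp downstream of one gene to
#' `margin` bp upstream of the next: the complement of gene spans padded by
#' `margin` on both sides, clipped to the chromosome.
#'
#' @param ann a [gene_annotation].
#' @param margin padding in bp around each gene span (default 200).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
define_intergenic <- function(ann, margin = 200, chrom_sizes) {
  out <- lapply(names(chrom_sizes), function(chrom) {
    L <- chrom_sizes[[chrom]]
    g <- ann$genes[ann$genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(chrom = chrom, start = 0L, end = L, stringsAsFactors = FALSE))
    pad <- gr0(chrom, pmax(0L, g$start - margin), pmin(L, g$end + margin))
    whole <- gr0(chrom, 0L, L)
    gap <- GenomicRanges::setdiff(whole, GenomicRanges::reduce(pad))
    if (length(gap) == 0L) return(NULL)
    data.frame(chrom = chrom, df0(gap)[, c("start", "end")], stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Filter transcript units to putative novel units
#'
#' A unit is kept when its span lies wholly within intergenic space, its
#' longest contiguous covered run is at least `min_len` bp, and its average
#' coverage is at least `min_avg_cov`.
#'
#' @param units a `transcript_units` object from [link_tars()].
#' @param intergenic data.frame from [define_intergenic()].
#' @param min_len minimum continuous mapping length in bp (default 150).
#' @param min_avg_cov minimum average coverage (default 2).
#' @return A filtered `transcript_units` object.
#' @export
filter_novel_units <- function(units, intergenic, min_len = 150, min_avg_cov = 2) {
  u <- units$units
  keep <- rep(FALSE, nrow(u))
  if (nrow(u) && nrow(intergenic)) {
    ugr <- gr0(u$chrom, u$start, u$end)
    igr <- gr0(intergenic$chrom, intergenic$start, intergenic$end)
    hit <- GenomicRanges::findOverlaps(ugr, igr, type = "within")
    keep[unique(S4Vectors::queryHits(hit))] <- TRUE
  }
  keep <- keep & u$max_run >= min_len & u$avg_coverage >= min_avg_cov
  structure(list(units = u[keep, , drop = FALSE],
                 members = units$members[units$members$unit_id %in% u$unit_id[keep], ,
                                         drop = FALSE]),
            class = "transcript_units")
}

#' Cluster novel units into transcriptionally active regions
#'
#' Single-linkage merge of unit spans whose inter-span gap is at most `gap`
#' bp (inclusive); the +/-3 kb rule of adjacent-fragment clustering.
#'
#' @param units a `transcript_units` object (typically the novel units).
#' @param gap maximum merge gap in bp (default 3000).
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `n_units`; unit membership in attribute `"membership"` (data.frame
#'   `unit_id`, `region_id`).
#' @export
cluster_units <- function(units, gap = 3000) {
  u <- units$units
  if (nrow(u) == 0L) {
    res <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_units = integer(),
                      stringsAsFactors = FALSE)
    attr(res, "membership") <- data.frame(unit_id = character(),
                                          region_id = character(),
                                          stringsAsFactors = FALSE)
    return(res)
  }
  ugr <- gr0(u$chrom, u$start, u$end)
  # reduce() keeps ranges separated by < min.gapwidth together
  red <- GenomicRanges::reduce(ugr, min.gapwidth = gap + 1L)
  hit <- GenomicRanges::findOverlaps(ugr, red)
  reg <- integer(nrow(u))
  reg[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  rd <- df0(red)
  ord <- order(rd$chrom, rd$start)
  rank <- match(seq_along(ord), ord)
  res <- data.frame(region_id = sprintf("TAR_R%05d", rank),
                    chrom = rd$chrom, start = rd$start, end = rd$end,
                    n_units = as.integer(table(factor(reg, levels = seq_len(length(red))))),
                    stringsAsFactors = FALSE)
  res <- res[ord, , drop = FALSE]; rownames(res) <- NULL
  attr(res, "membership") <- data.frame(unit_id = u$unit_id,
                                        region_id = res$region_id[match(reg, ord)],
                                        stringsAsFactors = FALSE)
  res
}
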