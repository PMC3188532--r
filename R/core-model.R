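#' @importFrom GenomicRanges GRanges seqnames start end width coverage reduce
#'   findOverlaps setdiff strand
#' @importFrom IRanges IRanges slice ranges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits runValue runLength Rle mcols
NULL

# Internal coordinates are 0-based half-open everywhere; conversion to the
# 1-based inclusive convention of GRanges/GTF happens only at the boundaries
# below.

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand optional strand vector ("+", "-", ".").
#' @param seqlengths optional named integer vector of chromosome lengths.
#' @return A `GRanges` (1-based internally, as GRanges requires).
#' @keywords internal
gr0 <- function(chrom, start, end, strand = NULL, seqlengths = NULL) {
  if (any(end <= start)) stop("interval with end <= start")
  if (any(start < 0)) stop("negative start coordinate")
  st <- if (is.null(strand)) "*" else ifelse(strand == ".", "*", strand)
  lev <- if (!is.null(seqlengths)) names(seqlengths) else unique(as.character(chrom))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(chrom), levels = lev),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end)),
    strand = st,
    seqlengths = seqlengths
  )
}

# GRanges -> data.frame in 0-based half-open coordinates
df0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Construct a gene annotation object
#'
#' The annotation is the reference against which novelty, splicing and
#' boundary extensions are judged. Coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one row per gene; the span covers all exons).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (non-overlapping within a gene, sorted by start).
#' @param transcripts optional data.frame with columns `gene_id`,
#'   `transcript_id`.
#' @return An object of class `gene_annotation`: a list with elements
#'   `genes`, `exons`, `transcripts`.
#' @export
gene_annotation <- function(genes, exons, transcripts = NULL) {
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("%s lacks columns: %s", what, paste(miss, collapse = ", ")))
  }
  req(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  req(exons, c("gene_id", "chrom", "start", "end"), "exons")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (is.null(transcripts)) {
    transcripts <- data.frame(gene_id = genes$gene_id,
                              transcript_id = if (nrow(genes))
                                paste0(genes$gene_id, ".t1") else character(0),
                              stringsAsFactors = FALSE)
  }
  ann <- structure(list(genes = genes, exons = exons, transcripts = transcripts),
                   class = "gene_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  g <- ann$genes; e <- ann$exons
  if (any(g$end <= g$start)) stop("gene with end <= start")
  if (any(e$end <= e$start)) stop("exon with end <= start")
  sp <- split(seq_len(nrow(e)), e$gene_id)
  gi <- match(names(sp), g$gene_id)
  if (anyNA(gi)) stop("exon with unknown gene_id: ", names(sp)[is.na(gi)][1])
  for (k in seq_along(sp)) {
    rows <- sp[[k]]; gene <- g[gi[k], ]
    ex <- e[rows, , drop = FALSE]
    if (any(ex$chrom != gene$chrom))
      stop("exon on wrong chromosome for gene ", gene$gene_id)
    if (any(ex$start < gene$start) || any(ex$end > gene$end))
      stop("exon outside gene span for gene ", gene$gene_id)
    if (nrow(ex) > 1) {
      o <- order(ex$start)
      if (any(ex$start[o][-1] < ex$end[o][-nrow(ex)]))
        stop("overlapping exons in gene ", gene$gene_id)
    }
  }
  invisible(ann)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

# Per-gene flattened exons (union of all transcripts' exons) as a GRanges,
# with mcol gene_id. Exonic length for RPKM is the width sum of these.
flatten_exons <- function(ann) {
  gr <- gr0(ann$exons$chrom, ann$exons$start, ann$exons$end)
  S4Vectors::mcols(gr)$gene_id <- ann$exons$gene_id
  grl <- GenomicRanges::reduce(GenomicRanges::split(gr, gr$gene_id))
  flat <- unlist(grl, use.names = TRUE)
  S4Vectors::mcols(flat)$gene_id <- names(flat)
  names(flat) <- NULL
  flat
}

#' Read a gene annotation from GTF or BED12
#'
#' GTF coordinates (1-based inclusive) and BED12 block offsets are converted
#' to the internal 0-based half-open convention. GTF parsing goes through
#' \pkg{rtracklayer}; `gene_id`/`transcript_id` attributes are required on
#' exon features. Exons of all transcripts of a gene are kept; overlapping
#' exons within a gene are merged (flattened) so the stored exon set is
#' non-overlapping.
#'
#' @param path file path.
#' @param format `"gtf"` or `"bed12"`; default guesses from the extension.
#' @return A [gene_annotation] object. An empty file yields an empty
#'   annotation with a warning.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed([0-9]*)$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  n_content <- length(grep("^\\s*(#|$)", readLines(path, warn = FALSE), invert = TRUE))
  if (n_content == 0L) {
    warning("empty annotation file: ", path)
    return(gene_annotation(
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(), strand = character()),
      exons = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer()),
      transcripts = data.frame(gene_id = character(), transcript_id = character())
    ))
  }
  if (format == "gtf") read_annotation_gtf(path) else read_annotation_bed12(path)
}

read_annotation_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ",
                                          conditionMessage(e)))
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stop("no exon features in GTF: ", path)
  if (is.null(ex$gene_id) || anyNA(ex$gene_id))
    stop("GTF exon lacking gene_id attribute in ", path)
  exdf <- data.frame(gene_id = as.character(ex$gene_id),
                     chrom = as.character(GenomicRanges::seqnames(ex)),
                     start = GenomicRanges::start(ex) - 1L,
                     end = GenomicRanges::end(ex),
                     strand = as.character(GenomicRanges::strand(ex)),
                     transcript_id = if (!is.null(ex$transcript_id))
                       as.character(ex$transcript_id) else NA_character_,
                     stringsAsFactors = FALSE)
  build_annotation_from_exons(exdf)
}

read_annotation_bed12 <- function(path) {
  bed <- rtracklayer::import(path, format = "bed")
  if (is.null(bed$blocks)) stop("BED input lacks block structure (need BED12): ", path)
  rows <- lapply(seq_along(bed), function(i) {
    bl <- bed$blocks[[i]]
    off <- GenomicRanges::start(bed)[i] - 1L   # 0-based record start
    data.frame(gene_id = bed$name[i],
               chrom = as.character(GenomicRanges::seqnames(bed))[i],
               start = off + GenomicRanges::start(bl) - 1L,
               end = off + GenomicRanges::end(bl),
               strand = as.character(GenomicRanges::strand(bed))[i],
               transcript_id = bed$name[i],
               stringsAsFactors = FALSE)
  })
  build_annotation_from_exons(do.call(rbind, rows))
}

build_annotation_from_exons <- function(exdf) {
  exdf$strand[!exdf$strand %in% c("+", "-")] <- "."
  sp <- split(exdf, exdf$gene_id)
  genes <- do.call(rbind, lapply(sp, function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  exons <- do.call(rbind, lapply(sp, function(d) {
    gr <- GenomicRanges::reduce(gr0(d$chrom, d$start, d$end))
    data.frame(gene_id = d$gene_id[1], df0(gr), stringsAsFactors = FALSE)
  }))
  tx <- unique(exdf[!is.na(exdf$transcript_id), c("gene_id", "transcript_id")])
  rownames(tx) <- NULL
  gene_annotation(genes, exons, tx)
}

#' Write a gene annotation to GTF
#'
#' Emits one `gene` line and per-exon `exon` lines per gene, in deterministic
#' order, converting back to 1-based inclusive GTF coordinates.
#'
#' @param ann a [gene_annotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  g <- ann$genes
  tx <- ann$transcripts
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- tx$transcript_id[match(gid, tx$gene_id)]
    if (is.na(tid)) tid <- paste0(gid, ".t1")
    st <- if (g$strand[i] %in% c("+", "-")) g$strand[i] else "."
    attr_g <- sprintf('gene_id "%s";', gid)
    writeLines(sprintf("%s\ttarscribe\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], st, attr_g), con)
    ex <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      attr_e <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      writeLines(sprintf("%s\ttarscribe\texon\t%d\t%d\t.\t%s\t.\t%s",
                         ex$chrom[j], ex$start[j] + 1L, ex$end[j], st, attr_e), con)
    }
  }
  invisible(path)
}
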