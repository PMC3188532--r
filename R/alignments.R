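# Aligned reads are the sole evidence stream for every discovery stage.
# An alignment set is a "long" data.frame with one row per aligned block:
#   read_id, mate (1/2), chrom, strand, start, end (0-based half-open),
#   block (1..n within the read), unique (logical), mismatches (integer).
# Multi-block records encode spliced reads; the gap between consecutive
# blocks is an implied junction.

#' Construct an alignment block table
#'
#' @param df data.frame with columns `read_id`, `mate`, `chrom`, `start`,
#'   `end`, `block`, `unique`; optional `strand` (default `"."`) and
#'   `mismatches` (default 0).
#' @return data.frame of class `alignment_blocks`, sorted by
#'   (read_id, mate, block).
#' @export
alignment_blocks <- function(df) {
  need <- c("read_id", "mate", "chrom", "start", "end", "block", "unique")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("alignment table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(df$strand)) df$strand <- "."
  if (is.null(df$mismatches)) df$mismatches <- 0L
  df$mate <- as.integer(df$mate)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$block <- as.integer(df$block)
  if (any(!df$mate %in% c(1L, 2L))) stop("mate must be 1 or 2")
  if (any(df$end <= df$start)) stop("alignment block with end <= start")
  df <- df[order(df$read_id, df$mate, df$block),
           c("read_id", "mate", "chrom", "strand", "start", "end",
             "block", "unique", "mismatches")]
  rownames(df) <- NULL
  # per-record invariant: blocks ascending with gap >= 1, one chrom
  key <- paste(df$read_id, df$mate)
  if (nrow(df) > 1) {
    same <- key[-1] == key[-nrow(df)]
    if (any(same & df$start[-1] < df$end[-nrow(df)] + 1L))
      stop("blocks of a read must be ascending with gap >= 1")
    if (any(same & df$chrom[-1] != df$chrom[-nrow(df)]))
      stop("blocks of a read must share one chromosome")
  }
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

#' @export
print.alignment_blocks <- function(x, ...) {
  n_rec <- length(unique(paste(x$read_id, x$mate)))
  cat(sprintf("alignment_blocks: %d records (%d blocks), %.1f%% unique\n",
              n_rec, nrow(x), 100 * mean(x$unique)))
  invisible(x)
}

# GRanges of blocks (optionally unique-only), carrying read_id/mate mcols.
blocks_gr <- function(aln, unique_only = TRUE, seqlengths = NULL) {
  if (unique_only) aln <- aln[aln$unique, , drop = FALSE]
  if (nrow(aln) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = seqlengths)
    S4Vectors::mcols(gr)$read_id <- character(0)
    S4Vectors::mcols(gr)$mate <- integer(0)
    return(gr)
  }
  gr <- gr0(aln$chrom, aln$start, aln$end, seqlengths = seqlengths)
  S4Vectors::mcols(gr)$read_id <- aln$read_id
  S4Vectors::mcols(gr)$mate <- aln$mate
  gr
}

#' Convert a CIGAR string to genomic blocks
#'
#' Walks the CIGAR of a SAM record: `M`, `=`, `X` and `D` consume reference
#' within the current block; `N` closes the block and opens the next one
#' after the skip; `I`, `S`, `H`, `P` consume no reference.
#'
#' @param cigar CIGAR string (e.g. `"40M200N50M"`).
#' @param pos 0-based leftmost reference position of the alignment.
#' @return data.frame with columns `start`, `end` (0-based half-open), one
#'   row per block.
#' @export
cigar_to_blocks <- function(cigar, pos) {
  if (cigar == "*" || !nzchar(cigar)) stop("unmapped or empty CIGAR")
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  starts <- integer(0); ends <- integer(0)
  cur_start <- pos; cur <- pos
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X", "D")) {
      cur <- cur + len
    } else if (op == "N") {
      if (cur > cur_start) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
      cur <- cur + len
      cur_start <- cur
    }
    # I, S, H, P: no reference consumed
  }
  if (cur > cur_start) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
  if (!length(starts)) stop("CIGAR consumes no reference: ", cigar)
  data.frame(start = starts, end = ends)
}

#' Read aligned reads from BED12 or minimal SAM
#'
#' BED12 input is the package's alignment dialect: the standard 12 columns
#' with the read name suffixed `/1` or `/2` for the mate, the score column
#' carrying the mismatch count, and a 13th column holding the per-record
#' unique-mapping flag (0/1). SAM input is the minimal text form (header
#' plus the 11 mandatory columns): secondary (0x100) and supplementary
#' (0x800) records are dropped, and a record counts as uniquely mapped when
#' its MAPQ is at least `min_mapq`.
#'
#' @param path file path.
#' @param format `"bed12"` or `"sam"` (default guesses from extension).
#' @param min_mapq MAPQ threshold for the SAM uniqueness policy (default 20).
#' @param chrom_sizes optional named vector; blocks on chromosomes absent
#'   from it raise an error listing the offenders.
#' @return An [alignment_blocks] table.
#' @export
read_alignments <- function(path, format = c("auto", "bed12", "sam"),
                            min_mapq = 20, chrom_sizes = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed12"
  if (!file.exists(path)) stop("alignment file not found: ", path)
  aln <- if (format == "sam") read_alignments_sam(path, min_mapq)
         else read_alignments_bed12(path)
  if (!is.null(chrom_sizes)) {
    bad <- setdiff(unique(aln$chrom), names(chrom_sizes))
    if (length(bad)) stop("alignments on unknown chromosome(s): ",
                          paste(bad, collapse = ", "))
  }
  aln
}

read_alignments_bed12 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(alignment_blocks(empty_alignment_df()))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop(sprintf("BED12 parse error at line %d of %s: %d fields", i, path, length(f)))
    chrom <- f[1]; cstart <- as.integer(f[2])
    name <- f[4]
    mate <- 1L; read_id <- name
    m <- regmatches(name, regexec("^(.*)/([12])$", name))[[1]]
    if (length(m) == 3) { read_id <- m[2]; mate <- as.integer(m[3]) }
    nblk <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])[seq_len(nblk)]
    offs <- as.integer(strsplit(f[12], ",")[[1]])[seq_len(nblk)]
    uniq <- if (length(f) >= 13) as.integer(f[13]) == 1L else TRUE
    out[[i]] <- data.frame(
      read_id = read_id, mate = mate, chrom = chrom,
      strand = if (f[6] %in% c("+", "-")) f[6] else ".",
      start = cstart + offs, end = cstart + offs + sizes,
      block = seq_len(nblk), unique = uniq,
      mismatches = suppressWarnings(as.integer(f[5])),
      stringsAsFactors = FALSE)
  }
  alignment_blocks(do.call(rbind, out))
}

read_alignments_sam <- function(path, min_mapq) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(alignment_blocks(empty_alignment_df()))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop(sprintf("SAM parse error at line %d of %s: %d fields", i, path, length(f)))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next            # unmapped
    if (bitwAnd(flag, 256L) != 0L) next          # secondary
    if (bitwAnd(flag, 2048L) != 0L) next         # supplementary
    mate <- if (bitwAnd(flag, 128L) != 0L) 2L else 1L
    pos0 <- as.integer(f[4]) - 1L
    bl <- cigar_to_blocks(f[6], pos0)
    nm <- 0L
    if (length(f) > 11) {
      tag <- grep("^NM:i:", f[12:length(f)], value = TRUE)
      if (length(tag)) nm <- as.integer(sub("^NM:i:", "", tag[1]))
    }
    out[[i]] <- data.frame(
      read_id = f[1], mate = mate, chrom = f[3],
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      start = bl$start, end = bl$end, block = seq_len(nrow(bl)),
      unique = as.integer(f[5]) >= min_mapq, mismatches = nm,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(alignment_blocks(empty_alignment_df()))
  alignment_blocks(do.call(rbind, out))
}

empty_alignment_df <- function() {
  data.frame(read_id = character(), mate = integer(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             block = integer(), unique = logical(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Write alignments in the BED12 alignment dialect
#'
#' One BED12 line per record (read/mate); the name is `read_id/mate`, the
#' score column carries the mismatch count and column 13 the unique flag.
#'
#' @param aln an [alignment_blocks] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed12 <- function(aln, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(aln)) {
    key <- paste(aln$read_id, aln$mate, sep = "\r")
    for (rows in split(seq_len(nrow(aln)), factor(key, levels = unique(key)))) {
      d <- aln[rows, , drop = FALSE]
      d <- d[order(d$block), , drop = FALSE]
      cstart <- d$start[1]; cend <- d$end[nrow(d)]
      writeLines(sprintf("%s\t%d\t%d\t%s/%d\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s\t%d",
                         d$chrom[1], cstart, cend, d$read_id[1], d$mate[1],
                         d$mismatches[1],
                         if (d$strand[1] %in% c("+", "-")) d$strand[1] else ".",
                         cstart, cend, nrow(d),
                         paste0(d$end - d$start, collapse = ","),
                         paste0(d$start - cstart, collapse = ","),
                         as.integer(d$unique[1])), con)
    }
  }
  invisible(path)
}
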