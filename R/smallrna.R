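# Small-RNA tag processing: adapter trimming and length filtering, the
# annotation filter cascade, known-miRNA matching with mismatch tolerance,
# and TPM summaries. Tags are processed as a collapsed table
# (sequence, count); per-read qualities are upstream of this package.

SRNA_MIN_LEN <- 18L
SRNA_MAX_LEN <- 30L

# Categories removed before miRNA analysis (structural RNA, repeats and
# exonic signal are excluded; intronic/intergenic tags stay in play).
SRNA_EXCLUDED <- c("rRNA", "tRNA", "scRNA", "snRNA", "snoRNA", "repeat", "exon")

#' Clean raw small-RNA tags
#'
#' Locates the leftmost exact occurrence of a 3' adapter prefix (at least
#' `min_adapter` matching bases, or the full remaining suffix) and trims
#' it; tags whose trimmed length falls outside 18-30 nt are dropped;
#' identical sequences are collapsed with summed counts.
#'
#' @param raw data.frame with columns `sequence`, `count`.
#' @param adapter 3' adapter sequence; `NULL` skips trimming.
#' @param min_adapter minimum adapter prefix length to trim on (default 5).
#' @return data.frame with columns `sequence`, `count`, sorted by
#'   decreasing count then sequence.
#' @export
clean_tags <- function(raw, adapter = NULL, min_adapter = 5) {
  seqs <- toupper(raw$sequence)
  if (!is.null(adapter) && nzchar(adapter)) {
    adapter <- toupper(adapter)
    # leftmost suffix that is an exact prefix of the adapter (and at least
    # min_adapter long, to avoid chance matches) marks the insert end
    seqs <- vapply(seqs, function(s) {
      n <- nchar(s)
      if (n < min_adapter) return(s)
      for (pos in seq_len(n - min_adapter + 1L)) {
        suff_len <- n - pos + 1L
        if (suff_len > nchar(adapter)) next
        if (substr(s, pos, n) == substr(adapter, 1, suff_len))
          return(substr(s, 1, pos - 1L))
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  len <- nchar(seqs)
  keep <- len >= SRNA_MIN_LEN & len <= SRNA_MAX_LEN
  seqs <- seqs[keep]; cnt <- raw$count[keep]
  if (!length(seqs))
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  agg <- tapply(cnt, seqs, sum)
  res <- data.frame(sequence = names(agg), count = as.integer(agg),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$count, res$sequence), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Length distribution of clean tags
#'
#' @param tags data.frame with columns `sequence`, `count`.
#' @return list with `histogram` (data.frame `length`, `count` over 18-30),
#'   `mode` (modal length, read-weighted) and `frac_20_23` (read mass in
#'   20-23 nt).
#' @export
length_distribution <- function(tags) {
  lens <- nchar(tags$sequence)
  h <- vapply(SRNA_MIN_LEN:SRNA_MAX_LEN,
              function(L) sum(tags$count[lens == L]), numeric(1))
  hist <- data.frame(length = SRNA_MIN_LEN:SRNA_MAX_LEN, count = h)
  total <- sum(h)
  list(histogram = hist,
       mode = if (total > 0) hist$length[which.max(hist$count)] else NA_integer_,
       frac_20_23 = if (total > 0) sum(h[hist$length %in% 20:23]) / total else NA_real_)
}

#' Categorise tags by the annotation filter cascade
#'
#' Each tag is assigned exactly one category: the first category in the
#' priority order whose reference set contains the tag (a tag matches a
#' category when its sequence is an exact substring of one of the
#' category's reference sequences); unmatched tags are `unannotated`.
#'
#' @param tags data.frame with columns `sequence`, `count`.
#' @param category_refs named list of character vectors: reference
#'   sequences per category (names from the priority order).
#' @param priority category precedence (default rRNA > tRNA > scRNA >
#'   snRNA > snoRNA > repeat > exon > intron).
#' @return `tags` with added `category` column; attribute `"retained"`
#'   holds the subset passed on to miRNA analysis (categories outside the
#'   excluded set).
#' @export
annotate_cascade <- function(tags, category_refs,
                             priority = c("rRNA", "tRNA", "scRNA", "snRNA",
                                          "snoRNA", "repeat", "exon", "intron")) {
  unknown <- setdiff(names(category_refs), priority)
  if (length(unknown)) stop("categories not in priority order: ",
                            paste(unknown, collapse = ", "))
  cat_out <- rep("unannotated", nrow(tags))
  undecided <- rep(TRUE, nrow(tags))
  for (cat in priority) {
    refs <- category_refs[[cat]]
    if (is.null(refs) || !length(refs)) next
    idx <- which(undecided)
    if (!length(idx)) break
    hit <- vapply(tags$sequence[idx], function(s)
      any(grepl(s, refs, fixed = TRUE)), logical(1), USE.NAMES = FALSE)
    cat_out[idx[hit]] <- cat
    undecided[idx[hit]] <- FALSE
  }
  res <- tags
  res$category <- cat_out
  attr(res, "retained") <- res[!res$category %in% SRNA_EXCLUDED, , drop = FALSE]
  res
}

# Minimum substitution distance between tag and mature sequence allowing a
# terminal offset of up to max_shift nt (isomiR tolerance): the shorter
# sequence is slid along the longer with at most max_shift unaligned bases
# at either end, and Hamming distance is taken over the aligned part.
shift_hamming <- function(tag, mature, max_shift = 2L) {
  a <- if (nchar(tag) <= nchar(mature)) tag else mature
  b <- if (nchar(tag) <= nchar(mature)) mature else tag
  la <- nchar(a); lb <- nchar(b)
  if (lb - la > 2L * max_shift) return(Inf)
  best <- Inf
  for (off in 0:(lb - la)) {
    if (off > max_shift || (lb - la - off) > max_shift) next
    sub <- substr(b, off + 1L, off + la)
    d <- sum(strsplit(a, "")[[1]] != strsplit(sub, "")[[1]])
    best <- min(best, d)
  }
  best
}

#' Match retained tags to known mature miRNAs
#'
#' A tag is assigned to the mature miRNA with the fewest substitutions up
#' to `max_mismatch`, allowing up to 2 nt of terminal offset between tag
#' and mature sequence. A tie between mature miRNAs splits the tag's count
#' equally and flags the quantification.
#'
#' @param tags retained tags (data.frame `sequence`, `count`).
#' @param mature_db named character vector of mature sequences (RNA or DNA
#'   alphabet; U is treated as T).
#' @param max_mismatch maximum substitutions (default 2).
#' @param clean_total total clean reads, for TPM (default: sum of tag
#'   counts).
#' @return data.frame with columns `mirna_id`, `count`, `tpm`, `tied`;
#'   unassigned tags in attribute `"unassigned"`.
#' @export
match_known <- function(tags, mature_db, max_mismatch = 2,
                        clean_total = sum(tags$count)) {
  if (!length(mature_db)) stop("mature_db is empty")
  if (is.null(names(mature_db)) || any(!nzchar(names(mature_db))))
    stop("mature_db must be a named vector")
  db <- toupper(chartr("U", "T", mature_db))
  counts <- stats::setNames(numeric(length(db)), names(db))
  tied <- stats::setNames(rep(FALSE, length(db)), names(db))
  unassigned <- integer(0)
  for (i in seq_len(nrow(tags))) {
    s <- toupper(chartr("U", "T", tags$sequence[i]))
    d <- vapply(db, shift_hamming, numeric(1), tag = s)
    dmin <- min(d)
    if (dmin > max_mismatch) { unassigned <- c(unassigned, i); next }
    best <- which(d == dmin)
    if (length(best) > 1L) tied[best] <- TRUE
    counts[best] <- counts[best] + tags$count[i] / length(best)
  }
  res <- data.frame(mirna_id = names(db), count = as.numeric(counts),
                    tpm = as.numeric(counts) * 1e6 / clean_total,
                    tied = as.logical(tied), stringsAsFactors = FALSE)
  res <- res[order(-res$count, res$mirna_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unassigned") <- tags[unassigned, , drop = FALSE]
  res
}

#' Top expressed miRNAs and their cumulative clean-read fraction
#'
#' @param quants data.frame from [match_known()].
#' @param k number of top entities (default 20).
#' @param clean_total total clean reads the fractions refer to.
#' @return list with `top` (the first `k` rows by TPM, with
#'   `cum_fraction`) and `top_k_fraction` (clean-read fraction of the top
#'   `k`).
#' @export
top_expressed <- function(quants, k = 20, clean_total) {
  if (!nrow(quants)) stop("empty quantification table")
  q <- quants[order(-quants$tpm, quants$mirna_id), , drop = FALSE]
  top <- utils::head(q, k)
  top$cum_fraction <- cumsum(top$count) / clean_total
  rownames(top) <- NULL
  list(top = top, top_k_fraction = sum(top$count) / clean_total)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste0(lines[seq(starts[i], ends[i])], collapse = ""), character(1))
  stats::setNames(gsub("\\s", "", seqs), ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}
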