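# Independent reference implementations used as oracles. These are kept
# deliberately naive (term-by-term enumeration, per-base scans) and never
# share code with the package.

# brute-force per-base TAR scan over an explicit depth vector
tar_oracle <- function(depth, min_depth = 2) {
  on <- depth >= min_depth
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             mean_depth = vapply(which(keep), function(i)
               mean(depth[(starts[i] + 1):ends[i]]), numeric(1)))
}

# doubled smaller tail of the conditional binomial, summed term by term
ac_oracle <- function(x, y, n1, n2) {
  n <- x + y
  if (n == 0) return(1)
  pr <- n2 / (n1 + n2)
  terms <- vapply(0:n, function(k) choose(n, k) * pr^k * (1 - pr)^(n - k),
                  numeric(1))
  lower <- sum(terms[seq_len(y + 1)])
  upper <- sum(terms[seq(y + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# vectorised enumeration over every split of a fixed pair sum
ac_oracle_all_splits <- function(n, n1, n2) {
  if (n == 0) return(1)
  pr <- n2 / (n1 + n2)
  terms <- choose(n, 0:n) * pr^(0:n) * (1 - pr)^(n:0)
  lower <- cumsum(terms)
  upper <- rev(cumsum(rev(terms)))
  pmin(1, 2 * pmin(lower, upper))
}

# hand step-up FDR: sort, take running minima of p_(j) m / j from the top
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# upper-tail hypergeometric by direct combinatorial summation
hyper_oracle <- function(k, K, n, N) {
  sum(vapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
}

# brute-force shifted Hamming scan, written from the definition
match_oracle <- function(tag, db, max_mm = 2, max_shift = 2) {
  best <- Inf
  for (m in db) {
    short <- if (nchar(tag) <= nchar(m)) tag else m
    long <- if (nchar(tag) <= nchar(m)) m else tag
    for (off in 0:(nchar(long) - nchar(short))) {
      if (off > max_shift) next
      if (nchar(long) - nchar(short) - off > max_shift) next
      d <- sum(strsplit(short, "")[[1]] !=
                 strsplit(substr(long, off + 1, off + nchar(short)), "")[[1]])
      best <- min(best, d)
    }
  }
  best <= max_mm
}


# at most 2 substitutions away from some mature sequence, same length window
match_oracle_exactish <- function(tag, mature) {
  if (abs(nchar(tag) - nchar(mature)) > 4) return(FALSE)
  short <- if (nchar(tag) <= nchar(mature)) tag else mature
  long <- if (nchar(tag) <= nchar(mature)) mature else tag
  for (off in 0:(nchar(long) - nchar(short))) {
    d <- sum(strsplit(short, "")[[1]] !=
               strsplit(substr(long, off + 1, off + nchar(short)), "")[[1]])
    if (d <= 2) return(TRUE)
  }
  FALSE
}
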