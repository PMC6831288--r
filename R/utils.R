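# Internal helpers shared across modules.

# reverse complement of a DNA character string (ACGTN)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all start positions (1-based) of fixed pattern in subject string
find_fixed <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) integer(0) else as.integer(m)
}

# overlapping occurrences of a fixed pattern (gregexpr skips overlaps)
find_fixed_overlapping <- function(subject, pattern) {
  n <- nchar(subject)
  k <- nchar(pattern)
  if (n < k) return(integer(0))
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(pattern, substr(subject, from, n), fixed = TRUE)
    if (p == -1L) break
    hits <- c(hits, from + as.integer(p) - 1L)
    from <- from + as.integer(p)   # advance one base: report overlaps
    if (from > n - k + 1L) break
  }
  hits
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# map a 1-based position in the sense-strand (transcription-order) UTR
# sequence to its 1-based genomic coordinate, given the UTR's genomic
# intervals (matrix with columns start, end; genomically ascending).
utr_rel_to_genomic <- function(intervals, strand, rel) {
  widths <- intervals[, 2] - intervals[, 1] + 1L
  if (strand == "-") {
    # transcription runs from the last interval backwards
    ord <- rev(seq_len(nrow(intervals)))
  } else {
    ord <- seq_len(nrow(intervals))
  }
  offs <- c(0L, cumsum(widths[ord]))
  out <- integer(length(rel))
  for (i in seq_along(rel)) {
    r <- rel[i]
    j <- max(which(offs[-length(offs)] < r))
    within <- r - offs[j]
    iv <- ord[j]
    out[i] <- if (strand == "-") intervals[iv, 2] - within + 1L
              else intervals[iv, 1] + within - 1L
  }
  out
}
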