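# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's scanning code paths.

# naive O(n*m) scan: every window-satisfying PAS occurrence in a sequence
oracle_pas_scan <- function(seq, motifs, wmin, wmax) {
  L <- nchar(seq)
  out <- NULL
  for (motif in motifs) {
    k <- nchar(motif)
    for (p in seq_len(max(L - k + 1L, 0L))) {
      if (substr(seq, p, p + k - 1L) != motif) next
      d <- L - (p + k - 1L)
      if (d >= wmin && d <= wmax)
        out <- rbind(out, data.frame(motif = motif, pos = p, distance = d,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    data.frame(motif = character(0), pos = integer(0), distance = integer(0))
  else out[order(out$pos, out$motif), , drop = FALSE]
}

# naive UGUA offsets within a radius of a PAS start position
oracle_ugua_offsets <- function(seq, pas_start, radius) {
  offs <- integer(0)
  for (p in seq_len(max(nchar(seq) - 3L, 0L))) {
    if (substr(seq, p, p + 3L) == "TGTA" && abs(p - pas_start) <= radius)
      offs <- c(offs, p - pas_start)
  }
  sort(offs)
}

# exhaustive two-sided Mann-Whitney p: enumerate every assignment of the
# combined values to group A, U statistic distance from its null mean
oracle_mw_exact_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mu <- n1 * n2 / 2
  idx <- utils::combn(length(vals), n1)
  us <- apply(idx, 2, function(i) u_of(vals[i], vals[-i]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# build a UTRIsoformGroup directly (bypassing GTF parsing) from explicit
# sense-strand isoform sequences; genomic coordinates laid out on a
# plus-strand gene starting at `offset`
make_group <- function(gene_id, seqs, offset = 1000L) {
  lens <- nchar(seqs)
  stopifnot(all(diff(lens) > 0))
  structure(list(
    gene_id = gene_id, chrom = "chrF", strand = "+",
    utr_start = offset,
    ends = offset + lens - 1L,
    utr_intervals = lapply(lens, function(l)
      cbind(start = offset, end = offset + l - 1L)),
    seqs = seqs,
    transcript_ids = paste0(gene_id, ".T", seq_along(seqs))
  ), class = "UTRIsoformGroup")
}

# random DNA free of the given motifs (rejection sampling)
random_clean_dna <- function(n, motifs = c("AATAAA", "ATTAAA", "TGTA")) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    if (!any(vapply(motifs, function(m) grepl(m, s, fixed = TRUE), TRUE)))
      return(s)
  }
}

# write GTF lines for a minimal hand-built fixture
write_gtf_fixture <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, feature, start, end, strand, gene, tx = NULL) {
  attrs <- if (is.null(tx)) sprintf('gene_id "%s";', gene)
           else sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, feature, start, end, strand, attrs)
}
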