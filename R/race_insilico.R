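# In-silico 3'RACE: predict amplicon sizes for proximal vs distal poly(A)
# site usage, mirroring the anchored oligo-dT validation assay.

# adapter + oligo-dT reverse-transcription primer and its nested universal
# reverse primer, as used in the wet-lab protocol
DEFAULT_RT_PRIMER <- "CCAGTGAGCAGAGTGACGAGGACTCGAGCTCAAGCTTTTTTTTTTTTTTTTT"
DEFAULT_UNIVERSAL_REVERSE <- "CCAGTGAGCAGAGTGACG"

#' Define a 3'RACE primer set
#'
#' The RT primer is an anchored oligo-dT: a 5' adapter followed by a run of
#' T. First-strand cDNA therefore carries the reverse-complemented adapter
#' after the poly(A) tail, and PCR with a gene-specific forward primer plus
#' the universal reverse primer (a prefix of the adapter) yields one band
#' per poly(A) site used.
#'
#' @param gene_forward data.frame with columns `gene_id`, `primer_id`,
#'   `sequence` (sense-strand, exact-match).
#' @param rt_primer the adapter + oligo-dT reverse-transcription primer.
#' @param universal_reverse the nested universal reverse primer; must be a
#'   prefix of the RT primer's adapter portion.
#' @return a `PrimerSet` list with `gene_forward`, `rt_primer`,
#'   `universal_reverse`, `adapter` (the RT primer minus its 3' T-run) and
#'   `polya_len` (length of that T-run).
#' @export
primer_set <- function(gene_forward,
                       rt_primer = DEFAULT_RT_PRIMER,
                       universal_reverse = DEFAULT_UNIVERSAL_REVERSE) {
  rt_primer <- toupper(rt_primer)
  universal_reverse <- toupper(universal_reverse)
  t_run <- regmatches(rt_primer, regexpr("T+$", rt_primer))
  if (length(t_run) == 0)
    stopf("rt_primer must end in an oligo-dT run")
  adapter <- substr(rt_primer, 1, nchar(rt_primer) - nchar(t_run))
  if (!startsWith(adapter, universal_reverse))
    stopf("universal_reverse must be a prefix of the RT primer's adapter")
  need <- c("gene_id", "primer_id", "sequence")
  if (!all(need %in% names(gene_forward)))
    stopf("gene_forward must have columns: %s", paste(need, collapse = ", "))
  gene_forward$sequence <- toupper(gene_forward$sequence)
  lens <- nchar(c(rt_primer, universal_reverse, gene_forward$sequence))
  if (any(lens < 15 | lens > 60))
    stopf("primers must be 15-60 nt")
  structure(list(gene_forward = gene_forward, rt_primer = rt_primer,
                 universal_reverse = universal_reverse, adapter = adapter,
                 polya_len = nchar(t_run)),
            class = "PrimerSet")
}

#' Predict 3'RACE amplicons for a gene's isoform group
#'
#' Models the cDNA of each isoform as its sense sequence plus a poly(A)
#' tail plus the reverse-complemented RT adapter, then predicts one PCR
#' product per (forward primer, cleavage end) with the primer site 5' of
#' that end. Amplicon length = (distance from the forward primer's 5' base
#' to the cleavage end, inclusive) + polyA tail + adapter. Forward primers
#' must match the long isoform exactly once.
#'
#' @param group a `UTRIsoformGroup` from [group_utr_isoforms()]. Primer
#'   sites are searched on the long-isoform 3'UTR sequence.
#' @param primers a [primer_set()] object.
#' @param polya_len poly(A) tail length appended to the template; defaults
#'   to the RT primer's oligo-dT run length.
#' @return a data.frame: `gene_id`, `primer_id`, `end_rank`,
#'   `cleavage_end`, `length`, `sequence`.
#' @export
predict_amplicons <- function(group, primers, polya_len = NULL) {
  stopifnot(inherits(group, "UTRIsoformGroup"), inherits(primers, "PrimerSet"))
  if (is.null(polya_len)) polya_len <- primers$polya_len
  fw <- primers$gene_forward[primers$gene_forward$gene_id == group$gene_id, ,
                             drop = FALSE]
  if (nrow(fw) == 0)
    stopf("no forward primers supplied for gene %s", group$gene_id)
  long_seq <- group$seqs[length(group$ends)]
  tail_seq <- paste0(strrep("A", polya_len), revcomp(primers$adapter))
  rows <- list()
  for (i in seq_len(nrow(fw))) {
    p <- fw$sequence[i]
    pos <- find_fixed_overlapping(long_seq, p)
    if (length(pos) != 1)
      stopf("forward primer %s matches gene %s %d times (positions: %s); need exactly 1",
            fw$primer_id[i], group$gene_id, length(pos),
            if (length(pos)) paste(pos, collapse = ", ") else "none")
    for (k in seq_along(group$ends)) {
      iso_len <- nchar(group$seqs[k])
      if (pos + nchar(p) - 1L > iso_len) next   # site not 5' of this end
      template <- substr(long_seq, pos, iso_len)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = group$gene_id, primer_id = fw$primer_id[i],
        end_rank = k, cleavage_end = group$ends[k],
        length = nchar(template) + polya_len + nchar(primers$adapter),
        sequence = paste0(template, tail_seq),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), primer_id = character(0),
                      end_rank = integer(0), cleavage_end = integer(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Can a gel resolve the predicted bands?
#'
#' @param predictions output of [predict_amplicons()] (possibly several
#'   genes).
#' @param min_gap minimal resolvable length difference in nt (default 50,
#'   a conservative figure for a 1% agarose gel).
#' @return a named logical vector per gene: `TRUE` iff all pairwise
#'   amplicon length gaps are at least `min_gap` (vacuously true for a
#'   single band).
#' @export
band_distinguishability <- function(predictions, min_gap = 50) {
  vapply(split(predictions$length, predictions$gene_id), function(lens) {
    if (length(lens) < 2) return(TRUE)
    all(abs(diff(sort(lens))) >= min_gap)
  }, TRUE)
}
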