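# Format I/O and strand-aware 3'UTR transcript models.
#
# Coordinates are 1-based inclusive throughout (GTF / Biostrings / GRanges
# convention); BED output converts to 0-based half-open at the boundary.

#' Read a FASTA file into a named sequence set
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet], uppercase, names truncated at the
#'   first whitespace.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stopf("no sequences in %s", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stopf("duplicate sequence names in %s: %s", path,
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0))
    stopf("empty sequence record(s) in %s: %s", path,
          paste(nm[Biostrings::width(seqs) == 0], collapse = ", "))
  names(seqs) <- nm
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Read a GTF annotation into transcript models
#'
#' Parses GTF2.2 (via [rtracklayer::import()]) and derives one model per
#' transcript. The 3'UTR is taken from explicit `three_prime_utr` features
#' when present; otherwise it is derived strand-aware as the part of the
#' exons downstream of the CDS end. Transcripts with neither CDS nor
#' explicit 3'UTR get an empty `utr3` with a warning.
#'
#' @param path GTF file path, or a feature data.frame with columns
#'   `seqname`, `feature`, `start`, `end`, `strand`, `gene_id`,
#'   `transcript_id`.
#' @return a data.frame of class `apa_transcripts`, one row per transcript:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`,
#'   `cleavage_end` (genomic coordinate of the transcript 3' terminus) and
#'   list-columns `exons`, `cds`, `utr3` (two-column start/end matrices in
#'   genomic order).
#' @export
read_gtf <- function(path) {
  if (is.data.frame(path)) return(features_to_transcripts(path))
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    feature = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = if ("transcript_id" %in% names(S4Vectors::mcols(gr)))
      gr$transcript_id else NA_character_,
    stringsAsFactors = FALSE)
  features_to_transcripts(df)
}

# feature table -> transcript models; shared by read_gtf and the generator
features_to_transcripts <- function(df) {
  need <- c("seqname", "feature", "start", "end", "strand",
            "gene_id", "transcript_id")
  if (!all(need %in% names(df)))
    stopf("feature table must have columns: %s", paste(need, collapse = ", "))
  df$line <- seq_len(nrow(df))
  fx <- df[df$feature %in% c("transcript", "exon", "CDS", "three_prime_utr") &
             !is.na(df$transcript_id), , drop = FALSE]
  if (nrow(fx) == 0) return(empty_transcripts())
  bad_strand <- !fx$strand %in% c("+", "-")
  if (any(bad_strand))
    stopf("unknown strand '%s' for feature at line %d",
          fx$strand[bad_strand][1], fx$line[bad_strand][1])
  models <- lapply(split(fx, fx$transcript_id), transcript_from_features)
  out <- data.frame(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    gene_id = vapply(models, `[[`, "", "gene_id"),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    tx_start = vapply(models, function(m) as.integer(m$tx_start), 1L),
    tx_end = vapply(models, function(m) as.integer(m$tx_end), 1L),
    cleavage_end = vapply(models, function(m) as.integer(m$cleavage_end), 1L),
    stringsAsFactors = FALSE)
  out$exons <- I(lapply(models, `[[`, "exons"))
  out$cds <- I(lapply(models, `[[`, "cds"))
  out$utr3 <- I(lapply(models, `[[`, "utr3"))
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("apa_transcripts", "data.frame")
  out
}

empty_transcripts <- function() {
  out <- data.frame(transcript_id = character(0), gene_id = character(0),
                    chrom = character(0), strand = character(0),
                    tx_start = integer(0), tx_end = integer(0),
                    cleavage_end = integer(0), stringsAsFactors = FALSE)
  out$exons <- I(list()); out$cds <- I(list()); out$utr3 <- I(list())
  class(out) <- c("apa_transcripts", "data.frame")
  out
}

interval_matrix <- function(sub) {
  if (nrow(sub) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  m <- cbind(start = as.integer(sub$start), end = as.integer(sub$end))
  m[order(m[, 1]), , drop = FALSE]
}

transcript_from_features <- function(sub) {
  tid <- sub$transcript_id[1]
  if (length(unique(sub$seqname)) > 1 || length(unique(sub$strand)) > 1)
    stopf("transcript %s spans multiple chromosomes or strands", tid)
  strand <- sub$strand[1]
  exons <- interval_matrix(sub[sub$feature == "exon", ])
  if (nrow(exons) == 0)   # fall back to the transcript row
    exons <- interval_matrix(sub[sub$feature == "transcript", ])
  if (nrow(exons) == 0)
    stopf("transcript %s has no exon or transcript feature", tid)
  tx_start <- min(exons[, 1]); tx_end <- max(exons[, 2])
  txrow <- sub[sub$feature == "transcript", , drop = FALSE]
  if (nrow(txrow) > 0 && (min(exons[, 1]) < min(txrow$start) ||
                          max(exons[, 2]) > max(txrow$end)))
    stopf("exon outside transcript bounds for %s (line %d)", tid, txrow$line[1])
  cds <- interval_matrix(sub[sub$feature == "CDS", ])
  utr3 <- interval_matrix(sub[sub$feature == "three_prime_utr", ])
  if (nrow(utr3) == 0) {
    if (nrow(cds) > 0) {
      utr3 <- derive_utr3(exons, cds, strand)
    } else {
      warnf("transcript %s has neither CDS nor three_prime_utr; 3'UTR empty", tid)
    }
  }
  list(transcript_id = tid, gene_id = sub$gene_id[1],
       chrom = sub$seqname[1], strand = strand,
       tx_start = tx_start, tx_end = tx_end,
       cleavage_end = if (strand == "+") tx_end else tx_start,
       exons = exons, cds = cds, utr3 = utr3)
}

# exon regions strictly downstream (transcription order) of the CDS
derive_utr3 <- function(exons, cds, strand) {
  if (strand == "+") {
    lo <- max(cds[, 2]) + 1L
    keep <- exons[, 2] >= lo
    m <- exons[keep, , drop = FALSE]
    if (nrow(m) > 0) m[1, 1] <- max(m[1, 1], lo)
  } else {
    hi <- min(cds[, 1]) - 1L
    keep <- exons[, 1] <= hi
    m <- exons[keep, , drop = FALSE]
    if (nrow(m) > 0) m[nrow(m), 2] <- min(m[nrow(m), 2], hi)
  }
  m
}

#' Group a gene's 3'UTR isoforms by shared 5' start
#'
#' Transcripts of one gene whose 3'UTRs begin at the same genomic 5'
#' boundary (in transcription order) form one group; distinct cleavage ends
#' within a group are ordered proximal to distal. Isoforms with identical
#' (start, end) collapse. Sequences are extracted sense-strand
#' (reverse-complemented for minus-strand genes).
#'
#' @param models an `apa_transcripts` data.frame from [read_gtf()].
#' @param genome a [Biostrings::DNAStringSet] (or path to FASTA) containing
#'   every chromosome referenced.
#' @return a list of `UTRIsoformGroup` objects, each a list with `gene_id`,
#'   `chrom`, `strand`, `utr_start` (genomic coordinate of the shared 5'
#'   UTR base), `ends` (cleavage-end coordinates, proximal first),
#'   `utr_intervals` (per-isoform interval matrices), `seqs` (per-isoform
#'   sense-strand 3'UTR sequences) and `transcript_ids`.
#' @export
group_utr_isoforms <- function(models, genome) {
  if (is.character(genome)) genome <- read_fasta(genome)
  groups <- list()
  for (gid in unique(models$gene_id)) {
    sub <- models[models$gene_id == gid, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1 || length(unique(sub$strand)) > 1)
      stopf("gene %s has transcripts on multiple chromosomes or strands", gid)
    chrom <- sub$chrom[1]; strand <- sub$strand[1]
    if (!chrom %in% names(genome))
      stopf("chromosome %s (gene %s) missing from the genome", chrom, gid)
    has_utr <- vapply(sub$utr3, nrow, 1L) > 0
    sub <- sub[has_utr, , drop = FALSE]
    if (nrow(sub) == 0) next
    # 5' start and cleavage end of each UTR in transcription order
    starts <- vapply(seq_len(nrow(sub)), function(i) {
      iv <- sub$utr3[[i]]
      if (strand == "+") min(iv[, 1]) else max(iv[, 2])
    }, 1L)
    ends <- vapply(seq_len(nrow(sub)), function(i) {
      iv <- sub$utr3[[i]]
      if (strand == "+") max(iv[, 2]) else min(iv[, 1])
    }, 1L)
    for (s in sort(unique(starts))) {
      sel <- which(starts == s)
      sel <- sel[!duplicated(ends[sel])]                 # collapse identical UTRs
      ord <- if (strand == "+") order(ends[sel]) else order(-ends[sel])
      sel <- sel[ord]                                    # proximal -> distal
      seqs <- vapply(sel, function(i)
        utr_sense_sequence(sub$utr3[[i]], strand, chrom, genome), "")
      groups[[length(groups) + 1L]] <- structure(list(
        gene_id = gid, chrom = chrom, strand = strand, utr_start = s,
        ends = ends[sel],
        utr_intervals = sub$utr3[sel],
        seqs = seqs,
        transcript_ids = sub$transcript_id[sel]
      ), class = "UTRIsoformGroup")
    }
  }
  groups
}

# sense-strand (transcription-order) sequence of a set of UTR intervals
utr_sense_sequence <- function(intervals, strand, chrom, genome) {
  pieces <- vapply(seq_len(nrow(intervals)), function(i)
    as.character(Biostrings::subseq(genome[[chrom]],
                                    intervals[i, 1], intervals[i, 2])), "")
  s <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' @export
print.UTRIsoformGroup <- function(x, ...) {
  cat(sprintf("UTRIsoformGroup %s (%s%s): UTR start %d, %d end(s): %s\n",
              x$gene_id, x$chrom, x$strand, x$utr_start, length(x$ends),
              paste(x$ends, collapse = ", ")))
  invisible(x)
}

#' Write motif hits as BED6
#'
#' @param hits a data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive genomic coordinates), `gene_id`, `motif`, `strand` — e.g. the
#'   `pas_hits` component of [run_screen()].
#' @param path output path; BED is written 0-based half-open, name column
#'   `gene_id:motif`, score 0.
#' @return invisibly, `path`.
#' @export
write_bed <- function(hits, path) {
  if (nrow(hits) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = hits$strand,
    name = paste0(hits$gene_id, ":", hits$motif),
    score = 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# write a feature table as GTF2.2 text (deterministic byte layout)
write_gtf_features <- function(features, path, header = NULL) {
  attrs <- ifelse(is.na(features$transcript_id),
                  sprintf('gene_id "%s";', features$gene_id),
                  sprintf('gene_id "%s"; transcript_id "%s";',
                          features$gene_id, features$transcript_id))
  frame <- ifelse(features$feature == "CDS", "0", ".")
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   features$seqname, features$source, features$feature,
                   features$start, features$end, features$strand, frame, attrs)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write transcript models back to GTF
#'
#' Emits transcript, exon, CDS and three_prime_utr rows for each model, so
#' that reading the file with [read_gtf()] reproduces the models exactly.
#'
#' @param models an `apa_transcripts` data.frame.
#' @param path output GTF path.
#' @return invisibly, `path`.
#' @export
write_gtf <- function(models, path) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    add <- function(feature, m) {
      if (nrow(m) == 0) return(NULL)
      data.frame(seqname = models$chrom[i], source = "apascreen",
                 feature = feature, start = m[, 1], end = m[, 2],
                 strand = models$strand[i], gene_id = models$gene_id[i],
                 transcript_id = models$transcript_id[i],
                 stringsAsFactors = FALSE)
    }
    tx <- matrix(c(models$tx_start[i], models$tx_end[i]), ncol = 2)
    rows[[length(rows) + 1L]] <- do.call(rbind, Filter(Negate(is.null), list(
      add("transcript", tx), add("exon", models$exons[[i]]),
      add("CDS", models$cds[[i]]), add("three_prime_utr", models$utr3[[i]]))))
  }
  write_gtf_features(do.call(rbind, rows), path)
}
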