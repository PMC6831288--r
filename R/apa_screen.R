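# The candidate screen: three gene-inclusion criteria for CFIm/NUDT21-
# responsive APA targets.
#
#   c1  >= 2 3'UTR isoforms sharing their 5' start with distinct ends
#   c2  a poly(A)-signal hexamer 10-60 nt upstream of each cleavage end
#   c3  the proximal PAS flanked by UGUA elements within 200 nt
#
# Motifs are stated in RNA (AAUAAA, UGUA) but matched on the sense-strand
# DNA sequence as AATAAA / TGTA.

PAS_CANONICAL <- c("AATAAA", "ATTAAA")
PAS_EXTENDED_EXTRA <- c("TATAAA", "AGTAAA", "AAGAAA", "AATATA", "AATACA",
                        "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")

#' Screening parameters
#'
#' @param pas_motifs poly(A)-signal hexamers, sense-strand DNA. Default is
#'   the canonical AAUAAA plus its strongest variant AUUAAA.
#' @param extended_pas if `TRUE`, add ten further common hexamer variants
#'   (the "similar sequences" of the weaker PAS classes).
#' @param pas_window inclusive `[min, max]` distance (nt) allowed between a
#'   hexamer's 3'-most base and the cleavage end; default 10-60.
#' @param ugua_radius maximal |offset| (nt) between a UGUA start and the
#'   proximal PAS start; default 200.
#' @param ugua_rule `"flanking_both_sides"` (default; at least one UGUA on
#'   each side of the proximal PAS) or `"any_two"` (any two within radius).
#' @param criteria_mode `"all"` (default; candidate iff c1 & c2 & c3) or
#'   `"any"`.
#' @param c2_rule `"all_ends"` (default; every cleavage end needs an
#'   in-window PAS) or `"any_end"`.
#' @return a `screen_params` list.
#' @export
screen_params <- function(pas_motifs = PAS_CANONICAL,
                          extended_pas = FALSE,
                          pas_window = c(10, 60),
                          ugua_radius = 200,
                          ugua_rule = c("flanking_both_sides", "any_two"),
                          criteria_mode = c("all", "any"),
                          c2_rule = c("all_ends", "any_end")) {
  ugua_rule <- match.arg(ugua_rule)
  criteria_mode <- match.arg(criteria_mode)
  c2_rule <- match.arg(c2_rule)
  if (extended_pas) pas_motifs <- unique(c(pas_motifs, PAS_EXTENDED_EXTRA))
  if (any(nchar(pas_motifs) != 6)) stopf("PAS motifs must be hexamers")
  if (length(pas_window) != 2 || pas_window[1] <= 0 ||
      pas_window[1] > pas_window[2])
    stopf("pas_window must be [min, max] with 0 < min <= max")
  if (ugua_radius <= 0) stopf("ugua_radius must be > 0")
  structure(list(pas_motifs = toupper(pas_motifs),
                 pas_window = as.integer(pas_window),
                 ugua_radius = as.integer(ugua_radius),
                 ugua_rule = ugua_rule, criteria_mode = criteria_mode,
                 c2_rule = c2_rule),
            class = "screen_params")
}

empty_pas_hits <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             strand = character(0), motif = character(0),
             start = integer(0), end = integer(0), rel_start = integer(0),
             distance = integer(0), cleavage_end = integer(0),
             end_rank = integer(0), is_proximal = logical(0),
             stringsAsFactors = FALSE)
}

#' Scan a 3'UTR isoform group for poly(A)-signal hexamers
#'
#' For each cleavage end of the group, every motif occurrence whose 3'-most
#' base lies between `pas_window[1]` and `pas_window[2]` nt (inclusive)
#' upstream of that end is reported. Overlapping occurrences are counted
#' separately. Hits supporting a non-distal end carry `is_proximal = TRUE`.
#'
#' @param group a `UTRIsoformGroup` from [group_utr_isoforms()].
#' @param params a [screen_params()] object.
#' @return a data.frame of PAS hits: `gene_id`, `chrom`, `strand`, `motif`,
#'   genomic `start`/`end` of the hexamer, `rel_start` (1-based position in
#'   the sense-strand UTR sequence), `distance` (nt from the motif's
#'   3'-most base to the cleavage end), `cleavage_end`, `end_rank`
#'   (1 = proximal) and `is_proximal`.
#' @export
scan_pas <- function(group, params = screen_params()) {
  stopifnot(inherits(group, "UTRIsoformGroup"))
  K <- length(group$ends)
  wmin <- params$pas_window[1]; wmax <- params$pas_window[2]
  rows <- list()
  for (k in seq_len(K)) {
    s <- group$seqs[k]
    L <- nchar(s)
    if (L < wmin + 6L) {
      warnf("gene %s: 3'UTR isoform %d (%d nt) shorter than the scan window",
            group$gene_id, k, L)
      next
    }
    for (m in params$pas_motifs) {
      for (p in find_fixed_overlapping(s, m)) {
        d <- L - (p + 5L)
        if (d < wmin || d > wmax) next
        g <- utr_rel_to_genomic(group$utr_intervals[[k]], group$strand,
                                c(p, p + 5L))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = group$gene_id, chrom = group$chrom,
          strand = group$strand, motif = m,
          start = min(g), end = max(g), rel_start = p,
          distance = d, cleavage_end = group$ends[k],
          end_rank = k, is_proximal = K >= 2 && k < K,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_pas_hits())
  out <- do.call(rbind, rows)
  out[order(out$end_rank, out$rel_start, out$motif), , drop = FALSE]
}

#' Scan for UGUA elements around the proximal poly(A) signal
#'
#' Reports every UGUA (TGTA in DNA) on the long (distal) isoform sequence
#' whose start lies within `ugua_radius` nt of the proximal PAS start
#' (signed offset = UGUA start - PAS start; the search window shrinks at
#' UTR boundaries rather than erroring). Criterion 3 is satisfied under
#' `"flanking_both_sides"` when at least one UGUA lies on each side of the
#' PAS, or under `"any_two"` when at least two lie within the radius.
#'
#' @param group a `UTRIsoformGroup`.
#' @param proximal_pas a single row of [scan_pas()] output with
#'   `is_proximal = TRUE`.
#' @param params a [screen_params()] object.
#' @return a list with `c3` (logical) and `offsets` (sorted signed nt).
#' @export
scan_ugua <- function(group, proximal_pas, params = screen_params()) {
  stopifnot(inherits(group, "UTRIsoformGroup"))
  if (nrow(proximal_pas) != 1 || !proximal_pas$is_proximal)
    stopf("proximal_pas must be a single PAS hit with is_proximal = TRUE")
  long_seq <- group$seqs[length(group$ends)]
  # isoforms share their 5' prefix, so the proximal-isoform position is
  # also the position on the long isoform
  pas_start <- proximal_pas$rel_start
  tg <- find_fixed_overlapping(long_seq, "TGTA")
  offsets <- sort(tg - pas_start)
  offsets <- offsets[abs(offsets) <= params$ugua_radius]
  c3 <- if (params$ugua_rule == "flanking_both_sides")
    any(offsets < 0) && any(offsets > 0)
  else length(offsets) >= 2
  list(c3 = c3, offsets = offsets)
}

#' Evaluate the three screening criteria for one isoform group
#'
#' Criterion 1 requires at least two distinct cleavage ends sharing a 5'
#' UTR start; criterion 2 requires an in-window PAS at every retained end
#' (or any end, per `c2_rule`); criterion 3 applies [scan_ugua()] to the
#' proximal PAS — the hit supporting the 5'-most non-distal end, ties
#' broken by smallest distance-to-end. A group with a single end has no
#' proximal PAS, so c3 is vacuously false.
#'
#' @param group a `UTRIsoformGroup`.
#' @param params a [screen_params()] object.
#' @return a `CandidateVerdict` list: `gene_id`, `c1`, `c2`, `c3`,
#'   `candidate`, `n_ends`, `pas_hits`, `ugua_offsets`.
#' @export
evaluate_gene <- function(group, params = screen_params()) {
  stopifnot(inherits(group, "UTRIsoformGroup"))
  K <- length(group$ends)
  c1 <- K >= 2
  hits <- suppressWarnings(scan_pas(group, params))
  ends_hit <- unique(hits$end_rank)
  c2 <- if (params$c2_rule == "all_ends") length(ends_hit) == K
        else length(ends_hit) >= 1
  prox <- hits[hits$is_proximal, , drop = FALSE]
  ugua_offsets <- integer(0)
  c3 <- FALSE
  if (nrow(prox) > 0) {
    prox <- prox[order(prox$end_rank, prox$distance), , drop = FALSE]
    res <- scan_ugua(group, prox[1, , drop = FALSE], params)
    c3 <- res$c3
    ugua_offsets <- res$offsets
  }
  flags <- c(c1 = c1, c2 = c2, c3 = c3)
  candidate <- if (params$criteria_mode == "all") all(flags) else any(flags)
  structure(list(gene_id = group$gene_id, c1 = c1, c2 = c2, c3 = c3,
                 candidate = candidate, n_ends = K, pas_hits = hits,
                 ugua_offsets = ugua_offsets),
            class = "CandidateVerdict")
}

#' @export
print.CandidateVerdict <- function(x, ...) {
  cat(sprintf("%s: c1=%s c2=%s c3=%s -> %s (%d end(s), %d PAS hit(s), %d UGUA)\n",
              x$gene_id, x$c1, x$c2, x$c3,
              if (x$candidate) "candidate" else "not a candidate",
              x$n_ends, nrow(x$pas_hits), length(x$ugua_offsets)))
  invisible(x)
}

#' Run the candidate screen over a genome and annotation
#'
#' Groups each gene's 3'UTR isoforms, evaluates the three criteria on the
#' gene's most isoform-rich group (ties broken by 5'-most UTR start) and
#' tabulates one verdict per gene. Genes without any 3'UTR fail all
#' criteria.
#'
#' @param annotation GTF path, feature data.frame or `apa_transcripts`.
#' @param genome FASTA path or [Biostrings::DNAStringSet].
#' @param params a [screen_params()] object.
#' @param expressed_gene_list optional character vector of gene ids (e.g.
#'   genes highly expressed in the tissue of interest); adds an `expressed`
#'   column and a filtered sub-table of expressed candidates.
#' @return an `apa_screen_result` list: `candidates` (one row per gene,
#'   gene_id-sorted: criteria flags, candidacy, evidence counts),
#'   `pas_hits` (all PAS hits, BED-ready via [write_bed()]), and
#'   `expressed_candidates` when a list was supplied.
#' @export
run_screen <- function(annotation, genome, params = screen_params(),
                       expressed_gene_list = NULL) {
  models <- if (inherits(annotation, "apa_transcripts")) annotation
            else read_gtf(annotation)
  if (is.character(genome)) genome <- read_fasta(genome)
  gene_ids <- sort(unique(models$gene_id))
  groups <- group_utr_isoforms(models, genome)
  by_gene <- split(groups, vapply(groups, `[[`, "", "gene_id"))
  rows <- vector("list", length(gene_ids))
  hit_tabs <- list()
  for (i in seq_along(gene_ids)) {
    gid <- gene_ids[i]
    gg <- by_gene[[gid]]
    if (is.null(gg)) {
      rows[[i]] <- data.frame(gene_id = gid, n_utr_isoforms = 0L,
                              c1 = FALSE, c2 = FALSE, c3 = FALSE,
                              candidate = FALSE,
                              n_pas_hits = 0L, n_ugua = 0L,
                              stringsAsFactors = FALSE)
      next
    }
    n_ends <- vapply(gg, function(g) length(g$ends), 1L)
    starts <- vapply(gg, `[[`, 1L, "utr_start")
    best <- gg[[order(-n_ends, starts)[1]]]
    v <- evaluate_gene(best, params)
    rows[[i]] <- data.frame(gene_id = gid, n_utr_isoforms = v$n_ends,
                            c1 = v$c1, c2 = v$c2, c3 = v$c3,
                            candidate = v$candidate,
                            n_pas_hits = nrow(v$pas_hits),
                            n_ugua = length(v$ugua_offsets),
                            stringsAsFactors = FALSE)
    if (nrow(v$pas_hits) > 0) hit_tabs[[length(hit_tabs) + 1L]] <- v$pas_hits
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_utr_isoforms = integer(0),
               c1 = logical(0), c2 = logical(0), c3 = logical(0),
               candidate = logical(0), n_pas_hits = integer(0),
               n_ugua = integer(0), stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  pas_hits <- if (length(hit_tabs)) do.call(rbind, hit_tabs) else empty_pas_hits()
  rownames(pas_hits) <- NULL
  out <- list(candidates = candidates, pas_hits = pas_hits, params = params)
  if (!is.null(expressed_gene_list)) {
    out$candidates$expressed <- out$candidates$gene_id %in% expressed_gene_list
    out$expressed_candidates <-
      out$candidates[out$candidates$candidate & out$candidates$expressed, ,
                     drop = FALSE]
  }
  structure(out, class = "apa_screen_result")
}

#' @export
print.apa_screen_result <- function(x, ...) {
  cat(sprintf("apa_screen_result: %d genes, %d candidate(s) (criteria_mode=%s)\n",
              nrow(x$candidates), sum(x$candidates$candidate),
              x$params$criteria_mode))
  if (!is.null(x$expressed_candidates))
    cat(sprintf("  expressed candidates: %d\n", nrow(x$expressed_candidates)))
  invisible(x)
}

#' Write the candidate table as TSV
#' @param result an `apa_screen_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_screen_table <- function(result, path) {
  write.table(result$candidates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
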