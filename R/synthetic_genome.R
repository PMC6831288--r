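# Synthetic genome / annotation / expression generator.
#
# Builds seeded toy genomes in which every gene either realizes or violates
# one of the three APA screening criteria, so downstream truth labels are
# exact rather than probabilistic: background sequence is uniform i.i.d.
# ACGT, and any accidental poly(A)-signal hexamer (AATAAA/ATTAAA in DNA) or
# UGUA (TGTA in DNA) inside a 3'UTR is rewritten before motifs are planted.

SCRUB_MOTIFS <- c("AATAAA", "ATTAAA", "TGTA")
SIM_CLASSES <- c("positive", "decoy_c1", "decoy_c2", "decoy_c3", "negative")

#' Simulation configuration
#'
#' Parameters for [generate_genome()] and [generate_expression()]. Defaults
#' describe the study conditions used throughout the package's tests: 200
#' genes of which 20% are screen-positive, one decoy class per screening
#' criterion, a 300 vs 600 nt short/long 3'UTR pair, a poly(A) signal 30 nt
#' upstream of each cleavage end, and UGUA elements flanking the proximal
#' PAS at +/-80 nt.
#'
#' @param n_genes number of genes to simulate.
#' @param frac_positive fraction of genes satisfying all three criteria.
#' @param decoy_mix named fractions of genes per decoy class
#'   (`no_multi_utr`, `pas_out_of_window`, `missing_ugua`); genes left over
#'   after positives and decoys are negatives (single isoform, no motifs).
#' @param utr_short_len,utr_long_len 3'UTR lengths (nt) of the proximal and
#'   distal isoform. `utr_long_len` must exceed `utr_short_len` by more than
#'   66 nt so the scan window of the distal end cannot reach the proximal
#'   PAS.
#' @param pas_offset nt between the planted PAS hexamer's 3'-most base and
#'   the cleavage end; must lie in the canonical 10-60 window.
#' @param decoy_pas_offset out-of-window offset used for the
#'   `pas_out_of_window` decoy class (default 5 nt).
#' @param ugua_offsets signed nt offsets of planted UGUA elements relative
#'   to the proximal PAS start; must include at least one negative
#'   (upstream) and one positive (downstream) value, all within 200 nt.
#' @param strand_policy `"plus_only"` or `"random"` (each gene drawn +/-).
#' @param n_replicates,baseline_ratio,oe_fold,kd_fold,ct_noise_sd,pcr_efficiency
#'   expression block: qPCR replicates per condition, latent long/total
#'   ratio of unperturbed genes, fold applied to responsive genes under
#'   NUDT21 overexpression (>= 1) and knockdown (<= 1), Gaussian sd added to
#'   simulated Ct values, and the amplification base (2 = perfect
#'   efficiency, matching the 2^-ddCt quantification model).
#' @param utr5_len,cds_len,spacer_len gene architecture: 5'UTR and CDS
#'   lengths, and intergenic spacing (>= 500 nt so +/-200 nt scan windows
#'   never cross genes).
#' @param seed integer seed; the same configuration and seed yield
#'   byte-identical FASTA/GTF/TSV outputs.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200,
                       frac_positive = 0.2,
                       decoy_mix = c(no_multi_utr = 0.2,
                                     pas_out_of_window = 0.2,
                                     missing_ugua = 0.2),
                       utr_short_len = 300,
                       utr_long_len = 600,
                       pas_offset = 30,
                       decoy_pas_offset = 5,
                       ugua_offsets = c(-80, 80),
                       strand_policy = c("plus_only", "random"),
                       n_replicates = 3,
                       baseline_ratio = 0.5,
                       oe_fold = 1.5,
                       kd_fold = 0.5,
                       ct_noise_sd = 0.2,
                       pcr_efficiency = 2,
                       utr5_len = 20,
                       cds_len = 120,
                       spacer_len = 500,
                       seed = 1) {
  strand_policy <- match.arg(strand_policy)
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (frac_positive < 0 || frac_positive > 1)
    stopf("frac_positive must lie in [0, 1]")
  need <- c("no_multi_utr", "pas_out_of_window", "missing_ugua")
  if (!all(need %in% names(decoy_mix)))
    stopf("decoy_mix must name fractions for: %s", paste(need, collapse = ", "))
  decoy_mix <- decoy_mix[need]
  if (any(decoy_mix < 0) || frac_positive + sum(decoy_mix) > 1 + 1e-9)
    stopf("frac_positive + sum(decoy_mix) must not exceed 1")
  if (!(utr_short_len > pas_offset + 6))
    stopf("utr_short_len must exceed pas_offset + 6")
  if (!(utr_long_len > utr_short_len + 66))
    stopf("utr_long_len must exceed utr_short_len + 66 nt")
  if (pas_offset < 10 || pas_offset > 60)
    stopf("pas_offset must lie in the canonical [10, 60] nt window")
  if (decoy_pas_offset >= 10 && decoy_pas_offset <= 60)
    stopf("decoy_pas_offset must lie outside [10, 60]")
  if (decoy_pas_offset < 0 || decoy_pas_offset + 6 > utr_long_len)
    stopf("decoy_pas_offset out of range for the long UTR")
  if (length(ugua_offsets) < 2 || !any(ugua_offsets < 0) || !any(ugua_offsets > 0))
    stopf("ugua_offsets must include at least one upstream (<0) and one downstream (>0) offset")
  if (any(abs(ugua_offsets) > 200))
    stopf("ugua_offsets must lie within 200 nt of the proximal PAS")
  pas_start <- utr_short_len - pas_offset - 5   # UTR-relative PAS start, 1-based
  ug <- pas_start + ugua_offsets
  if (any(ug < 1) || any(ug + 3 > utr_long_len))
    stopf("a planted UGUA would fall outside the long 3'UTR; adjust ugua_offsets")
  if (baseline_ratio <= 0 || baseline_ratio >= 1)
    stopf("baseline_ratio must lie in (0, 1)")
  if (oe_fold < 1) stopf("oe_fold must be >= 1")
  if (kd_fold <= 0 || kd_fold > 1) stopf("kd_fold must lie in (0, 1]")
  if (ct_noise_sd < 0) stopf("ct_noise_sd must be >= 0")
  if (pcr_efficiency <= 1 || pcr_efficiency > 2)
    stopf("pcr_efficiency must lie in (1, 2]")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (spacer_len < 500) stopf("spacer_len must be >= 500 nt")
  structure(list(
    n_genes = as.integer(n_genes), frac_positive = frac_positive,
    decoy_mix = decoy_mix, utr_short_len = as.integer(utr_short_len),
    utr_long_len = as.integer(utr_long_len), pas_offset = as.integer(pas_offset),
    decoy_pas_offset = as.integer(decoy_pas_offset),
    ugua_offsets = as.integer(ugua_offsets), strand_policy = strand_policy,
    n_replicates = as.integer(n_replicates), baseline_ratio = baseline_ratio,
    oe_fold = oe_fold, kd_fold = kd_fold, ct_noise_sd = ct_noise_sd,
    pcr_efficiency = pcr_efficiency, utr5_len = as.integer(utr5_len),
    cds_len = as.integer(cds_len), spacer_len = as.integer(spacer_len),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# class labels for each gene, shuffled under the active RNG stream
sim_gene_classes <- function(config) {
  n <- config$n_genes
  n_pos <- round(config$frac_positive * n)
  n_dec <- round(config$decoy_mix * n)
  n_neg <- n - n_pos - sum(n_dec)
  if (n_neg < 0) stopf("class fractions round to more genes than n_genes")
  cls <- c(rep("positive", n_pos),
           rep("decoy_c1", n_dec[["no_multi_utr"]]),
           rep("decoy_c2", n_dec[["pas_out_of_window"]]),
           rep("decoy_c3", n_dec[["missing_ugua"]]),
           rep("negative", n_neg))
  sample(cls)
}

# plant spans for one gene class; coordinates are 1-based relative to the
# UTR start; returns matrix with columns start, end plus motif names
sim_planted_spans <- function(class, config) {
  P <- config$utr_short_len
  D <- config$utr_long_len
  g <- config$pas_offset
  spans <- list()
  pas_at <- function(end, gap) c(end - gap - 5L, end - gap, "AATAAA")
  prox_pas_start <- P - g - 5L
  add_ugua <- function() lapply(config$ugua_offsets, function(o) {
    s <- prox_pas_start + o
    c(s, s + 3L, "TGTA")
  })
  spans <- switch(class,
    positive = c(list(pas_at(P, g), pas_at(D, g)), add_ugua()),
    decoy_c1 = list(pas_at(D, g)),
    decoy_c2 = c(list(pas_at(P, g), pas_at(D, config$decoy_pas_offset)),
                 add_ugua()),
    decoy_c3 = list(pas_at(P, g), pas_at(D, g)),
    negative = list()
  )
  if (length(spans) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0)))
  m <- do.call(rbind, spans)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             motif = m[, 3], stringsAsFactors = FALSE)
}

# rewrite accidental screen motifs in a UTR sequence, preserving planted
# spans; errors if a clean sequence is not reached in max_iter sweeps
scrub_utr <- function(utr, planted, max_iter = 500L) {
  covered <- rep(FALSE, nchar(utr))
  for (i in seq_len(nrow(planted)))
    covered[planted$start[i]:planted$end[i]] <- TRUE
  for (iter in seq_len(max_iter)) {
    spurious <- NULL
    for (m in SCRUB_MOTIFS) {
      hits <- find_fixed_overlapping(utr, m)
      for (h in hits) {
        is_planted <- any(planted$motif == m & planted$start == h)
        if (!is_planted) spurious <- rbind(spurious, c(h, h + nchar(m) - 1L))
      }
    }
    if (is.null(spurious)) return(utr)
    for (r in seq_len(nrow(spurious))) {
      pos <- spurious[r, 1]:spurious[r, 2]
      pos <- pos[!covered[pos]]
      if (length(pos) == 0)
        stopf("planted motifs collide irresolvably; adjust offsets")
      p <- if (length(pos) == 1) pos else sample(pos, 1)
      old <- substr(utr, p, p)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      substr(utr, p, p) <- new
    }
  }
  stopf("could not scrub spurious motifs within %d sweeps", max_iter)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant_motifs <- function(utr, planted) {
  for (i in seq_len(nrow(planted)))
    substr(utr, planted$start[i], planted$end[i]) <- planted$motif[i]
  utr
}

sim_truth_flags <- function(class) {
  switch(class,
    positive = c(TRUE, TRUE, TRUE),
    decoy_c1 = c(FALSE, TRUE, FALSE),   # c3 unevaluable without a proximal end
    decoy_c2 = c(TRUE, FALSE, TRUE),
    decoy_c3 = c(TRUE, TRUE, FALSE),
    negative = c(FALSE, FALSE, FALSE)
  )
}

#' Generate a synthetic genome with planted APA architecture
#'
#' Emits a single-chromosome genome, a GTF2.2 annotation and a ground-truth
#' table. Positive genes carry two 3'UTR isoforms sharing their 5' start,
#' with an AATAAA hexamer planted `pas_offset` nt upstream of both cleavage
#' ends and UGUA elements flanking the proximal PAS; each decoy class
#' violates exactly the criterion it is named for (no second isoform;
#' distal PAS outside the 10-60 nt window; no UGUA). 3'UTRs are scrubbed of
#' accidental AATAAA/ATTAAA/TGTA so truth labels are exact. Minus-strand
#' genes (under `strand_policy = "random"`) are stored reverse-complemented
#' with coordinates adjusted.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `apa_simulation`: a list with `genome`
#'   (a [Biostrings::DNAStringSet]), `features` (GTF feature table),
#'   `transcripts` (transcript models as returned by [read_gtf()]), `truth`
#'   (one row per gene: class, expected criteria flags, candidacy,
#'   responsiveness) and `config`.
#' @seealso [write_simulation()], [generate_expression()], [run_screen()]
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- sim_gene_classes(config)
  n <- config$n_genes
  gene_len <- config$utr5_len + config$cds_len + config$utr_long_len
  u0 <- config$utr5_len + config$cds_len + 1L   # gene-relative UTR start

  strands <- if (config$strand_policy == "plus_only") rep("+", n)
             else sample(c("+", "-"), n, replace = TRUE)
  gene_ids <- sprintf("G%04d", seq_len(n))

  chrom_parts <- character(2 * n + 1)
  chrom_parts[1] <- random_dna(config$spacer_len)
  feats <- vector("list", n)
  truth <- vector("list", n)
  offset <- config$spacer_len   # bases already emitted

  for (i in seq_len(n)) {
    cls <- classes[i]
    planted <- sim_planted_spans(cls, config)
    utr <- random_dna(config$utr_long_len)
    utr <- plant_motifs(utr, planted)
    utr <- scrub_utr(utr, planted)
    upstream <- random_dna(config$utr5_len + config$cds_len)
    sense <- paste0(upstream, utr)

    gstart <- offset + 1L
    gend <- offset + gene_len
    minus <- strands[i] == "-"
    chrom_parts[2 * i] <- if (minus) revcomp(sense) else sense
    chrom_parts[2 * i + 1] <- random_dna(config$spacer_len)
    offset <- gend + config$spacer_len

    # map gene-relative [a, b] to genomic 1-based coordinates
    map <- function(a, b) {
      if (minus) c(gend - b + 1L, gend - a + 1L) else c(gstart + a - 1L, gstart + b - 1L)
    }
    two_iso <- cls %in% c("positive", "decoy_c2", "decoy_c3")
    tx_ends_rel <- if (two_iso) c(u0 + config$utr_short_len - 1L, gene_len)
                   else gene_len
    gid <- gene_ids[i]
    tx_rows <- list()
    for (k in seq_along(tx_ends_rel)) {
      tid <- sprintf("%s.T%d", gid, k)
      txe <- tx_ends_rel[k]
      tx <- map(1L, txe)
      cds <- map(config$utr5_len + 1L, u0 - 1L)
      utr3 <- map(u0, txe)
      tx_rows[[k]] <- data.frame(
        feature = c("transcript", "exon", "CDS", "three_prime_utr"),
        start = c(tx[1], tx[1], cds[1], utr3[1]),
        end = c(tx[2], tx[2], cds[2], utr3[2]),
        gene_id = gid, transcript_id = tid, stringsAsFactors = FALSE)
    }
    tx_df <- do.call(rbind, tx_rows)
    gene_row <- data.frame(feature = "gene",
                           start = min(tx_df$start), end = max(tx_df$end),
                           gene_id = gid, transcript_id = NA_character_,
                           stringsAsFactors = FALSE)
    gf <- rbind(gene_row, tx_df)
    gf$seqname <- "chrS"
    gf$strand <- strands[i]
    feats[[i]] <- gf

    fl <- sim_truth_flags(cls)
    truth[[i]] <- data.frame(
      gene_id = gid, class = cls, c1 = fl[1], c2 = fl[2], c3 = fl[3],
      candidate = all(fl), responsive = cls == "positive",
      stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chrS"
  features <- do.call(rbind, feats)
  features$source <- "apascreen"
  features <- features[, c("seqname", "source", "feature", "start", "end",
                           "strand", "gene_id", "transcript_id")]
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$gene_id), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(genome = genome, features = features,
                 transcripts = features_to_transcripts(features),
                 truth = truth, config = config),
            class = "apa_simulation")
}

#' @export
print.apa_simulation <- function(x, ...) {
  cat(sprintf("apa_simulation: %d genes on %s (%d bp), seed %d\n",
              nrow(x$truth), names(x$genome)[1], Biostrings::width(x$genome)[1],
              x$config$seed))
  print(table(x$truth$class))
  invisible(x)
}

#' Generate replicated qPCR-style expression measurements
#'
#' Simulates long-amplicon and total-amplicon Ct values per gene, condition
#' and replicate. The latent long/total ratio of a responsive gene is
#' `baseline_ratio` under control, `baseline_ratio * oe_fold` under NUDT21
#' overexpression and `baseline_ratio * kd_fold` under each knockdown;
#' non-responsive genes keep the baseline ratio everywhere. Abundances are
#' converted to cycle thresholds through `Ct = -log(abundance, base =
#' pcr_efficiency)` and Gaussian noise of sd `ct_noise_sd` is added.
#'
#' @param config a [sim_config()] object.
#' @param truth truth table from [generate_genome()] (columns `gene_id`,
#'   `responsive`).
#' @param conditions condition labels; must include `control`, an
#'   overexpression (`OE`) and at least one knockdown (`KD*`).
#' @return a long-format data.frame with columns `gene_id`, `condition`,
#'   `replicate`, `amplicon` (`long`/`total`), `value_kind` (`"Ct"`) and
#'   `value`.
#' @export
generate_expression <- function(config, truth,
                                conditions = c("control", "OE", "KD1", "KD2")) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("gene_id", "responsive") %in% names(truth)))
    stopf("truth must have gene_id and responsive columns")
  if (!"control" %in% conditions || !"OE" %in% conditions ||
      !any(grepl("^KD", conditions)))
    stopf("conditions must include control, OE and at least one KD")
  if (config$baseline_ratio * config$oe_fold > 1)
    stopf("oe_fold x baseline_ratio exceeds 1: a long/total ratio cannot exceed 1")
  set.seed(config$seed)
  base <- config$pcr_efficiency
  total_ab <- base^-20   # latent total abundance, i.e. total Ct ~ 20
  nrep <- config$n_replicates
  out <- vector("list", nrow(truth) * length(conditions))
  idx <- 0L
  for (gi in seq_len(nrow(truth))) {
    for (cond in conditions) {
      ratio <- config$baseline_ratio
      if (truth$responsive[gi]) {
        if (cond == "OE") ratio <- ratio * config$oe_fold
        if (grepl("^KD", cond)) ratio <- ratio * config$kd_fold
      }
      ct_long <- -log(ratio * total_ab, base) + rnorm(nrep, 0, config$ct_noise_sd)
      ct_total <- -log(total_ab, base) + rnorm(nrep, 0, config$ct_noise_sd)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        gene_id = truth$gene_id[gi], condition = cond,
        replicate = rep(seq_len(nrep), 2),
        amplicon = rep(c("long", "total"), each = nrep),
        value_kind = "Ct", value = c(ct_long, ct_total),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a simulation to disk
#'
#' Writes `genome.fa` (60-column wrapped FASTA), `annotation.gtf` (GTF2.2
#' with gene/transcript/exon/CDS/three_prime_utr features), `truth.tsv` and,
#' when an expression table is supplied, `expression.tsv`. TSV and GTF files
#' carry the generating seed in a comment header; outputs are byte-identical
#' across runs with the same configuration.
#'
#' @param sim an `apa_simulation` from [generate_genome()].
#' @param dir output directory (created if missing).
#' @param expression optional table from [generate_expression()].
#' @return invisibly, a named character vector of file paths.
#' @export
write_simulation <- function(sim, dir, expression = NULL) {
  stopifnot(inherits(sim, "apa_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gtf"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]], width = 60L)
  write_gtf_features(sim$features, paths[["annotation"]],
                     header = sprintf("#!seed %d", sim$config$seed))
  write_seeded_tsv(sim$truth, paths[["truth"]], sim$config$seed)
  if (!is.null(expression)) {
    paths <- c(paths, expression = file.path(dir, "expression.tsv"))
    write_seeded_tsv(expression, paths[["expression"]], sim$config$seed)
  }
  invisible(paths)
}

write_seeded_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a truth or expression table written by [write_simulation()]
#' @param path TSV path (comment lines starting with `#` are skipped).
#' @return a data.frame.
#' @export
read_sim_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Mirror a simulation to the opposite strand
#'
#' Reverse-complements every chromosome and remaps all annotation
#' coordinates, flipping gene strands. The mirrored genome describes the
#' identical transcripts, so screening results must be invariant under this
#' transformation.
#'
#' @param sim an `apa_simulation`.
#' @return a new `apa_simulation` on the mirrored genome.
#' @export
mirror_simulation <- function(sim) {
  stopifnot(inherits(sim, "apa_simulation"))
  genome <- Biostrings::reverseComplement(sim$genome)
  names(genome) <- names(sim$genome)
  lens <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  f <- sim$features
  L <- lens[f$seqname]
  new_start <- L - f$end + 1L
  new_end <- L - f$start + 1L
  f$start <- as.integer(new_start)
  f$end <- as.integer(new_end)
  f$strand <- ifelse(f$strand == "+", "-", "+")
  structure(list(genome = genome, features = f,
                 transcripts = features_to_transcripts(f),
                 truth = sim$truth, config = sim$config),
            class = "apa_simulation")
}
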