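test_that("read_fasta returns uppercase named sequences and rejects bad input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a extra words", "acgt", ">b", "GGCC", "AATT"), fa)
  seqs <- read_fasta(fa)
  expect_equal(names(seqs), c("a", "b"))
  expect_equal(as.character(seqs[["a"]]), "ACGT")
  expect_equal(as.character(seqs[["b"]]), "GGCCAATT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(c(">a", "ACGT", ">empty", ""), fa)
  expect_error(read_fasta(fa), "empty")
})

test_that("read_gtf derives the 3'UTR from the CDS end, strand-aware", {
  # plus strand: CDS ends at 100, transcript ends at 160 -> UTR [101, 160]
  p1 <- write_gtf_fixture(c(
    gtf_line("c1", "transcript", 1, 160, "+", "gA", "tA"),
    gtf_line("c1", "exon", 1, 160, "+", "gA", "tA"),
    gtf_line("c1", "CDS", 21, 100, "+", "gA", "tA")))
  m <- read_gtf(p1)
  expect_equal(unname(m$utr3[[1]][1, ]), c(101L, 160L))
  expect_equal(m$cleavage_end, 160L)

  # minus strand: CDS starts at 201, transcript starts at 141 -> UTR
  # [141, 200], cleavage end at the transcript start
  p2 <- write_gtf_fixture(c(
    gtf_line("c1", "transcript", 141, 300, "-", "gB", "tB"),
    gtf_line("c1", "exon", 141, 300, "-", "gB", "tB"),
    gtf_line("c1", "CDS", 201, 280, "-", "gB", "tB")))
  m2 <- read_gtf(p2)
  expect_equal(unname(m2$utr3[[1]][1, ]), c(141L, 200L))
  expect_equal(m2$cleavage_end, 141L)

  # explicit three_prime_utr features win over derivation
  p3 <- write_gtf_fixture(c(
    gtf_line("c1", "transcript", 1, 160, "+", "gC", "tC"),
    gtf_line("c1", "exon", 1, 160, "+", "gC", "tC"),
    gtf_line("c1", "CDS", 21, 100, "+", "gC", "tC"),
    gtf_line("c1", "three_prime_utr", 111, 160, "+", "gC", "tC")))
  expect_equal(unname(read_gtf(p3)$utr3[[1]][1, ]), c(111L, 160L))

  # neither CDS nor three_prime_utr: empty UTR with a warning
  p4 <- write_gtf_fixture(c(
    gtf_line("c1", "transcript", 1, 160, "+", "gD", "tD"),
    gtf_line("c1", "exon", 1, 160, "+", "gD", "tD")))
  expect_warning(m4 <- read_gtf(p4), "neither CDS nor three_prime_utr")
  expect_equal(nrow(m4$utr3[[1]]), 0)
})

test_that("read_gtf rejects exons outside transcript bounds", {
  p <- write_gtf_fixture(c(
    gtf_line("c1", "transcript", 10, 100, "+", "gE", "tE"),
    gtf_line("c1", "exon", 5, 100, "+", "gE", "tE")))
  expect_error(read_gtf(p), "outside transcript bounds")
})

test_that("isoforms group by shared 5' UTR start with proximal-first ends", {
  set.seed(41)
  chrom <- Biostrings::DNAStringSet(c(c1 = random_clean_dna(500)))
  feats <- function(tx_end, tid, utr_start = 101) data.frame(
    seqname = "c1", feature = c("transcript", "exon", "three_prime_utr"),
    start = c(1, 1, utr_start), end = c(tx_end, tx_end, tx_end),
    strand = "+", gene_id = "g1", transcript_id = tid,
    stringsAsFactors = FALSE)

  # same start, ends 80 nt apart -> one group with two ends
  m <- read_gtf(rbind(feats(220, "t1"), feats(300, "t2")))
  grp <- group_utr_isoforms(m, chrom)
  expect_length(grp, 1)
  expect_equal(grp[[1]]$ends, c(220L, 300L))
  expect_equal(nchar(grp[[1]]$seqs), c(120L, 200L))
  # sequences share their 5' prefix
  expect_equal(substr(grp[[1]]$seqs[2], 1, 120), grp[[1]]$seqs[1])

  # different UTR starts -> two single-ended groups
  m2 <- read_gtf(rbind(feats(220, "t1"), feats(300, "t2", utr_start = 151)))
  expect_length(group_utr_isoforms(m2, chrom), 2)

  # identical (start, end) isoforms collapse
  m3 <- read_gtf(rbind(feats(220, "t1"), feats(220, "t2")))
  expect_length(group_utr_isoforms(m3, chrom)[[1]]$ends, 1)
})

test_that("minus-strand groups order ends by transcription, larger coordinate proximal", {
  set.seed(42)
  chrom <- Biostrings::DNAStringSet(c(c1 = random_clean_dna(500)))
  feats <- function(tx_start, tid) data.frame(
    seqname = "c1", feature = c("transcript", "exon", "three_prime_utr"),
    start = c(tx_start, tx_start, tx_start), end = c(400, 400, 300),
    strand = "-", gene_id = "g1", transcript_id = tid,
    stringsAsFactors = FALSE)
  grp <- group_utr_isoforms(read_gtf(rbind(feats(181, "t1"), feats(101, "t2"))),
                            chrom)
  expect_length(grp, 1)
  expect_equal(grp[[1]]$utr_start, 300L)
  expect_equal(grp[[1]]$ends, c(181L, 101L))   # proximal end numerically larger
  # sense sequence is the reverse complement of the plus-strand slice
  plus_slice <- as.character(Biostrings::subseq(chrom[["c1"]], 101, 300))
  expect_equal(
    grp[[1]]$seqs[2],
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_slice))))
})

test_that("a gene on multiple strands is rejected", {
  df <- data.frame(
    seqname = "c1", feature = rep(c("transcript", "exon"), 2),
    start = c(1, 1, 50, 50), end = c(40, 40, 90, 90),
    strand = rep(c("+", "-"), each = 2), gene_id = "g1",
    transcript_id = rep(c("t1", "t2"), each = 2), stringsAsFactors = FALSE)
  chrom <- Biostrings::DNAStringSet(c(c1 = strrep("C", 100)))
  expect_error(suppressWarnings(group_utr_isoforms(read_gtf(df), chrom)),
               "multiple chromosomes or strands")
})

test_that("BED output is 0-based half-open and round-trips coordinates", {
  hits <- data.frame(chrom = "c1", start = c(265L, 565L), end = c(270L, 570L),
                     gene_id = "g1", motif = "AATAAA", strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  bed <- tempfile(fileext = ".bed")
  write_bed(hits, bed)
  lines <- readLines(bed)
  expect_length(lines, 2)
  f1 <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.integer(f1[2:3]), c(264L, 270L))   # BED start is 0-based
  expect_equal(f1[4], "g1:AATAAA")
  back <- rtracklayer::import(bed)
  expect_equal(GenomicRanges::start(back), hits$start)
  expect_equal(GenomicRanges::end(back), hits$end)

  write_bed(hits[0, ], bed)
  expect_length(readLines(bed), 0)
})

test_that("GTF -> models -> GTF round trip is the identity", {
  cfg <- sim_config(n_genes = 6, strand_policy = "random", seed = 19)
  sim <- generate_genome(cfg)
  p1 <- tempfile(fileext = ".gtf")
  p2 <- tempfile(fileext = ".gtf")
  write_gtf(sim$transcripts, p1)
  m1 <- read_gtf(p1)
  write_gtf(m1, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(m1$cleavage_end, sim$transcripts$cleavage_end)
  expect_equal(m1$utr3, sim$transcripts$utr3, ignore_attr = TRUE)
})
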