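# builds a two-isoform group whose long UTR is clean background with
# motifs spliced in at chosen positions (1-based, relative to UTR start)
planted_group <- function(short_len, long_len, plants,
                          gene_id = "gX", seed = 1) {
  set.seed(seed)
  s <- random_clean_dna(long_len)
  for (i in seq_len(nrow(plants)))
    substr(s, plants$pos[i], plants$pos[i] + nchar(plants$motif[i]) - 1L) <-
      plants$motif[i]
  make_group(gene_id, c(substr(s, 1, short_len), s))
}

test_that("PAS hits respect the inclusive 10-60 nt window", {
  for (d in c(9L, 10L, 60L, 61L)) {
    g <- planted_group(300, 600,
                       data.frame(pos = 300L - d - 5L, motif = "AATAAA"))
    hits <- scan_pas(g)
    prox_hits <- hits[hits$end_rank == 1, ]
    if (d %in% c(10L, 60L)) {
      expect_equal(nrow(prox_hits), 1)
      expect_equal(prox_hits$distance, d)
      expect_true(prox_hits$is_proximal)
    } else {
      expect_equal(nrow(prox_hits), 0)
    }
  }
})

test_that("overlapping PAS occurrences are reported separately", {
  # AATAAATAAA holds AATAAA at both offsets 0 and +4
  g <- planted_group(300, 600, data.frame(pos = 255L, motif = "AATAAATAAA"))
  hits <- scan_pas(g)
  prox <- hits[hits$end_rank == 1, ]
  expect_equal(prox$rel_start, c(255L, 259L))
  expect_equal(prox$distance, c(40L, 36L))
  # agrees with the naive oracle
  orc <- oracle_pas_scan(g$seqs[1], "AATAAA", 10, 60)
  expect_equal(prox$rel_start, orc$pos)
  expect_equal(prox$distance, orc$distance)
})

test_that("PAS hit genomic coordinates map back to the motif", {
  g <- planted_group(300, 600, data.frame(pos = 265L, motif = "AATAAA"))
  hits <- scan_pas(g)
  h <- hits[1, ]
  # the group fixture is plus-strand starting at coordinate 1000
  expect_equal(h$start, 1000L + 265L - 1L)
  expect_equal(h$end, h$start + 5L)
})

test_that("UGUA rules distinguish flanking from same-side pairs", {
  pas_pos <- 265L
  both <- planted_group(300, 600, data.frame(
    pos = c(pas_pos, pas_pos - 50L, pas_pos + 120L),
    motif = c("AATAAA", "TGTA", "TGTA")))
  hit <- scan_pas(both)[1, ]
  r1 <- scan_ugua(both, hit, screen_params(ugua_rule = "flanking_both_sides"))
  r2 <- scan_ugua(both, hit, screen_params(ugua_rule = "any_two"))
  expect_true(r1$c3); expect_true(r2$c3)
  expect_equal(r1$offsets, c(-50L, 120L))

  upstream_only <- planted_group(300, 600, data.frame(
    pos = c(pas_pos, pas_pos - 50L, pas_pos - 120L),
    motif = c("AATAAA", "TGTA", "TGTA")))
  hit <- scan_pas(upstream_only)[1, ]
  expect_false(scan_ugua(upstream_only, hit,
                         screen_params(ugua_rule = "flanking_both_sides"))$c3)
  expect_true(scan_ugua(upstream_only, hit,
                        screen_params(ugua_rule = "any_two"))$c3)
})

test_that("UGUA offsets beyond the 200 nt radius are excluded", {
  pas_pos <- 265L
  g <- planted_group(300, 600, data.frame(
    pos = c(pas_pos, pas_pos - 50L, pas_pos + 201L),
    motif = c("AATAAA", "TGTA", "TGTA")))
  hit <- scan_pas(g)[1, ]
  res <- scan_ugua(g, hit)
  expect_equal(res$offsets, -50L)    # +201 dropped
  expect_false(res$c3)
  expect_equal(res$offsets,
               oracle_ugua_offsets(g$seqs[2], pas_pos, 200))
})

test_that("scanning matches the brute-force oracle on random sequences", {
  set.seed(99)
  par <- screen_params(extended_pas = TRUE)
  for (i in 1:25) {
    L <- sample(300:800, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    g <- make_group("gR", c(substr(s, 1, L %/% 2), s))
    hits <- suppressWarnings(scan_pas(g, par))
    for (k in 1:2) {
      got <- hits[hits$end_rank == k, c("motif", "rel_start", "distance")]
      got <- got[order(got$rel_start, got$motif), ]
      orc <- oracle_pas_scan(g$seqs[k], par$pas_motifs, 10, 60)
      expect_equal(got$rel_start, orc$pos)
      expect_equal(got$distance, orc$distance)
      expect_equal(got$motif, orc$motif)
    }
    prox <- hits[hits$is_proximal, ]
    if (nrow(prox) > 0) {
      res <- scan_ugua(g, prox[1, ], par)
      expect_equal(res$offsets,
                   oracle_ugua_offsets(g$seqs[2], prox$rel_start[1], 200))
    }
  }
})

test_that("evaluate_gene combines criteria as configured", {
  cfg <- sim_config(n_genes = 10, frac_positive = 0.4, seed = 7)
  sim <- generate_genome(cfg)
  groups <- group_utr_isoforms(sim$transcripts, sim$genome)
  names(groups) <- vapply(groups, `[[`, "", "gene_id")
  cls <- split(sim$truth$gene_id, sim$truth$class)

  v <- evaluate_gene(groups[[cls$positive[1]]])
  expect_true(v$c1 && v$c2 && v$c3 && v$candidate)

  v3 <- evaluate_gene(groups[[cls$decoy_c3[1]]])
  expect_true(v3$c1 && v3$c2 && !v3$c3 && !v3$candidate)
  v3any <- evaluate_gene(groups[[cls$decoy_c3[1]]],
                         screen_params(criteria_mode = "any"))
  expect_true(v3any$candidate)

  # single-isoform gene: c1 false, c3 vacuously false (no proximal end)
  v1 <- evaluate_gene(groups[[cls$decoy_c1[1]]])
  expect_false(v1$c1)
  expect_true(v1$c2)
  expect_false(v1$c3)
  expect_equal(v1$n_ends, 1L)
})

test_that("run_screen reproduces planted truth and filters by expression", {
  cfg <- sim_config(n_genes = 50, seed = 11)
  sim <- generate_genome(cfg)
  res <- run_screen(sim$transcripts, sim$genome)
  expect_equal(res$candidates$gene_id, sort(sim$truth$gene_id))
  m <- merge(res$candidates, sim$truth, by = "gene_id",
             suffixes = c(".obs", ".exp"))
  expect_equal(m$c1.obs, m$c1.exp)
  expect_equal(m$c2.obs, m$c2.exp)
  expect_equal(m$c3.obs, m$c3.exp)
  expect_equal(m$candidate.obs, m$candidate.exp)

  # generic expressed-gene intersection: half the positives
  pos <- sim$truth$gene_id[sim$truth$class == "positive"]
  half <- pos[seq_len(length(pos) %/% 2)]
  res2 <- run_screen(sim$transcripts, sim$genome,
                     expressed_gene_list = half)
  expect_equal(sort(res2$expressed_candidates$gene_id), sort(half))

  expect_error(run_screen(sim$transcripts,
                          Biostrings::DNAStringSet(c(other = "ACGT"))),
               "chrS")
})

test_that("an empty annotation yields an empty candidate table", {
  empty <- data.frame(seqname = character(0), feature = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), gene_id = character(0),
                      transcript_id = character(0))
  res <- run_screen(empty, Biostrings::DNAStringSet(c(c1 = "ACGT")))
  expect_equal(nrow(res$candidates), 0)
  expect_equal(nrow(res$pas_hits), 0)
})

test_that("enlarging the PAS window or UGUA radius never loses a candidate", {
  cfg <- sim_config(n_genes = 30, seed = 17)
  sim <- generate_genome(cfg)
  base <- run_screen(sim$transcripts, sim$genome, screen_params())
  for (par in list(screen_params(pas_window = c(5, 80)),
                   screen_params(pas_window = c(10, 100), ugua_radius = 300),
                   screen_params(ugua_radius = 250))) {
    wider <- run_screen(sim$transcripts, sim$genome, par)
    expect_true(all(wider$candidates$candidate[base$candidates$candidate]))
  }
})

test_that("the extended PAS set contains the 12 common hexamer variants", {
  par <- screen_params(extended_pas = TRUE)
  expect_length(par$pas_motifs, 12)
  expect_true(all(c("AATAAA", "ATTAAA") %in% par$pas_motifs))
  expect_true(all(nchar(par$pas_motifs) == 6))
})
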