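---
title: "Screening for NUDT21-responsive alternative polyadenylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for NUDT21-responsive alternative polyadenylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apascreen)
```

## The biological model

Cleavage and polyadenylation of a pre-mRNA is directed by a poly(A)
signal (PAS) — canonically the hexamer AAUAAA — positioned a short
distance upstream of the cleavage site, together with auxiliary elements.
The CFIm complex recognizes UGUA tetramers near the PAS; its 25 kDa
subunit NUDT21 (CFIm25) promotes usage of the distal site, so genes under
CFIm control produce relatively more long-3′UTR transcript when NUDT21 is
abundant and more short-3′UTR transcript when it is depleted.

A gene can only display this behaviour if its 3′UTR offers the machinery
a choice, which motivates the screen's three structural criteria
(evaluated by `evaluate_gene()`):

* **c1 — isoform structure.** At least two 3′UTR isoforms sharing their
  5′ starting point (the boundary after the stop codon) but ending at
  distinct cleavage sites. "Starting point" is read in transcription
  order: APA changes *ending* points, so only a shared 5′ boundary makes
  the comparison meaningful.
* **c2 — a positioned PAS.** A PAS hexamer whose 3′-most base lies 10–60
  nt (inclusive) upstream of a cleavage end. The distance is measured to
  *each transcript's own cleavage end* — not to the UTR start — because
  that is where PAS biology operates. By default every retained end must
  carry a PAS (`c2_rule = "all_ends"`): a site without its own signal
  would not be processed, and the screen's model gene has signals at both
  sites. `"any_end"` relaxes this.
* **c3 — CFIm binding sites at the proximal PAS.** UGUA elements
  "surrounding" the proximal PAS within 200 nt. The default reading of
  *surrounded* is flanking — at least one UGUA on each side
  (`ugua_rule = "flanking_both_sides"`); `"any_two"` accepts any two
  within the radius. The proximal PAS is the hit supporting the 5′-most
  non-distal cleavage end, ties broken by the smallest distance-to-end,
  which makes the choice deterministic. Offsets are measured
  start-to-start on the long isoform so a downstream flank exists; the
  search window simply shrinks where it would cross a UTR boundary.

Candidacy combines the criteria conjunctively by default
(`criteria_mode = "all"`). The screen's source description enumerates the
criteria with "or", but the biological model — a CFIm-bound UGUA cluster
at the proximal PAS of a multi-ended UTR — and the phrase "met the
criteria" imply conjunction; `"any"` is available as a flag and we take
no position on the original intent.

### PAS motif set

The default set is {AATAAA, ATTAAA} (DNA sense strand): the canonical
hexamer and its strongest natural variant. `extended_pas = TRUE` adds the
ten further common variants (TATAAA, AGTAAA, AAGAAA, AATATA, AATACA,
CATAAA, GATAAA, AATGAA, TTTAAA, ACTAAA). The conservative default keeps
the screen specific; the toggle documents what "or a similar sequence"
may include. Motifs are defined in RNA but matched on sense-strand DNA
(AAUAAA → AATAAA, UGUA → TGTA), since annotation and genome files are
DNA.

## Quantification and the responsiveness call

qPCR reports a cycle threshold Ct per amplicon; under amplification base
$b$ (2 at perfect efficiency), abundance $\propto b^{-Ct}$, and the
classical relative quantification is
$b^{-\Delta\Delta Ct}$ (`ddct_relative()`). For APA we form, per
replicate, the **long/total ratio**
$R = b^{-(Ct_{long} - Ct_{total})}$: the fraction of a gene's transcripts
extending past the proximal site. No reference gene enters this ratio —
both amplicons come from the same cDNA, so template-amount terms cancel.

`classify_responsive()` calls a gene responsive when

$$\bar R_{OE} \ge f \cdot \bar R_{ctrl} \quad\text{and}\quad
  \bar R_{KD_i} \le \bar R_{ctrl} / f \;\; \forall i,$$

with `min_fold` $f = 1.2$ by default and both comparisons additionally
required to be strict changes (so at $f = 1$ the rule degenerates to a
pure direction check and a perfectly flat gene is never called). The
source protocol states direction only; the 1.2 margin is this package's
parameterization, a small guard against replicate noise, and is exposed
as a flag. All knockdowns must pass by default (`require_all_kd`)
because the reference experiment used two independent shRNAs and
required both to agree. Two-sided Mann–Whitney p-values
(`rank_test()`: exact for combined $n \le 12$ without ties, normal
approximation with tie/continuity correction otherwise, via
`stats::wilcox.test`) are reported alongside each comparison but do not
gate the call — the underlying selection rule is directional, and with
triplicates the exact test cannot fall below $p = 0.1$ anyway.

## In-silico 3′RACE

3′RACE reverse-transcribes with an anchored oligo-dT primer
(35 nt adapter + 17 T in the default oligo) and amplifies with a
gene-specific forward primer plus a universal reverse primer that is a
prefix of the adapter. `predict_amplicons()` models the product as
*template from the forward primer's 5′ base to the cleavage end* +
*poly(A) tail* + *reverse-complemented adapter*, so a proximal and a
distal site differ in band size by exactly the distance between their
cleavage ends. Primer binding is exact-match (no mismatch or melting
model — this is a validation-scale tool and determinism keeps its tests
sharp), and a primer matching zero or multiple times is an error listing
positions. The default poly(A) length (17) and adapter (35 nt) are
counted from the printed RT oligo and are configurable.
`band_distinguishability()` applies a 50 nt minimum gap, a conservative
figure for a 1% agarose gel.

## The synthetic-data generator

`generate_genome()` emulates exactly the features the screen reads:

* genes with two 3′UTR isoforms sharing a 5′ start (`utr_short_len` 300
  nt, `utr_long_len` 600 nt by default — typical mammalian UTR scale,
  and far enough apart that a scan window at the distal end cannot reach
  the proximal signal);
* an AATAAA planted `pas_offset` (30) nt upstream of both ends — mid-window,
  matching the canonical ~21–30 nt PAS-to-cleavage spacing;
* UGUA elements at `ugua_offsets` (−80, +80) nt around the proximal PAS;
* one decoy class per criterion: `no_multi_utr` (single isoform),
  `pas_out_of_window` (distal PAS at 5 nt, outside 10–60; the proximal
  PAS stays in-window so c3 remains evaluable and true),
  `missing_ugua`, plus fully negative genes — by default 20% positives
  and 20% of each decoy class among 200 genes;
* replicated Ct tables under control / overexpression / two knockdowns
  with latent ratio 0.5 shifted by `oe_fold` 1.5 and `kd_fold` 0.5
  (ratios stay within (0, 1]), Gaussian Ct noise sd 0.2 cycles — a
  realistic well-to-well scatter — and triplicates as in standard
  qRT-PCR practice.

Background sequence is i.i.d. uniform ACGT, and every accidental
AATAAA/ATTAAA/TGTA inside a 3′UTR is rewritten (bounded rejection loop,
planted spans protected) before motifs are planted. This is the central
design choice of the generator: truth labels are *exact*, not
probabilistic, so screen recovery can be asserted at sensitivity =
specificity = 1 rather than approximately. The cost is realism — real
UTRs are AU-rich, contain non-functional PAS-like hexamers, introns, and
more than two isoforms — so passing these tests demonstrates correctness
of the scanning/decision logic, not performance on genomic data. Genes
are spaced ≥ 500 nt apart so no scan window crosses a gene; minus-strand
genes (under `strand_policy = "random"`) are stored reverse-complemented
with coordinates remapped, and `mirror_simulation()` flips an entire
simulation for strand-invariance testing. One RNG stream per artifact,
seeded from the configuration; the seed is recorded in GTF/TSV headers
and identical configurations produce byte-identical files.

One asymmetry is worth stating: a single-isoform gene has no proximal
end, so criterion 3 is *vacuously false* for it regardless of planted
UGUA elements. The `no_multi_utr` decoy therefore carries expected flags
(c1 = F, c2 = T, c3 = F) — c3 cannot be "true but unevaluable".

## Numerical conventions and degenerate inputs

* **Coordinates are 1-based inclusive everywhere** (GTF, Biostrings and
  GRanges convention); BED output converts to 0-based half-open at the
  boundary via rtracklayer. Keeping a single convention in-memory avoids
  the classic off-by-one at the cost of a conversion confined to
  `write_bed()`.
* Window bounds are inclusive on both sides: a PAS exactly 10 or 60 nt
  upstream counts, 9 or 61 does not; a UGUA at |offset| = 200 counts.
* Overlapping motif occurrences are all reported (AATAAATAAA yields two
  hits 4 nt apart).
* A 3′UTR shorter than the scan window yields no hits and a warning, not
  an error. A transcript with neither CDS nor explicit three_prime_utr
  gets an empty UTR with a warning and fails all criteria.
* Replicates with zero total abundance have an undefined ratio and are
  dropped with a warning. Non-finite Ct values are errors.
* Genes whose transcripts span multiple chromosomes or strands are
  rejected, as are exons outside transcript bounds and unknown strand
  codes.
* Multi-exon 3′UTRs are supported by concatenating exon slices in
  transcription order, but the generator emits intronless UTRs only and
  all validated behaviour is at sequence level.
* When a gene has several isoform groups (different UTR starts),
  `run_screen()` evaluates the most isoform-rich group, ties broken by
  5′-most start — deterministic and aligned with c1's intent.

## Problem sizes used by the tests

Module tests run on genomes of 6–50 genes; the end-to-end properties use
the generator's default conditions — 200 genes per genome across 20
seeds for screen recovery, 100 random 2 kb sequences against the
brute-force scanning oracle, and 500 genes × 6 replicates at 0.2 Ct
noise for the responsiveness recovery / false-positive bounds (≥ 0.95
recovery, ≤ 0.05 false positives at `min_fold = 1.2`). The acceptance
script recomputes all of these from scratch at a user-supplied seed.

## Known limitations

* The screen reads annotated isoform structure; it neither discovers
  unannotated poly(A) sites nor estimates usage from RNA-seq coverage
  (no PDUI-style index).
* Criterion counts from genome-scale runs depend on the annotation
  release; the package takes no position on any particular Ensembl
  version, and expression filtering is a generic user-supplied gene-list
  intersection rather than a database query.
* The responsiveness classifier compares group means with a fold margin;
  it reports but does not correct rank-test p-values across genes.
* The IHC proportion bins as published overlap at exactly 80% ("51–80%"
  vs "80% or more"); `proportion_bin()` resolves the tie upward, a
  documented convention rather than the original authors' stated intent.
* 3′RACE prediction ignores primer thermodynamics and PCR efficiency;
  band sizes are exact sequence arithmetic.
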