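---
title: "mirseek: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirseek: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseek)
```

`mirseek` implements a small-RNA analysis pipeline of the kind used in plant
miRNA studies: collapsed small-RNA tags are classified against reference
sets, conserved miRNA families are profiled as reads per ten million (RPTM),
novel miRNAs are called from genome-mapped tags that show both duplex arms
and a predictable fold-back precursor, and miRNA cleavage targets are
identified from degradome (PARE) 5'-end evidence. This vignette explains the
models and the design decisions; the README shows the workflow itself.

## Tag processing and classification

Reads are adapter-trimmed (`trim_adapter()`): the leftmost full adapter
occurrence, or an adapter prefix of at least `min_overlap = 5` bases running
to the read end, is removed, and reads are kept when the trimmed length falls
in `[min_len, max_len]`. The default window is 18–26 nt: plant miRNA
populations are dominated by 21- and 22-nt guides plus a 24-nt class, and all
three must pass. The window can be widened (up to 34 nt) for raw accounting.
Sequences are held internally as uppercase RNA; DNA input is converted once
at the boundary. FASTQ qualities are not interpreted — only an ambiguous-base
fraction filter (default 10%) is applied, since small-RNA protocols rarely
publish quality thresholds and the tag-counting downstream is robust to rare
miscalls.

Collapsed tags are classified hierarchically (`classify_tag()`), each tag
receiving the *first* matching category in the order

> ncRNAs → pre-miRBase → repeats → cdna → genome → unmapped,

which mirrors the usual processing narrative (structural-RNA exclusion first,
then known precursors). Published read-accounting tables do not always state
whether their rows were computed sequentially or independently; here the
order is an explicit argument (`order =`), so either convention can be
reproduced. A match is an exact substring occurrence (configurable to allow
mismatches); reverse-complement hits count for the repeat, cDNA and genome
categories but not for structural RNAs or precursors, whose reads are
sense-stranded, and never for mature-miRNA identity, which is
strand-defined.

## Family profiles and RPTM

A tag is assigned to a conserved family when it is identical to a mature
reference sequence (`match_mirbase()`). The profiling wrapper additionally
accepts 3'-end length variants of up to 2 nt (tag and reference identical
over their common prefix) — the dominant isomiR mode — and aggregates them
into the family. A tag identical to members of k different families is
counted 1/k to each. Rows are kept separate by family, arm (5p/3p) and star
status, matching the convention of printing star abundances as their own
(bold) rows.

RPTM is `raw_count * 1e7 / denominator` (`rptm_normalize()`), rounded
half-up to integers for reporting. The denominator is the library's total
clean reads (post-trimming, pre-classification): published family tables
rarely state their denominator, and total clean reads is the most common
convention; `denominators =` overrides it (e.g. with genome-mapped totals)
when a different convention is wanted.

## Novel miRNA discovery

Unannotated tags of 20–24 nt are mapped to the genome exactly on both
strands (`map_tags_to_genome()`); tags with more than 20 loci are treated as
repeat-derived and excluded. The mismatch tolerance is configurable (0 by
default, 1 being reasonable when tags from one species are mapped onto a
sister genome). Two tag loci on one strand, separated by a loop gap of at
least 3 nt within a 250-nt span, form a candidate hairpin: the genomic
segment spanning both arms is folded and the miRNA/miRNA* duplex checked.

`fold()` is a maximum base-pairing (Nussinov) engine written in C++:
pseudoknot-free, Watson–Crick plus G:U pairs, minimum hairpin loop of 3
unpaired bases; the score is the pair count sign-flipped so lower is better.
Maximum pairing is deliberately simple and dependency-free, and the engine
is validated against exhaustive structure enumeration for short sequences.
Its known weakness is degeneracy: on long random flanks many co-optimal
structures exist, and the traceback's choice among them is arbitrary. Two
design choices contain this. First, candidates are folded over the
arm-spanning segment only (the `excise_precursor()` windows of 15/200 nt
serve to bound the arm search, not as the folded sequence) — folding 200 nt
of random flank under a maximum-pairing objective would pair arm bases
promiscuously with flank and destroy the duplex signal. Second, the duplex
register used for the overhang test is estimated robustly: in an
antiparallel duplex `position + partner` is constant, so the modal
antidiagonal over all mature–star pairs is used, which is insensitive to a
slipped terminal pair.

`check_duplex()` passes a candidate when (a) mature and star occupy disjoint
spans pairing with each other, (b) at least 60% of mature bases pair with
star bases, (c) the star shows the canonical 2-nt 3' overhang within ±1 nt,
and (d) at most 5 mature bases are unpaired. The 60%/5-base/±1-nt numbers
follow community plant-miRNA annotation practice; primary reports typically
state only "star sequenced plus predictable hairpin", so these thresholds
are package decisions and all four are arguments. A call further requires
(`call_novel()`) the mature arm at `min_count >= 5` reads in at least
`min_libraries = 3` genotypes and the star sequenced (count ≥ 1) in at least
one library — reading the "both arms sequenced across genotypes" requirement
as: mature support everywhere, star evidence anywhere. The dominant arm is
the arm with the greater summed count; ties resolve to 5p, deterministically.

## Degradome targets

Complementarity is scored ungapped and antiparallel (`score_site()`):
miRNA position 1 pairs the last base of the transcript window, each
mismatch costs 1 and each G:U wobble 0.5. The half-unit wobble weight is
inferred from the half-unit mismatch scores (0.5, 1.5, 2.5, 3.5) that
degradome target tables print; it is exposed as `wobble_weight`. Sites are
every window with score ≤ 4 (`find_sites()`); gapped or bulged sites are out
of scope — the score is defined by mismatch counting, and fixed-length
MmeI-derived tags give no leverage to resolve bulges.

The expected cleavage position is the transcript base paired to miRNA
position 10, `site_start + (L - 10)`, i.e. opposite the 10/11 bond.
`tally_reads()` counts degradome 5' ends within ±1 nt of that position as
valid (a common degradome convention that absorbs 1-nt end ambiguity;
`window = 0` demands the exact position) against all reads on the
transcript. `percent_at_cleavage()` is `100 * valid / total` rounded
half-up to one decimal; `format_percent()` prints whole numbers bare, as
such tables are typeset. Reported rows need `min_valid` valid reads
(default 1); non-conserved miRNA families additionally need cleavage on the
same (family, gene) pair in at least 2 genotypes — conserved families are
exempt, as that support rule is described for low-abundance non-conserved
miRNAs only.

## The synthetic study

`simulate_study()` generates, from one seed, everything the pipeline
consumes: a 3-chromosome genome with planted precursors and decoy loci,
per-genotype tag libraries, a transcriptome with planted complementary
sites, degradome tables concentrated at the expected cleavage positions,
and reference FASTAs, together with the ground truth (`truth.json`).

* **Precursors** are mature + loop + star (arms swapped when the mature is
  placed 3p), the star built as `revcomp(mature[1..L-2])` plus two free 3'
  bases — the canonical 2-nt 3' overhang geometry — with 0–2 injected G:U
  wobbles and 0–1 mismatches. Each draw is folded and duplex-checked;
  failing draws are rejected and redrawn, so planted hairpins are valid by
  construction.
* **Placement** leaves at least 300 nt between any two planted elements, so
  a candidate hairpin contains at most one planted element and decoy loci
  cannot chain into spurious two-arm candidates. This is a simplification:
  real genomes contain clustered miRNAs and tandem repeats, and the
  generator does not exercise that failure mode.
* **Abundances** are log-normal across families (sdlog 1.25), with
  per-library log-normal jitter (sdlog 0.3) and Poisson sampling; stars are
  a `star_fraction = 0.25` of their mature; decoys are sequenced at low
  abundance; 5% of reads are random noise tags. Published family tables
  span roughly six decades of RPTM; at the desk-scale depth of 1e4 reads
  per library used throughout the tests, families below ~1e3 RPTM would be
  unsequenceable, so the generator compresses the dynamic range rather than
  emulate it fully. Recovery claims therefore say nothing about miRNAs
  sequenced near the detection floor.
* **Degradome** reads per transcript are Poisson around `depth = 200`; on a
  target transcript a binomial `signal_fraction = 0.7` of reads sit exactly
  at the expected cleavage position, the rest uniform — no RNA-structure-
  aware degradation background, no polymorphism between genotypes, no
  sequencing-error model.

Determinism: every generator takes an explicit seed and `simulate_study()`
derives component seeds from its master seed, so identical seeds give
byte-identical output files.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
default study (10 precursors, 50 decoys, 3 genotypes, depth 1e4, degradome
depth 200, signal fraction 0.7), validate the fold engine against exhaustive
enumeration for sequences up to 18 nt, and validate the site scan against an
exhaustive window scan on transcripts up to 5 kb — sizes chosen so each
stage's behaviour is fully observable at desk scale. Rounding is half-up
everywhere a table value is printed (RPTM to integers, percentages to one
decimal). Degenerate inputs: empty read sets collapse to empty tag tables;
transcripts shorter than the miRNA yield no sites; a transcript with no
degradome reads is suppressed from the report rather than reported as 0/0.

## Limitations

Genome mapping and site scanning are exact-substring methods scaled for toy
genomes (tens of kilobases) and transcriptomes (hundreds of transcripts);
production-scale data would need an indexed aligner in front of the same
interfaces. Maximum-pairing folding is not thermodynamic: it validates
duplex geometry but its `mfe_score` is a pair count, not an energy.
IsomiR handling is limited to 3' length variants; 24-nt siRNA-like families
are profiled but not distinguished from miRNAs; phased siRNA analysis and
degradome category classification (0–4 schemes) are out of scope.
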