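---
title: "Methods: two-library small-RNA analysis for CMS studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small-RNA analysis for CMS studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircms)
```

# The experimental design this package models

A cytoplasmic male sterile (CMS) line and its isogenic fertile
maintainer differ, ideally, only in the mitochondrial sterilizing
factor and whatever regulatory cascade it triggers. Sequencing the
small RNA fraction (18–30 nt) of floral buds from both lines —
one pooled library per line, here called **WA** (sterile) and **WB**
(fertile) — and comparing miRNA abundances is a standard design for
finding miRNAs involved in anther development and CMS occurrence.
Because each condition is one pooled library, there are **no
replicates**: the appropriate significance test is an exact test on a
pair of counts given the two library sizes, not a dispersion-based
model. Everything downstream of the sequencer is in scope here;
nothing upstream (library construction, qPCR validation) is.

# Stage by stage

## Preprocessing

Reads pass, in order: mean-quality filter, 5' contaminant removal,
3' adapter trimming, poly-A removal, N removal, and the 18–30 nt
length window. The order matters only for the itemized accounting;
membership of the final clean set is order-independent. Choices the
underlying protocol leaves open, made here once:

* *Low quality* means mean Phred < 20 (`min_qual`), applied only when
  qualities are present.
* *Poly-A* means ≥ 80 % A after trimming — a read of template origin
  essentially never reaches that fraction at these lengths.
* Adapter search allows one mismatch per 10 nt of adapter and requires
  at least 6 nt of adapter (or the full remaining suffix) to call a hit.

Cleaned reads are collapsed to unique tags; all later stages work on
tags weighted by per-library counts. The conservation invariants
(reads in = kept + removed, per filter; collapse preserves the read
multiset) are tested property-style on random fixtures.

## Annotation

Matching is **ungapped Hamming matching** with at most
`max_mismatch_ref` (default 2) mismatches — the mismatch mode of the
short-read aligners these pipelines historically used is gapless, and
two independent knobs cover the reference-mapping and the
known-miRNA steps. A tag hitting several categories is resolved by
the fixed priority rRNA > tRNA > snRNA > snoRNA > miRNA, which
reproduces "subtract structural ncRNA first, then identify miRNAs" as
a single pass. Internally, large tag sets are matched with a
pigeonhole scheme over Biostrings dictionaries (k+1 trusted bands;
a hit with ≤ k mismatches leaves at least one band clean), which is
exact and is tested against a brute-force all-window Hamming scan.

Family aggregation is a curation fact, not an algorithm: merged
families such as miR156/157 ship as an editable TSV
(`inst/extdata/family_alias.tsv`). The family abundance ratio is
deliberately computed from **raw** WA/WB read sums (not RPM): with
near-equal library sizes the published tables round to the same
values, and raw sums are what those tables print.

## Folding

The built-in folder maximizes a stacking-aware pair score
(G:C = 3, A:U = 2, G:U = 1, +2 for each pair stacked directly on
another, hairpin loops ≥ 3 nt) by dynamic programming with a
deterministic traceback (prefer leaving the 3' base unpaired, then
the smallest pairing partner, then the stacked continuation). The
stacking bonus matters: pure maximum-pairing folds scatter pairs over
long windows, while stacking concentrates them into helices, which is
what the duplex evaluation needs. The optimum is verified against
exhaustive enumeration of all nested structures for sequences up to
12 nt.

The folder's "MFE" is the negated score — a **pseudo-energy**, always
flagged `energy_model = "pseudo"`. For thermodynamic energies select
`backend = "vienna"` (shells out to `RNAfold` when installed); only
then is the |MFE| ≥ 18 kcal/mol precursor criterion active, because a
kcal/mol threshold is meaningless on the pseudo scale.

## Novel miRNA discovery

For each unannotated tag of mature length (20–24 nt) with at least
`min_reads` total reads (default 5 — a Mireap-style abundance floor
without which sequencing-noise singletons dominate runtime), mapped
uniquely enough (≤ 15 loci), candidate precursors are excised as a
**ladder of four windows**: 20 nt up / 160 nt down, the mirror, and a
compact pair with 60 nt (`flank_short`) in place of 160. The compact
pair exists because in a 200 nt window, distal sequence sometimes
outcompetes the true star arm under maximum-score folding; a window
just large enough for any plausible hairpin (mature ≤ 24 + loop ≤ 15
+ arm ≤ 24, plus slack) removes the competition. Acceptance is
deduplicated by locus (strand-agnostically, because the star arm of a
near-palindromic hairpin also maps antisense to the mature arm), so
which window found the hairpin does not matter.

The duplex is read **off the pair table of the fold**, not by
re-aligning sequences: the miRNA:miRNA\* duplex is taken as the
largest consistent helix run among the mature's pairing partners —
consecutive pairs on the majority arm with monotone (nested)
partners, bulge asymmetry ≤ 2 nt, and internal loops capped at 4 nt.
Pairs outside that run (a stray base pairing 100 nt away, a tail
folded back into the loop) are counted as duplex **mismatches**, not
bulges. Acceptance requires ≥ 60 % of mature bases in the run, ≤ 4
mismatches, and asymmetry within bound. If a wide window locates the
arm but fails these bounds, the window is re-folded once restricted
to the duplex neighborhood (± 12 nt) — the focused fold resolves
competition that the wide fold cannot.

The star is the duplex partner shifted by the canonical 2-nt 3'
overhang. Because a sequenced star can sit a couple of nucleotides
off the computed partner, the "star observed" flag accepts any tag
contained in the star region ± 2 nt, preferring the most abundant.

**Known limitation.** The numeric duplex criteria alone admit
occasional chance hairpins: an abundant random 20–24 nt tag placed in
a random genome passes them a few percent of the time, under the
built-in folder *and* under RNAfold. This is inherent to
count-free structural criteria (it is why star support and shuffling
p-values exist in the literature). In practice the `min_reads` floor
keeps random background tags out, star support separates planted from
chance candidates, and the thermodynamic backend adds the MFE floor;
shuffling-based significance (randfold-style) is out of scope.

## Differential expression

Expression is reads per million of **total clean reads per library**.
The alternative reading, "per million miRNA-mapped reads", is
rejected by a printed-value check: only total-clean-read denominators
(20,287,225 / 21,989,236) reproduce the published 11.09-fold change
for the WA-specific novel miRNA with raw reads (443, 0). A zero count
becomes the pseudo-expression 0.01 **after** normalization, exactly
as the convention states, so a 443-read WA-specific miRNA yields
log2(21.8364 / 0.01) ≈ 11.09.

The test is the exact Audic–Claverie two-library test. Given count x
in a library of n1 and y in a library of n2, and t = n2/n1, the
conditional law of y given x is negative binomial
(size x + 1, prob n1/(n1+n2)); the two-sided p doubles the smaller
tail (capped at 1). Two numerical points:

* tails are computed with `pnbinom` (and its `lower.tail = FALSE`
  upper tail — the naive `1 - pnbinom(...)` loses all precision for
  p below ~1e-14);
* the p-value is **symmetrized over the conditioning direction** (the
  maximum of the two conditionals), because the single-direction
  formula is not exactly label-symmetric when n1 ≠ n2, and exchanging
  WA and WB must not change significance. The symmetrization is
  conservative; the empirical type-I error at α = 0.05 on 2,000
  simulated null miRNAs stays below 0.05.

Calls use the raw p ≤ 0.05 and |log2 FC| ≥ 1 (the fold-change
threshold is on the log2 scale — the fold change is *defined* as a
log2). Benjamini–Hochberg q-values are reported alongside but do not
affect calls, mirroring the single-library-pair practice. Fisher's
exact test on (x, n1−x; y, n2−y) is available as an alternative.

## Target prediction and the network

The expectation score penalizes each duplex position — mismatch 1,
G:U wobble 0.5, indel 2 — doubled within the seed (miRNA positions
2–13 from the 5' end); at most one indel; sites at or below
expectation 3.0 are reported. Transcript scanning is vectorized
(prefix-sum evaluation of all single-gap alignments) and verified
against per-window rescoring; overlapping sites keep the lowest
expectation. Inhibition is annotated "translation" when a mismatch
falls at miRNA positions 9–11 (the cleavage-site region), else
"cleavage". The network keeps only differentially expressed miRNAs;
an edge is "negative" only when target expression direction is
supplied and opposes the miRNA's call — without expression data the
correlation is reported "unknown", never guessed.

# The synthetic-data generator

`simulation_config()` defaults define the study conditions used by
the tests and the acceptance script: a 100 kb genome, 30 known
miRNAs, 20 planted novel hairpin loci on both strands, 10 structural
ncRNA decoys, 200,000 reads per library, star reads at 5 % of mature
abundance, per-base substitution noise 0.001, and a fold-change table
giving 20 % of miRNAs a true |log2 FC| of 2–3 (infinite fold change
means absent from one library). Counts are **Poisson** — with one
pooled library per condition no overdispersion is estimable, so a
negative binomial would add an unidentifiable parameter. Mature
means are log-normal around `mean_count` (default 200 reads),
putting planted miRNAs in the well-powered regime the published
summary tables show for DE-called miRNAs.

Planted hairpins are canonical **by construction**: mature 20–24 nt,
loop 8–15 nt, opposite arm the reverse complement with ≤ 2 planted
non-pairing substitutions, resampled until the folded precursor's
optimal structure is the intended one (the evaluator confirms the
planted arm and exactly the planted mismatch count). Without that
check a few percent of random arms are self-complementary enough to
misfold, which would corrupt the truth table rather than test the
pipeline. Transcripts carry one perfect complementary site per
fold-changed miRNA so the target/network stages have planted truth
too.

What the generator does **not** emulate: sequencer error profiles
and adapter-ligation bias, multi-locus miRNA families, isomiR
heterogeneity, degradation products of real transcriptomes, and the
heavy-tailed abundance of real libraries. Passing the recovery tests
therefore shows the pipeline's logic is correct on data satisfying
its own assumptions — it does not certify performance on real
libraries, where annotation databases and thermodynamic folding
matter more.

# Problem sizes and determinism

Unit tests run on small fixtures (genomes of 20–50 kb, libraries of
4,000–5,000 reads); the end-to-end recovery checks use the full
default conditions (100 kb genome, 2 × 200,000 reads), which complete
in a couple of minutes. Every stochastic step is driven by the
configured seed; identical configuration and seed give byte-identical
report files, and the suite asserts this. Thresholds that came from
the modeled protocol (18/30 nt, 2 mismatches, pseudo 0.01, α = 0.05,
|log2 FC| ≥ 1, expectation ≤ 3.0, seed 2–13, duplex bounds) are all
configuration fields with those values as defaults, never hard-coded
in stage logic.
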