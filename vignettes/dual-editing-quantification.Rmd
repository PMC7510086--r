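---
title: "Quantifying dual base-editing outcomes from amplicon reads"
author: "dualedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual base-editing outcomes from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualedit)
```

## The problem

Dual-function base editors carry both a cytidine deaminase (C•G → T•A) and
an adenosine deaminase (A•T → G•C) on one Cas9 nickase, and their defining
claim is *same-strand co-editing*: a single DNA molecule acquiring both a
C-to-T and an A-to-G substitution at one protospacer. Bulk Sanger traces
cannot make that claim — two substitutions visible in a trace may live on
different alleles. Amplicon deep sequencing can, because each read is one
molecule. `dualedit` implements the corresponding read-level analysis:

1. **Quality filter.** A read is kept iff its mean Phred score is at least
   30. The filter is read-level because amplicon pipelines conventionally
   summarize quality per read; the threshold is a parameter
   (`quality_threshold`) for anyone who prefers a different rule.
2. **Orientation and alignment.** Each read and its reverse complement are
   aligned semi-globally (read end-to-end, reference overhangs free) to the
   reference amplicon with affine gap scores (match +2, mismatch −3, gap
   open −5, gap extend −1); the better orientation wins, ties go to
   forward. Reads with alignment identity below 0.75 are counted
   `unaligned`; reads whose alignment does not span the whole protospacer
   are counted `not covering` and excluded from every denominator. This is
   the only denominator under which per-position frequencies are
   well-defined; `n_total`, `n_pass_qc`, `n_aligned` and `n_covering` are
   all reported so the attrition is auditable.
3. **Per-read classification.** The bases observed at the L protospacer
   positions (expressed on the protospacer strand, so minus-strand sites
   behave identically) classify each read as `WT`, `C_TO_T_ONLY`,
   `A_TO_G_ONLY`, `DUAL_SAME_STRAND` (at least one C>T *and* one A>G call
   on the same read), `INDEL`, or `OTHER`. Indels take precedence —
   pie-chart conventions treat indel reads as one standalone slice — and
   unrelated substitutions never demote a read out of its C>T/A>G/dual
   class. Ambiguous bases (`N`) and deleted positions never produce calls.
4. **Aggregation.** Category frequencies, an allele (haplotype) table keyed
   by the full L-character call string, per-position C>T / A>G frequencies,
   cross-site means in PAM-relative coordinates, dinucleotide-context
   preference, and Welch *t* comparisons between replicate groups.

## Coordinates and windows

Protospacer positions are numbered +1 (PAM-distal, 5′) to +L, with the PAM
at +L+1..+L+3 (+21..+23 for a canonical 20-nt spacer). The reporting
windows default to +1..+7 for C-to-T and +4..+6 for A-to-G — the ranges
where this class of editor is active. Windows are a *reporting* concept:
classification counts co-occurrence anywhere in the protospacer, because
co-editing claims are about substitutions on one molecule, not about where
the deaminase is most active. A `windows_only` flag restricts
classification to the windows for anyone who wants the stricter gate.

## Dual classification is read-level, deliberately

`DUAL_SAME_STRAND` requires a C>T call and an A>G call in the *same*
read's call string, which is the level at which "both edits on one allele"
is literally true. The invariant is checked in the test suite: every dual
haplotype string carries a T at a reference-C position and a G at a
reference-A position simultaneously.

## Alignment engine

Alignment is `Biostrings::pairwiseAlignment(type = "global-local")` with a
substitution matrix in which `N` scores 0 against everything. The package
maps its gap convention (a k-column gap costs `open + (k−1)·extend` with
open 5, extend 1) onto Biostrings' `gapOpening`/`gapExtension` parameters,
and the test suite verifies optimal scores against an independently
written Gotoh dynamic program on 500 random small sequence pairs.

Deep amplicon data is dominated by full-length substitution-only reads, so
the batch path first screens each read (both orientations) by ungapped
Hamming identity; reads at ≥ 0.95 are resolved by direct column
comparison, everything else — length changes, heavy damage — goes through
the full affine DP. For substitution-only reads the two routes give
identical per-position observations (asserted in the tests); gapped
realignment of scattered substitutions is never score-optimal at that
identity, because converting a mismatch (−3 → +2 gain of 5) cannot repay
two gap openings (−10) unless at least three mismatches are rescued at
once, which scattered errors do not allow.

## Indel window

A read is `INDEL` when any insertion or deletion touches the protospacer +
PAM extended by `indel_flank` (default 5 nt) on each side; insertions at
the window edge count as inside. Published indel proportions rarely state
their window; flanked-protospacer is the convention of amplicon-editing
quantifiers, and the flank is a parameter.

## The synthetic generator

Real deposited reads (SRA accession PRJNA601637) are not redistributable
inside a package, so every pipeline property is validated on synthetic
reads whose truth is known. `simulate_read_set()` emits full-amplicon
copies with:

* an outcome class per read (`WT`/`CT_ONLY`/`AG_ONLY`/`DUAL`/`INDEL`), or
  a per-position Bernoulli "profile" mode in which the marginal
  per-position edit frequency equals the profile exactly (what
  spectrum-recovery experiments need);
* class-specific edits applied on the protospacer strand;
* deletions of 1–10 nt (geometrically decaying lengths — the small-deletion
  regime of nickase repair) starting uniformly in the protospacer;
* uniform per-base sequencing error (each base miscalled with probability
  ε to one of the three alternatives), constant Phred qualities (default
  Q37), and random read orientation (probability 0.5).

Default study conditions: 20,000 reads per sample; dual fraction 0.2788
(the strongest reported reporter-locus co-editing operating point); a 3%
indel load (the middle of the reported 1.72–5.11% range); ε = 0.001
(Q30-scale error). `default_ct_profile()` encodes the editing windows as a
trapezoid over +1..+7 spanning 0.11–0.29 (the reported 10.92–29.00% band)
and an A>G profile of 0.071/0.117/0.071 over +4..+6 (reported 7.07–11.68%).
`fixture_panel()` builds 45-site panels of random 200–300-nt amplicons
with embedded G-N19-NGG protospacers on random strands, guaranteeing at
least one editable C in +2..+7 and A in +4..+6; a `tc_multiplier` doubles
(by default: leaves alone) the C>T rate at TC dinucleotides to emulate
cytidine-deaminase context preference.

What the generator does **not** model: PCR jackpots and chimeras,
quality-by-cycle error profiles, strand-specific error asymmetries, and
insertions (available behind the deletion-only default). Passing the
recovery tests therefore demonstrates correctness of the *quantification*
given the stated noise model, not robustness to every artifact of real
libraries.

## What recovery can and cannot show

With ε = 0 and fixed patterns, pipeline frequencies equal the generator's
realized counts exactly. With ε > 0 there is an irreducible
misclassification floor: a WT read that picks up both a C>T-looking and an
A>G-looking error is *indistinguishable* from a true dual read. Its
per-read probability is approximately `nC·nA·(ε/3)²` (nC, nA = number of
protospacer C and A positions) — about 1 read in 18,000 at ε = 0.005 for a
typical 20-nt protospacer. This is negligible against any real signal but
means a sample with *zero* true dual editing is expected to report a few
false dual reads per 20,000 at high error rates; the recovery test suite
shows exactly this behaviour, and per-sample background subtraction with
an untreated control (as in any careful experiment) is the remedy on real
data.

## Statistics

Group comparisons use the Welch unequal-variance two-tailed *t* test
(replicate counts are typically 3, so degrees of freedom are fractional);
significance tiers are N.S. (p ≥ 0.05), `*` (0.05 > p ≥ 0.001), `**`
(0.001 > p ≥ 0.0001), `***` (p < 0.0001). Published legends of this form
are sometimes internally inconsistent between the `*` and `**` ranges;
the package uses the only self-consistent reading. No multiple-testing
correction is applied, matching field practice for per-locus panels; this
is a documented choice, not an oversight. Replicate summaries report mean
± s.e.m. with the sample standard deviation (n−1) over √n.

## Guide tools

`validate_guide()` checks the G-N19-NGG design rule with 3′-anchored
protospacer matching; `spacer_variants()` builds PAM-anchored length
variants (15–31 nt) that share the PAM-proximal end, extending 5′-ward
into genomic sequence for long variants and reporting — never silently
fixing — a non-G leading base. `scan_offtargets()` is an un-gapped
both-strand scan: windows whose trailing 3 nt match the PAM pattern
exactly (no mismatch budget in the PAM, which matches "mismatches in the
sgRNA target sequence" search settings) and whose spacer portion has at
most `max_mismatches` (default 3) differences; `N` in the genome counts as
a mismatch and never satisfies a PAM. A linear scan is deliberate — panels
of candidate loci are kilobases, not genomes — and the suite checks
equality with a brute-force position-by-position oracle.

## Numerical and tie-break choices

* Allele tables order by count descending, ties broken by haplotype string
  in C-locale; outputs are byte-reproducible.
* Orientation ties go to forward.
* Frequencies over an empty covering set are `NA` (flagged), never 0; the
  same holds for spectrum positions whose reference base is not editable.
* Problem sizes in the test suite: 20,000 reads per stochastic-recovery
  cell (the depth at which a 0.3–28% frequency has a sub-percent binomial
  SD), 45 × 2,000 reads for panel aggregation, 500 random pairs for the
  alignment oracle, all 6⁴ call strings for the classification oracle.

## Limitations

Paired-end merging, adapter trimming, demultiplexing and UMI handling are
out of scope — input is merged single-end FASTQ. SAM/BAM ingestion is not
provided. Off-target *editing* is quantified by running the same
quantifier on the listed loci, not by a genome-scale search. Sanger-trace
quantification is a different problem and is not reimplemented here.
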