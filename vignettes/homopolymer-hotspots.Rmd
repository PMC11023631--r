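---
title: "Homopolymer spectra, shuffle nulls and slippage hotspots: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homopolymer spectra, shuffle nulls and slippage hotspots: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homorun)
```

## The biological question

Sedentary chromosomal integrons (SCIs) carry very large cassette arrays
whose dynamics are driven by a tyrosine recombinase, the integron
integrase (in *Vibrio cholerae*, IntIA). When integrase activity becomes
costly, the cheapest evolutionary escape is to break the integrase gene,
and the gene's DNA homopolymers — maximal stretches of one repeated
nucleotide — are natural breakpoints: replication slippage
(slipped-strand mispairing, SSM) at a long run produces a +/-1 bp indel
and a frameshift. An 8xA run near the 5' end of *intIA* is the canonical
example of such a hotspot. This package implements the sequence-level
analyses around that observation:

1. decompose genes into maximal homopolymer runs and build run-length
   spectra and per-position "barcode" tracks;
2. compare observed spectra to a composition-preserving nucleotide-shuffle
   null ("theo" spectra);
3. compare two groups of genes (SCI-like vs MI-like integrases) through
   per-length enrichment ratios;
4. filter deep-sequencing variant calls (allele frequency, Fisher strand
   balance) and attribute the surviving indels to homopolymer runs;
5. normalize integron array maps for IS-location displays; and
6. simulate all of the above with planted ground truth.

## Run decomposition and spectra

`split_runs()` tiles a sequence into maximal runs (e.g. `ATTTAACC` ->
`A`, `TTT`, `AA`, `CC`); the runs are sorted, non-overlapping and join
back to the input, which the test suite checks on large random panels.
`run_spectrum()` counts runs by length independently of base content,
top-coding at `lmax = 10`: spectra are reported for lengths 1-10 and any
longer run lands in the top bin, while raw lengths are retained so the
conservation law (sum of length x count equals total bases) stays
checkable. Coordinates are 1-based inclusive throughout, the native R and
Bioconductor convention; ATG-relative positions are reported with the A
of the start codon as position 1.

Group spectra pool runs across the group's sequences (runs never span a
sequence boundary). Whether one should pool runs or average per-sequence
proportions is genuinely open; pooling weights genes by their run counts
and is what `group_frequencies()` implements. For panels of same-length
genes, as here, the two differ negligibly.

`barcode_track()` reports, per position, the length of the covering run
when that length is at least `min_len = 3` (shorter runs are visual
noise), with display saturation at 8 — the standard barcode rendering of
a gene's homopolymer landscape.

## The shuffle null

The "theoretical" spectrum of a gene is the mean spectrum of uniformly
random permutations of its own residues, so each gene's null preserves
its exact base multiset. `null_spectrum()` uses Monte-Carlo permutation
with a default of 10,000 replicates, the standard protocol for this
analysis; per-bin replicate SDs are retained purely so tests can use
tolerance bands. Group-level theo spectra are pooled per-sequence null
means, normalized last.

Reproducibility: one root seed; each sequence gets a stream derived
deterministically from (seed, id) by `seed_for_sequence()`, so results
are independent of processing order, and identical inputs with one seed
are bit-identical.

Two independent oracles validate the Monte-Carlo machinery:

* `exact_null_enumeration()` enumerates all distinct arrangements of the
  base multiset (equiprobable under a uniform permutation) and averages
  their spectra; it refuses beyond 1e5 arrangements, which is ample for
  the short-sequence panels it exists for.
* `iid_expected_runs()` is the closed form for i.i.d. sequences: with
  composition \(p\) and length \(n\), the expected number of maximal runs
  of length exactly \(L < n\) is
  \[\sum_b \left[(n - L - 1)\, p_b^L (1-p_b)^2 + 2\, p_b^L (1-p_b)\right],\]
  interior windows needing a mismatch on both sides and the two edge
  windows one; for \(L = n\) it is \(\sum_b p_b^n\). The suite validates
  this against exhaustive enumeration of all \(4^n\) sequences up to
  \(n = 8\), and a 10 kb shuffle null reproduces it to within 2% for all
  bins with expected count >= 1 — at that scale, shuffling an i.i.d.
  draw is statistically indistinguishable from redrawing it.

## Group enrichment ratios

`enrichment_ratio()` reports, per length bin, the ratio of group A's
frequency to group B's, both observed and theoretical. Ratios are never
silently dropped: each carries a status — `finite`, `zero_numerator`, or
`undefined_zero_denominator` (the numeric value is then `Inf` or `NaN`
and consumers must check the flag). A zero denominator under a positive
numerator is an unbounded enrichment, which is exactly the interesting
outcome when the comparison group simply lacks long runs. No
pseudo-counts are added by default (the canonical analysis reports raw
differentials); a `pseudocount` argument exists for exploratory use only.
No confidence intervals are attached to ratios.

A calibration caveat: the ratio of two independent run counts is only
stable when both expectations are large. Counts of rare long runs are
near-Poisson, so at an expected count around 7 per group the ratio falls
outside [0.5, 2] roughly one time in five even under a perfect null;
bands that tight are meaningful only for bins with expectations well
above ~20. The test suite computes the empirical coverage itself.

## Variant filtering

`parse_variants()` consumes Freebayes-dialect VCF v4.2 (INFO keys `AO`,
`RO`, `SAF`, `SAR`, `SRF`, `SRR`, `DP`), decomposing multi-allelic sites
into per-allele records. Choices the VCF itself does not dictate:

* **Frequency denominator.** `freq = AO / (AO + RO)` by default — the
  per-allele observation ratio is robust to depth inflation at
  overlapping alleles; `AO / DP` is available as `freq_mode = "depth"`.
* **Threshold semantics.** `frequency_filter()` keeps `freq >= min_freq`
  (default 0.001, i.e. 0.1%, appropriate at ~10,000x coverage); the
  boundary case is kept.
* **Strand test.** `strand_balance_filter()` runs a two-sided Fisher
  exact test on the 2x2 table [[alt_fwd, alt_rev], [ref_fwd, ref_rev]]:
  the reference reads supply the per-site strand baseline, so a site
  whose alt reads all sit on one strand while ref coverage is balanced —
  the classic artifact signature — is removed at `p < 0.05`. P-values
  come from exact hypergeometric summation (verified exhaustively
  against brute-force summation and against `fisher.test()`), with no
  multiple-testing correction: the filter is per-record hygiene, not an
  inference procedure. Records lacking strand counts are kept but
  flagged; all-zero tables are excluded with a warning.

Both filters log every removal with exactly one reason
(`removed_variants()`), and they commute.

## Indel attribution

VCF encodes a homopolymer indel ambiguously (any anchor within the run,
arbitrary padding). `normalize_indel()` first trims to the parsimonious
representation, then left-aligns against the reference, producing the
canonical anchor form. An indel is attributed to run R iff its net
inserted/deleted bases are all R's base and its normalized anchor lies
within R or immediately 5' of it; runs shorter than 3 are not
attribution targets, and SNV/MNV records are never attributed. The test
suite checks that equivalent right-shifted encodings of the same event
land on the same run. `hotspot_table()` then sums attributed variant
frequencies per run (ties broken by position) and reports per-position
frequencies by variant type, ATG-relative.

## Array maps

`normalize_map()` sends an array envelope [start, end] (1-based
inclusive) onto [0, 1] by the direct affine map and, when the integrase
sits on the right, reflects (`x -> 1 - x`) and flips orientations so all
strains read integrase-first; interspace gaps between SCI parts are
flagged. Reflection is involutive to 1e-12. `inversion_segment()` calls
a pair of opposite-orientation IS copies an inverted repeat and reports
the inter-IS segment (exclusive of the ISs) that recombination between
them would invert; orientation `unknown` yields `indeterminate`, and no
sequence-level recombination is modeled.

## Synthetic data: what it does and does not emulate

`generate_cds()` draws i.i.d. backgrounds (uniform composition by
default) and overwrites planted runs, flank-guarded so planted lengths
are exact. `generate_group_panel()` encodes the two group policies:
SCI-like plants one run of length 7-9 per 1 kb gene; MI-like
rejection-samples until no run exceeds 5. Those defaults mirror the
qualitative contrast the analysis is built to detect — long runs present
versus absent — at the panel scale (50 x 1 kb) used throughout.
`simulate_integrase_gene()` is the canonical single-gene fixture: 960 bp,
ORF-mode, an 8xA run at position 58 (57 bp after the A of the ATG) plus a
7-mer and a 6-mer, background capped at 5 so the planted runs are the
gene's largest homopolymers, as in the real *intIA* layout.

`slippage_model()` assigns run L an indel rate `min(r1 * g^(L-1),
rate_max)` (defaults r1 = 1e-5, g = 4, cap 0.5). The geometric form is a
testability device, not an empirical claim about SSM kinetics: it makes
rate order strictly monotone in run length so hotspot recovery has an
unambiguous ground truth. `simulate_variants()` emits one +/-1 bp indel
per eligible run (left-aligned, parsimonious), background SNVs at a flat
per-site noise rate, binomial read counts at fixed coverage, binomial
strand splits, and optional planted strand-biased artifacts; every
emitted record appears exactly once in the ground-truth table.

Deliberately not emulated: codon usage and amino-acid realism beyond the
ORF constraints, read-level sequencing error (no FASTQ), correlated or
multi-unit slippage events, selection and population dynamics. Passing
tests therefore demonstrate that the pipeline recovers planted structure
under a known generative model — not that real integrase sets or real
sequencing runs would yield any particular effect size.

## Problem sizes and numerical choices

Defaults follow the methodological protocol (10,000 shuffle replicates;
0.1% frequency threshold; alpha 0.05). The test suite and the analysis
drivers run the same estimators at reduced replicate counts — 50 per
sequence for 100-gene panels, 200 in the interactive driver, 20,000 for
the single 10 kb closed-form comparison — chosen so that the Monte-Carlo
SE of every quantity under test is small against its tolerance band while
a full run stays interactive. Degenerate inputs are contracts, not
crashes: an empty run list yields a flagged empty spectrum; an all-one-
base sequence has a deterministic null (its only permutation is itself);
undefined ratios carry status flags. The enumeration oracle caps at 1e5
arrangements; the Fisher test uses the same 1e-7 relative tie tolerance
as `fisher.test()` so the two agree bitwise-for-practical-purposes.

## Limitations

* Real integrase sets (e.g. IntegronFinder-derived SCI/MI collections)
  are accepted as FASTA + group TSV but are not shipped; published
  effect sizes (such as a ~55-fold depletion of 8-mers in MI integrases)
  depend on those external collections and are not reproduced by the
  synthetic panels, which are calibrated for qualitative recovery only.
* The strand-balance test assumes ref reads give a fair strand baseline;
  ampliconic or strand-asymmetric protocols would violate that.
* Attribution handles single-base-multiset indels only; complex events
  (mixed-base insertions) are classified but never attributed to runs.
* Enrichment ratios at bins with small expected counts are intrinsically
  unstable (see the calibration caveat above); interpret them through
  their status flags and expected counts, not as point estimates.
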