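---
title: "Quantifying starvation-responsive miRNAs: models, parameters and design choices"
author: "mirstarve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying starvation-responsive miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mirstarve` reimplements, at desk scale, the small RNA-seq workflow used
to identify starvation-responsive miRNAs in *C. elegans* early L4
larvae: two single-end 36-cycle libraries (one well-fed, one 12-hr
starved, no biological replicates) are cleaned, collapsed, multi-mapped
against a class-labelled reference, tabulated with fractional
multi-mapper counting under a class hierarchy, and tested for
differential expression with a fixed-dispersion negative-binomial exact
test under TMM normalisation. The qPCR arithmetic used to validate
selected changes (Pfaffl efficiency-corrected ratios) is included, as is
a seeded synthetic-data generator whose ground truth lets every stage be
scored without the original sequencing data.

# The reference and the mature-extension rule

Reads are mapped in *transcript space* against a concatenated catalogue
of five classes: extended mature miRNAs, miRNA hairpins, non-coding
transcripts, coding transcripts and the genome. Mature annotations are
widened by 3 nt at the 5' end and 5 nt at the 3' end (clipped at the
hairpin boundaries) before their sequence is excised from the hairpin;
this absorbs the 1-2 nt end heterogeneity of sequenced isomiRs so they
still align end-to-end within the mature region. Coordinates are 0-based
half-open everywhere internally and 1-based closed only at the GFF3
boundary.

Hairpin features record their extended-mature intervals. A hit on a
hairpin that falls entirely inside a *single* extended-mature interval
is promoted to the corresponding mature feature; anything else on the
hairpin is a hairpin ("loop") read. Where two extended matures on one
hairpin overlap, the outside-mature region is the complement of their
union; a window contained in the union but in no single interval is a
degenerate case we keep as hairpin. Transcript-like classes are matched
sense-only; the genome is additionally searched on the reverse strand
(reads from either strand are meaningful only there). Both choices are
arguments (`rc_classes`) rather than constants.

# Read cleanup

The pipeline order is fixed: 5' hexamer trim, 3' adapter trim, length
selection, N-drop, collapsing.

* **Hexamer**: the artificial `ACATCG` prefix seen on 6-8% of reads is
  removed once, only at the 5' terminus (`max_trims` raises the limit).
  A single-pass trim is the conservative reading of an artefact that
  appears at most once per ligation.
* **Adapter**: the Illumina small-RNA 3' adapter
  `ATCTCGTATGCCGTCTTCTGCTTGC` is located by the best un-gapped alignment
  of an adapter prefix to the read's 3' portion -- minimum overlap 8 nt,
  mismatch rate at most 10%, no indels; ties go to the earliest
  (longest) alignment. Reads with no qualifying match are kept
  unchanged: the length filter is the only discard gate, since the
  cleanup criterion for this protocol is purely length-based.
* **Length**: cleaned reads of 16-28 nt inclusive are kept.
* **N bases**: reads still containing N are dropped before collapsing
  (the aligner scores substitutions only) and reported separately.
* **Collapsing**: identical sequences become one record carrying their
  total count, ordered by descending count then sequence, with
  deterministic uids; base qualities are carried by the FASTQ reader but
  never used.

Per-stage totals are returned so that raw reads always equal kept plus
discarded -- the conservation identity the tests assert.

# Alignment

Every end-to-end placement with at most 2 substitutions is reported
(bowtie `-v 2 -a`-like semantics), capped at 100 locations per read;
reads exceeding the cap keep their first 100 placements in the
deterministic order (mismatches, then feature id, then offset) and are
flagged rather than discarded, so the choice is visible downstream. The
search runs over a single N-spaced concatenation of the reference
(`Biostrings::matchPattern`, substitutions only); placements overhanging
a feature or the subject are rejected, which also makes the N spacers
inert at the 2-mismatch budget. The test suite checks the implementation
hit-for-hit against an exhaustive sliding-window oracle, including
planted-mismatch and reverse-strand cases.

# Class assignment and fractional counting

Each read is assigned to the highest-preference class present among its
hits -- mature > hairpin > ncRNA > coding > genome -- after the
hairpin-to-mature promotion above; a genome-only read is "intergenic".
Within the winning class, the read's count is divided equally across its
locations (distinct offsets on one feature are distinct locations, and a
feature's count is the sum of its shares). A read whose divided count
falls below 1 contributes nothing anywhere. The drop rule runs after
class resolution and before tabulation, so a read never splits across
classes and every per-feature contribution is either 0 or at least 1.
Counts are plain doubles rather than exact rationals; equal division by
small integers is exact in binary floating point often enough that the
conservation identity (table + ignored + unmapped = collapsed counts)
holds to 1e-9 on every fixture, which the tests assert.

Class composition (the pie-chart summary) is computed on full read
counts at the assignment stage, so the six fractions -- five classes
plus unmapped -- sum to exactly one per library. Both this and the
top-miRNA shares are reported per library.

# Differential expression without replicates

Only the mature + hairpin rows of the count table are tested, and their
column sums are the library totals used for CPM -- the matrix being
tested defines its own denominator. Features need at least 1 CPM
(inclusive) in at least one library.

* **TMM**: the classic weighted trimmed mean of M-values -- log2
  relative-proportion ratios against a reference library, double-trimmed
  (30% on M, 5% on A), precision-weighted, over features nonzero in both
  libraries, normalised to geometric mean 1. The reference library is
  the one whose upper quartile is closest to the mean upper quartile.
  The implementation is checked against both an independently coded
  textbook version and `edgeR::calcNormFactors` (agreement to 1e-9).
* **Exact test**: with a single library per condition the dispersion
  cannot be estimated, so a common dispersion of 0.1 (variance
  mu + 0.1 mu^2) is fixed by configuration. Counts are rescaled to the
  geometric mean of the two effective (TMM-adjusted) sizes and rounded
  to pseudo-counts; conditioning on the pseudo-count sum *s*, the
  two-sided p-value is the total conditional probability of splits no
  more likely than the observed one under independent NB(s/2, phi)
  margins, computed by enumeration over 0..s in log space. At phi = 0
  this is exactly the conditional binomial test, which the suite
  verifies against `binom.test` and an independent enumeration. This
  conditional-enumeration formulation is a deliberate simplification of
  edgeR's quantile-adjusted machinery: numeric equality with edgeR is
  not promised, enumeration-oracle equality and reproduction of the
  published derived columns are the contracts.
* **Fold changes**: log2FC uses a small proportional prior (0.125,
  scaled by relative library size) so zeros stay finite. The *reported*
  fold change follows the publication's convention -- the higher CPM
  divided by the lower, signed by the log2FC direction -- with an
  exactly-zero side replaced by 0.05 CPM (half the smallest displayable
  1-d.p. value) before division.
* **FDR**: Benjamini-Hochberg step-up with an explicit test count `m`
  at least the list length; `m` greater than the list models tested but
  unlisted features at p = 1. Applied to the published p-value column,
  the printed FDRs are reproduced with m = 250, the value implied (and
  verified in the tests) by printed FDR x rank / p at the low ranks --
  i.e. about 250 miRNA regions passed the CPM filter in the original
  analysis.
* The MA table carries A = mean log2 prior-cushioned CPM and M = the
  log2FC above, with the significance flag at the configured FDR.

Because the published inputs are themselves rounded (CPMs to 1 d.p.,
p-values to 2 significant figures), derived columns are compared to
within one unit of the last printed digit wherever exact re-rounding is
impossible; the signed fold-change column reproduces exactly at 1 d.p.
for all nine well-expressed rows.

# qPCR relative quantification

The efficiency-corrected ratio is E_t^dCt_t / E_r^dCt_r with
dCt = Ct(control) - Ct(treated) and E the per-cycle amplification factor
(2 = perfect doubling, the default since no measured efficiencies are
reported; overridable per assay, accepted up to 2.2 to tolerate apparent
super-efficiency). One ratio is computed per biological replicate from
its replicate-mean Cts, then summarised as mean +/- SEM with a direction
flag -- matching a triplicate design summarised as the SEM of three
independent experiments.

# What the generator emulates -- and what it does not

`paper_shaped_scenario()` mirrors the study's structure: 60 hairpins
with both arms annotated; ~90% of reads from matures; one dominant
mature near a 50% share of miRNA reads and a second near 20%; a
seven-member cluster truly upregulated 6-20x; two features truly
downregulated 8x and 13x; star (5p) arms at 2% of their 3p partner; 36-
cycle reads with adapter read-through, the hexamer on 7% of reads, and
per-feature NB counts at dispersion 0.1. Perturbed baselines are set
high enough (roughly 300-600 counts at the default 100,000 reads per
library) that a 6-20x change is detectable at desk depth -- the same
role the cluster's moderate CPMs play at 20-30M reads. Mature reads are
sampled as the *annotated mature* sequence with +/-1 nt end jitter (the
isomiR population the 3+5 extension rule is designed to absorb); the
extension itself is not a sequenced molecule, and 26-32 nt inserts would
in any case lose their adapter anchor within 36 cycles and be discarded
by the 16-28 nt filter.

Known departures from real data: uniform random reference sequence (no
genomic repeat structure, so multi-mapping is rarer than in a real
genome); uniform substitution errors with flat qualities; no ligation or
PCR bias, so class fractions track the configured mix; and NB dispersion
applied per feature per library, which makes single-draw summaries such
as the dominant miRNA's realised share fluctuate around its expectation
(~49%) with a ~32% CV on the dominant count. Passing tests therefore
demonstrate correctness of the arithmetic and the statistical machinery
under the stated model, not robustness to real-library artefacts.

Problem sizes used by the tests and the acceptance script -- 100,000
reads per library for the end-to-end scenario, 300-2,000 features for
the count-level simulations -- were chosen once as the smallest scales
at which the recovery and calibration properties are comfortably
measurable.

# Numerical and interface choices

* Ties in alignment order, collapsing order and BH mapping are broken
  lexicographically so every output is byte-stable under a fixed seed.
* The conditional distribution is normalised in log space; the
  "no more likely than observed" comparison uses a 1e-12 log tolerance
  so mirrored splits of symmetric distributions tie exactly.
* The published summary text counts 13 upregulated matures, but the
  published table's 19 rows classify (by sign and miR-/mir- naming) to
  14 up matures + 2 down matures + 1 up hairpin + 2 down hairpins; the
  text's own list omits cel-miR-359. The package reports what the table
  implies and the test suite records the discrepancy rather than hiding
  it.
* The interface is the R API plus this vignette; no shell entry point is
  shipped, as the package is an analysis library in the edgeR mold and
  each stage is a single function call.

# Limitations

Designed for exactly two libraries (the no-replicate design); replicated
designs, GLM testing and dispersion estimation are out of scope, as are
FM-index-scale genomes, gapped alignment, isomiR sub-classification,
novel-miRNA prediction and target prediction. Fold-change estimates for
features with near-zero counts depend on the prior and the zero-CPM
substitute and should be read as bounded summaries, not estimates.
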