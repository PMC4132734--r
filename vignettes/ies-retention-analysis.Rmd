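---
title: "Models and methods for IES retention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for IES retention analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesr)
```

# Scope

`iesr` implements the computational core of a genome-wide analysis of
programmed DNA elimination in ciliates such as *Paramecium tetraurelia*.
During somatic (macronuclear, MAC) genome development, tens of thousands of
short, unique, TA-bounded internal eliminated sequences (IESs) are excised
precisely from a copy of the germline (micronuclear, MIC) genome; a single
TA is retained at each junction. The package provides:

* a synthetic MAC / MAC+IES genome and read generator with known per-IES
  retention, used in place of deposited sequencing data;
* per-IES retention scores (IRS) from boundary- and junction-crossing reads;
* detection, canonical realignment and classification of TA-bounded
  excision errors ("TA-indels") against the MAC reference;
* a scanner for quasi-IESs — MAC segments flanked by perfect terminal
  inverted repeats of an IES end motif;
* sub-terminal base-frequency analytics, relative-entropy sequence logos
  with a non-uniform background, and two-sample logos;
* small-RNA (scnRNA / iesRNA) density profiles against retention scores;
* correlations between retention scores of identical and of adjacent IESs.

The package's interface is its exported functions plus the `run_all()`
pipeline driver, which chains every stage on a synthetic dataset and writes
TSV outputs with a JSON manifest.

# The retention score

For each IES, reads are classified against the two reference spaces:

* **IES+** — a read whose aligned span, in MAC+IES space, crosses an IES
  end with at least `min_anchor` aligned bases on both sides of the
  boundary point. Both ends qualify, but each read contributes at most one
  count per IES (guarding against double counting on short IESs and against
  paralogous matches).
* **IES−** — a read whose aligned span, in MAC space, crosses the excised
  junction with at least `min_anchor` bases on each side of the junction
  point; the retained junction TA lies on the right side of that point and
  must be contained in the read.

The retention score is `IRS = IES+ / (IES+ + IES−)`, so 0 means complete
excision and 1 complete retention. Counting only at ends avoids the length
bias that whole-IES read counting would introduce. IESs with no informative
reads have an undefined score and are excluded from downstream statistics
(retained in outputs with a flag).

`min_anchor` defaults to 5 aligned bases: large enough to suppress spurious
1--2 base overlaps, small enough to keep short-read sensitivity. It is
exposed as a parameter. The anchor for IES− is measured from the junction
*point* (the left edge of the retained TA) rather than from both edges of
the TA; this makes the informative window for the excised form exactly as
wide as the window for a retained boundary, which removes a small systematic
bias in IRS that the asymmetric reading would cause.

## Precision of the estimator

A read can witness a junction only by covering it, so the number of
informative reads per IES is bounded by the local read depth:
`n <= c * (1 - 2 * min_anchor / read_len)` at depth `c`. Since
`IES+ | n ~ Binomial(n, rho)` under the simulator (see below), the
population correlation between IRS and the true retention fraction
`rho ~ U(0, 1)` is `1 / sqrt(1 + 2/n)`: about 0.98 at 50x depth and about
0.99 at 100x. Users validating IRS precision on simulations should budget
coverage accordingly; no counting rule can beat the depth bound without
biasing the score.

# The synthetic data generator

The generator is first-class, tested code: its defaults *are* the
biological conditions being modelled, and every downstream module is
validated against its ground truth.

## Genomes and annotations

MAC scaffolds are i.i.d. sequence over an AT-rich background
(`A = T = 0.4`, `C = G = 0.1` by default, matching the near-neutral
composition of IES interiors). IESs are inserted at TA sites with a minimum
spacing (150 bp default) and distance from scaffold ends; excising
`[start, start + length)` from the MAC+IES scaffold reproduces the MAC
scaffold byte-for-byte, with the IES's right TA serving as the retained
junction TA. Stored IES sequences include both boundary TAs; the reported
length counts exactly one TA, so the minimum is 26 bp.

## The IES length model

Lengths are drawn from a discretised Gaussian mixture with peaks every
10 bp starting at 28 bp (twelve peaks, per-peak SD 1.5 bp, geometric weight
decay 0.6), a multiplicative depletion (factor 0.2) of the "forbidden"
38--46 bp window, and a 1% exponential tail (rate 1/400 per bp) reaching
5 kb. The peak period, modal length, forbidden window and range are fixed
landmarks of the *Paramecium* IES length distribution; the per-peak spread,
weight decay and tail law are not constrained by published summaries, so
they are explicit configuration knobs rather than inferred facts.

## End and interior composition

The three bases inward of each boundary TA follow length-stratified
probability tables: short IESs favour a `TAG`-like sub-terminus (giving the
`TATAG` terminus typical of first-peak IESs), longer ones shift toward C at
position 1 (`TACAG`-like). The right end is generated on the reverse
complement so both ends share one orientation convention. Interior bases
are i.i.d. from the `A = T = 0.4`, `C = G = 0.1` background. A configurable
number of IES sequences are copied verbatim to a second locus to support
identical-pair analyses.

## DNA-seq reads

Each fragment is anchored by a MAC-destined span `[s, s + f)`: `s` uniform,
`f` from a normal insert model floored at twice the read length (mean
250 bp, SD 30 bp, 100 nt reads by default). For every junction strictly
inside the span, the molecule retains the IES with probability `rho`
independently per fragment; retained sequence is inserted between the
anchors. Mate 1 reads forward from `s`; mate 2 reads backward from
`s + f`. Reads containing retained IES sequence are reported in MAC+IES
space (with deletion operations across any excised IESs inside the span);
purely MAC-destined reads are reported in MAC space, where excised
junctions are seamless.

This anchoring is the one design decision that is easy to get wrong: if
fragments were placed uniformly on the MAC+IES coordinate system, a
retained IES would expose *two* informative boundaries against the excised
form's *one* junction, biasing the expected IRS toward
`2 rho / (1 + rho)`. Anchoring both mates at MAC-destined coordinates gives
the retained and excised forms informative windows of identical width, so
the IES+ count among informative reads is exactly binomial in `rho` — which
is what makes exact envelope tests possible. The insert floor of `2 *
read_len` keeps the two mate windows disjoint, so informative counts are
independent across reads. A physical consequence is that a fragment's
sequenced length grows with retained content; fragment-length selection
effects are deliberately not modelled.

The base-substitution error rate defaults to 0 so that oracle tests are
exact; a uniform substitution knob exists for robustness checks. No PCR
duplicates, GC bias, quality model, or chromosome
fragmentation/telomere-addition (imprecise elimination) are simulated.

## Small RNAs

scnRNAs are fixed-length 25 nt windows placed uniformly over the MAC+IES
genome, so a fraction spans IES boundaries — their density per IES is
independent of retention. iesRNAs are 21--31 nt (mode 27 nt), lie strictly
within IES intervals (lengths that do not fit are resampled), and
accumulate toward IES ends: half of the starts are drawn within 5 nt of
either end, half uniformly. The end-accumulation tendency is known only
qualitatively, so the 50/50 split and the 5 nt window are configuration
defaults rather than measured quantities. Per-IES iesRNA counts are Poisson with mean
`scale * length * (0.25 + 0.75 * rho)`, encoding the observed positive
association between iesRNA density and retention. Note that 25 nt iesRNAs
exist (the length distribution covers 25), so a normal simulated library's
25 nt class is a scnRNA/iesRNA mixture exactly as in real control samples;
a pure scnRNA profile is obtained by simulating with `abundance_scale = 0`,
the in-silico analogue of silencing the iesRNA dicer.

## Planted excision errors

Cryptic deletions remove a TA-bounded MAC segment far from any junction;
alternative-boundary deletions start at an annotated junction TA and extend
to a nearby TA. Supporting read pairs carry the deletion with an
aligner-style *maximally left-shifted* CIGAR placement, while the recorded
truth uses canonical coordinates — exercising the realignment step under
realistic reporting ambiguity.

# TA-indel detection

Within-read deletions of 5 bp to 10 kb against the MAC reference are
extracted from CIGARs; deletions whose deleted span contains `N` are
flagged and excluded. Because a deletion's placement is ambiguous wherever
flanking sequence repeats, every shift-equivalent placement is enumerated
and the leftmost placement whose deleted segment starts with `TA` and ends
with `TA` is taken as canonical (deletions with no TA-bounded placement are
canonicalised to the leftmost equivalent placement and flagged). A stricter
"excision-form" rule — segment starts with `TA` and the two reference bases
following it are `TA`, mirroring one-TA IES excision chemistry — is
available as `mode = "excision"`; the default follows the catalogue
convention that the deleted segment itself is TA-bounded. Canonical
deletions are merged across supporting reads, classified
`alternative_boundary` when an endpoint coincides (tolerance 0, exposed)
with an annotated junction and `cryptic` otherwise, and rates are reported
as reads with TA-indels per million mapped reads. Retention of an IES
("residual" errors) is an insertion relative to MAC and is measured by the
retention module, never by the deletion scanner.

# Quasi-IES scanning

For a 5-base motif `m` starting with `TA` (e.g. `TATAG`), a quasi-IES is a
segment with `m` at its 5' end and `reverse-complement(m)` at its 3' end as
a perfect terminal inverted repeat. For motif occurrences `[i, i+5)` and
`[j-5, j)`, the one-TA length is `j - 2 - i`, so the last two bases of the
inverted motif play the role of the retained junction TA and a 26 bp
quasi-IES has the same extremities as a 26 bp IES. All occurrences,
overlapping and nested, are reported; the scan indexes motif hits rather
than all position pairs, so it is linear in genome length plus output.
Expected counts per length come either from independent-site closed form
using the genome's base composition, or from dinucleotide-preserving
shuffles (random Eulerian walk on the base-transition multigraph). The
observed/expected ratio per length window quantifies depletion of
excision-prone segments. The default length cap of 150 bp matches the range
over which the per-length profile is informative; it is configurable.

# End-base analytics

Sub-terminal positions 1--3 (inward of the TA) are tallied per group —
by length, or by retention-score bin inside a narrow (~10 bp) length
window, which removes the length/retention confound; the package's own
check is that mean IES length stays flat across score bins within such a
window. Series over ordered keys are smoothed with the standard EWMA
recursion (`alpha = 2/(span + 1)`, seeded with the first observation), and
trends are only interpreted within 2 standard deviations of the mean score,
where data are dense.

Sequence logos use relative entropy against a non-uniform background
(default `A = T = 0.4`, `C = G = 0.1`, the IES-interior composition):
column information is `sum(p * log2(p/q))` bits, clamped at zero, with
letter heights proportional to `p`. This is the only logo form that honours
a composition-biased genome; a uniform-background logo would show spurious
A/T "information" everywhere. Two-sample logos test per-position, per-base
presence indicators between two sequence groups with Welch's t-test
(pooled-variance optional), Bonferroni-corrected over positions x 4 bases;
complete separation with zero within-group variance is reported as p = 0,
and zero variance with equal means as p = 1. The t-variant and family size
are knobs because the analysis convention varies between studies.

# sRNA densities

sRNA reads are assigned in two stages: reads matching the MAC genome are
assigned there; the remainder matching the MAC+IES genome are assigned
there; reads with multiple exact matches in their assigned reference are
dropped. Densities are reads per base of one-TA IES length, with
normalisation per million mapped reads of 15--35 nt (the size range is read
as inclusive; the bound pair is configurable). A 27 nt (iesRNA-typical)
read counts toward an IES when fully contained in its interval; a 25 nt
(scnRNA-typical, boundary-spanning) read counts on any overlap — both
policies are exposed. Profiles against retention scores take the median
density per 0.01 score bin, EWMA-smoothed (span 5), trend-restricted to
2 SD around the mean score, with an optional outlier cap that excludes
extreme densities from the binned statistic but never from the per-IES
table.

# Pair correlations

Identical IESs are grouped by exact full-sequence identity; pairs whose
flanks over one read length on each side are also identical cannot be
distinguished by their IES+ reads and are excluded (and counted). Optional
filters mirror common analysis conditions: minimum scaffold length,
exclusion of zero scores, and a knockdown-score-vs-control filter
implemented verbatim as `score >= fraction * control`; since the printed
form of that filter is nearly vacuous when control scores are ~0, the
fraction and its reading are left as parameters rather than asserted.
Adjacent pairs are emitted per scaffold with a configurable number of
intervening IESs and a maximum gap; a seeded random-pair generator provides
the no-association baseline. Correlations (Pearson and Spearman, two-tailed
p) use `stats::cor.test()`.

# Numerical conventions

* Coordinates are 0-based half-open internally; GFF3 output is 1-based
  inclusive and round-trips exactly. BED output is 6+2 columns.
* Degenerate inputs: empty read sets give all-zero counts and undefined
  scores; reads shorter than `2 * min_anchor` are uninformative; empty
  series smooth to empty series; zero-variance margins give undefined
  correlations with a warning.
* Tie-break in realignment: the leftmost qualifying placement.
* All floating TSV output keeps full precision; the manifest stores file
  MD5 checksums, the seed and a config snapshot. Identical configurations
  reproduce byte-identical outputs; all randomness flows from the single
  master seed through fixed per-stage derivations.

# What the synthetic data does and does not show

Passing the suite demonstrates that every operation is correct against
ground truth and independent oracles *under the generator's assumptions*:
i.i.d. background sequence, independent per-fragment retention, exact
truth alignments, uniform substitution errors only. Real data add mapping
ambiguity from a repetitive genome, old-MAC carryover fragments,
copy-number differences between old and new MAC, library biases and
contaminants — none of which the generator emulates, and all of which sit
upstream of the statistics tested here. Test problem sizes (tens of kb of
scaffold, hundreds of IESs, 25--100x coverage) were chosen so the full
suite exercises every code path at statistically meaningful depth while
remaining quick to run; they are smaller than the real genome by two orders
of magnitude.
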