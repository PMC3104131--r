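---
title: "Methods: rare CNV detection from array CGH log2 ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV detection from array CGH log2 ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcall)
```

## The analysis problem

Whole-genome array CGH measures, for ~135,000 oligonucleotide probes tiled
roughly every 25 kb, the log2 ratio of test versus reference DNA abundance.
A diploid locus sits near 0; a heterozygous duplication (three copies)
shifts probes by about `log2(3/2) = +0.585`; a heterozygous deletion (one
copy) by `log2(1/2) = -1`. `cnvcall` turns per-probe ratios into discrete
copy-number variant (CNV) calls, separates rare from common variants using
a catalog of CNVs seen in unaffected individuals, annotates calls with gene
overlap and parental inheritance, and summarizes a case cohort with a
rare-CNV burden test.

## The calling model

**Chromosome-wise z-scores.** For each chromosome `c`, ratios are
standardized with that chromosome's own mean and sample standard deviation
(`n - 1` denominator): `z_i = (r_i - mean_c) / sd_c`. Standardizing per
chromosome makes calls invariant to chromosome-wide shifts (dye or
hybridization offsets); it also means a chromosome with no variance (for
instance, an all-constant synthetic track) has no defined z-scores and is
rejected with an explicit error rather than silently passed through. The
sample-sd convention is immaterial at the 10^3-10^5 probes per chromosome
the pipeline is designed for.

**Three-state Gaussian HMM.** Probes are classified `decreased`, `normal`
or `increased` by a hidden Markov model with Gaussian emissions on the
z-score scale. The normal state emits N(0, 1); the altered states share
the normal state's standard deviation and have means two standard
deviations below and above it (means -2 and +2; the shift is the
`emission_mean_shift` parameter). Transitions are symmetric: each state
keeps itself with probability `s = state_self_transition` and moves to
each other state with probability `(1 - s)/2`; the initial distribution is
uniform. Decoding is the Viterbi (global maximum a posteriori) path,
computed independently per chromosome — copy-number states do not continue
across a centromere-free chromosome boundary, and the z-scale is
chromosome-specific anyway. All decoding arithmetic is in log space, so
10^5-probe chromosomes decode without underflow. Exact score ties (which
arise only on contrived inputs) are resolved normal > increased >
decreased, biasing toward no-call.

**Choosing the transition prior.** The published rule set fixes the
emission geometry but not the transition probabilities, so `s` is a
genuine design parameter. It was set from a genome-wide specificity
argument: `1 - s` is the per-probe hazard of a copy-number state change,
and a human genome assayed at 25-kb resolution harbors on the order of ten
detectable CNV boundaries per 10^5 probes, i.e. a hazard near 10^-4. The
default `s = 0.9999` encodes that rate. It also controls false discovery:
under the null, a run of `k` probes flips to an altered state only when its
summed emission log-odds `sum(d*z_i - d^2/2)` (with `d = 2`) exceeds the
two-transition penalty `2*log((1-s)/(2s))` (~19.8 at the default), which
for a 5-probe run requires a mean z-score near 3 and keeps the expected
number of false segments per genome far below one — consistent with
studies of this design reporting only a handful of rare calls across
hundreds of genomes. A laxer prior (e.g. `s = 0.99`, penalty ~10.6) admits
a false >= 5-probe call on a few percent of 4,000-probe null tracks, which
would swamp a cohort-level carrier rate. Sensitivity is essentially
unaffected for the events this pipeline targets: a heterozygous
duplication at the default noise level sits near z = 4, giving ~5.7
log-odds units per probe, so even 5-probe events clear the threshold with
a wide margin.

**From states to segments.** Consecutive probes of the same non-normal
state form a segment, but a run is split wherever two adjacent probes are
50 kb or more apart (`merge_gap_bp`; the rule is strict "less than 50 kb
are merged"). Two same-state segments with no other segment between them
are then bridged into a single variant — together with the intervening
probes — when the intervening sequence has at most 5 probes
(`bridge_max_probes`) and the gap between the segments' facing boundaries
spans at most 10 kb (`bridge_max_bp`). Bridging repeats to a fixed point,
each individual bridge satisfying both conditions on its own; chained
bridging is not otherwise specified by the rule set, and the fixed-point
reading is the conservative one that never bridges across a wider gap than
10 kb in a single step. Note that at a uniform 25-kb spacing the bridge
rule is nearly inert (any intervening probe implies a span above 10 kb);
it matters on platforms or regions with denser tiling. Segment
coordinates are the outermost probe positions of the run, half-open
(`end` = last probe + 1), so a single-probe segment is non-degenerate; the
reported size is `(end - start) / 1e6` Mb.

**Filters.** Calls with fewer than `min_probes = 5` probes are discarded.
A call is *common* — and removed — when a control-catalog interval of the
same type (gain/loss) overlaps it with reciprocal overlap at least
`common_overlap_fraction = 0.5`; reciprocal overlap,
`min(w/len_call, w/len_catalog)` for intersection width `w`, is the
field-standard CNV matching criterion, and the published rule set names no
specific one. Surviving calls are flagged rare.

**Annotation and inheritance.** A call is *gene-containing* when it fully
contains or partially overlaps at least one gene interval; both lists are
reported (report tables mark full containment "++" and partial overlap
"+", following the convention of published rare-CNV tables), and the
carrier statistic counts either kind, matching the way partially
overlapped genes are listed in such tables. Inheritance uses the same
overlap engine and threshold as the common filter: a child call matched by
a same-type parental call is `inherited_<parent>`, an unmatched call is
`not_in_tested_parent`, and with no parent data the verdict is `unknown`.
One overlap semantics across the package keeps the two classifications
consistent by construction.

**Burden statistics.** The cohort summary reports the percentage of
samples carrying at least one rare gene-containing call (one decimal), and
for each size threshold compares the number of case samples with a rare
event *strictly* above the threshold against a supplied control count via
Fisher's exact test. The two-sided p-value uses the probability-mass
definition — the sum of hypergeometric probabilities of all tables (fixed
margins) no more probable than the observed one, with a 1e-7 relative
tolerance at the boundary — i.e. the convention of standard statistical
software; on the canonical 2x2 table (3/183 cases vs 8/2485 controls) it
yields P = 0.036. Control calls themselves are not recomputed: published
control carrier counts enter as integers. A table with a zero margin is
uninformative and returns p = 1 with a warning.

## The synthetic-data generator

`sim_spec()`/`simulate_track()` emulate the tiling platform: probes on a
jittered grid (25-kb spacing, +/-2-kb uniform jitter), baseline log2 ratio
0, i.i.d. Gaussian probe noise with sd 0.15 log2 units, and implanted
CNVs shifted by ideal copy-number arithmetic `log2(CN/2)`. The noise
default makes the +/-2-sd emission means roughly coincide with the
heterozygous-deletion shift, so 5-8-probe events are detectable but not
trivial. `cohort_spec()`/`simulate_cohort()` build a case cohort on a
desk-scale genome of three 50-Mb chromosomes: a synthetic gene map (5
genes/Mb, 20-100-kb genes), a set of 8 common CNV loci (10-25 probes
each) that forms the control catalog and segregates through all samples at
carrier fraction 0.3, and one rare gene-overlapping implant (8-60 probes,
duplication or deletion with equal probability) in each of a chosen number
of carrier samples, placed clear of every catalog locus. Everything is
deterministic given the spec seed.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real arrays: dye bias and GC/wave artifacts,
intensity compression (real shifts undershoot `log2(CN/2)`),
segmental-duplication cross-hybridization, correlated probe noise, sex
chromosomes, and mosaicism. The generator validates the pipeline's logic
and statistics, not platform chemistry.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere internally (BED
  convention); report tables display Mb to two decimals, converted only at
  write time.
- Chromosome names are accepted with or without the "chr" prefix and
  normalized to the prefixed form.
- Degenerate inputs fail loudly with typed errors: zero-variance or
  single-probe chromosomes, non-finite ratios, duplicate probe positions,
  inverted intervals, invalid configurations.
- Viterbi is implemented in C++ (Rcpp) for cohort-scale throughput;
  interval overlap runs on GenomicRanges/IRanges.
- Published call tables occasionally print sizes inconsistent with their
  own coordinates; the reporting layer always derives size from
  coordinates and never reconciles such rows.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
decoding against exhaustive enumeration of all 3^n state paths on tracks
of up to 12 probes; Fisher's p-values against direct binomial-coefficient
enumeration (and base R's implementation); gene and rarity overlap against
interval arithmetic constructed by hand; and the end-to-end pipeline
against simulated ground truth. Cohort-scale checks run 20 replicates of
a 186-sample cohort with 14 implanted rare carriers (~6,000 probes per
sample), sizes chosen to exercise the full design at workstation scale;
recovery checks use 200 replicates of 4,000-probe tracks with one
8-probe implant.

## Known limitations

- **Boundary wobble is intrinsic to the emission geometry.** Moving a
  segment boundary does not change the number of transitions, so the MAP
  path absorbs `m` flanking normal probes whenever their summed emission
  log-odds is positive, i.e. their mean z-score exceeds `d/2 = 1`. For
  standard-normal flanking probes that happens with probability ~0.16 for
  one probe and ~0.07 for an excursion of two or more, per boundary — the
  transition prior cannot change this, only the (fixed) emission shift
  can. Consequently calls are expected to overshoot the implanted
  boundaries by >= 2 probes on at least one side in roughly 12% of events;
  the test suite measures both-boundaries-within-one-probe recovery at
  about 88%, in line with this analysis. Boundary-critical applications
  should refine edges with a denser platform, as the original study design
  did for validation.
- Detection requires the z-scale shift to clear the decoding threshold;
  with noise sd much above ~0.2 log2 units, 5-probe heterozygous
  duplications start to be missed.
- The common filter is interval-based; it cannot distinguish a rare CNV
  nested inside a common one with high reciprocal overlap.
- No GC/wave correction, no mosaicism model, no sex-chromosome baseline
  adjustment, no multi-sample joint segmentation.
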