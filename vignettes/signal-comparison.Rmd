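---
title: "Move-table signal extraction and condition comparison: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Move-table signal extraction and condition comparison: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nanotrace extracts per-base nanopore current segments by composing two
alignments that modern sequencing pipelines already produce — the
basecaller's move table (signal → read) and a conventional aligner's
CIGAR/MD record (read → reference) — and compares experimental conditions
through per-position statistics, kernel density estimates, UMAP embeddings
and Gaussian mixture clustering. This vignette is the package's account of
the underlying model, its conventions, and the design decisions taken where
the problem left genuine choices.

## The signal-to-reference composition

**Move table.** The `mv` tag is a stride `s` followed by a binary vector
with one entry per block of `s` raw samples after trimming `ts` samples
from the signal start; a 1 marks the block where a new base was emitted.
With `b_i` the block index of the i-th 1, base i (in basecall order,
i.e. signal-time order) occupies the half-open sample interval

    [ts + s*b_i,  ts + s*b_{i+1})        (ns for the last base)

inside the read's `ns`-sample signal window. These segments are contiguous,
non-overlapping, and partition `[ts, ns)`; every segment length is a
multiple of `s` except possibly the last, which is *truncated at* `ns`
rather than extended past it when `ns − ts` is not a multiple of the
stride. Malformed tags (first move 0, no 1s, `ts ≥ ns`) are hard errors:
they indicate corrupted inputs, not conditions to repair.

**Orientation.** Two independent index flips relate basecall order to the
query string stored in the BAM:

* *strand*: reverse-strand records store the reverse complement, so query
  position `q` is basecall index `L−1−q`;
* *molecule*: direct RNA passes the pore 3'→5' while the basecalled
  sequence is reported 5'→3', so the i-th emitted base is sequence index
  `L−1−i`.

Applying both flips cancels to the identity. This is the single most
error-prone convention in the ecosystem, so it is isolated in one function
(`orient_segments()`) and checked exhaustively for all read lengths up to
20 in the tests, plus end-to-end on mixed-strand and RNA fixtures.

**Split reads.** Reads split from a parent signal carry `pi` (parent id)
and `sp` (sample offset); their move-table coordinates apply to the parent
slice `[sp, sp + ns)`. The format does not state `sp`'s reference point
beyond the parent signal origin; that convention is assumed and is the only
one the fixtures exercise.

**Reference composition.** The CIGAR walk pairs query and reference
coordinates at aligned columns; the MD tag reconstructs the reference base
at every aligned or deleted column, so no FASTA is needed. Insertions
advance the query only, deletions the reference only; soft-clipped bases
keep their signal segments but receive no reference position. Hard clips
are rejected outright — the clipped bases' signal cannot be reconstructed —
as are exotic ops (P, B). MD/CIGAR inconsistency is an error, never a
guess.

## Window extraction and filters

A window is an odd number K of reference positions centered on the position
of interest. A read contributes only if every window position is aligned in
it ("incomplete span" otherwise) — the per-read output must be rectangular
for trace plots and feature vectors. Optional filters mirror standard
practice: `exclude_reads_with_indels` drops reads with any insertion or
deletion inside the window; `matched_query_base` drops reads whose query
differs from the reference at any window position (deliberately
whole-window, i.e. stricter than a center-only match — documented because
the looser reading is also defensible). A read whose alignment *deletes* a
window position can never supply a segment there; such reads are excluded
with their own reason code (`deletion_in_window`) independent of the indel
flag, because an empty segment would break every downstream statistic.
Exclusions are reason-counted, and survivors plus exclusions always equal
the fetched total — an invariant the tests enforce.

Normalizers (e.g. z-scoring) are applied to the *whole* calibrated read
signal before slicing, so they see the read's full dynamic range rather
than a window-local snippet, and must preserve the sample count.

Zero surviving reads is a well-formed result with populated exclusion
counts, not an error; a window falling off the reference is an error before
any I/O.

## Statistics conventions

Segments are treated as complete signal populations for their base, so
`std` is the population standard deviation (divide by n). Skewness is the
Fisher–Pearson moment coefficient `g1 = m3/m2^{3/2}` and kurtosis is
*excess* kurtosis `g2 = m4/m2² − 3` (normal → 0; the bare word "kurtosis"
is ambiguous and this is the convention chosen). Zero-variance and
single-sample segments yield `std = 0` and skewness/kurtosis 0 by
convention rather than NaN. Duration (dwell) is reported in samples by
default — the unit the move table natively provides — with millisecond
conversion via the per-read sample rate as an option.

KDEs use a Gaussian kernel with Scott's-rule bandwidth `sd(x)·n^{−1/5}` and
a grid spanning `[min − 3bw, max + 3bw]`, so the trapezoidal integral of
the density is ≈ 1 (the tests require [0.98, 1.02]). A distribution with
fewer than two distinct values has no usable KDE; the error advises the
histogram instead, and the panel plots fall back to one automatically with
a warning. Histograms use equal-width, right-closed bins spanning
[min, max], so counts always sum to n.

## Population models

**Feature vectors.** Each read is summarized by the chosen statistics at
each offset of a positional window (statistics outer, offsets inner), a
(reads × statistics·offsets) matrix with condition labels carried along.

**UMAP.** One model is always fit on the pooled rows of all conditions —
labels cannot influence the fit, which the tests verify by relabeling.
Columns are z-scored (pooled) first, since UMAP's metric is
scale-sensitive; defaults are `n_neighbors = 15`, `min_dist = 0.1`, the
library defaults, as no domain-specific values are established. The
numerical embedding is delegated to the umap-learn library through a small
`python` subprocess with an explicit `random_state`, making results exactly
reproducible for a fixed seed and input.

**Gaussian mixtures.** Clustering operates in a bivariate space: two
statistics, each averaged across the offset window
(`aggregate_features()`). The fit is full-covariance EM (model "VVV" via
mclust, whose hierarchical-clustering initialization is deterministic; the
seed is recorded with the fit for provenance). The mixture is fit to the
*pooled* conditions, each read assigned to its maximum-responsibility
component, and the per-condition assignment distribution tabulated —
condition-specific subpopulations then show up as skewed assignment rows.
Per-condition fits are available for model-to-model comparison. Duplicated
degenerate points make the covariance singular; the error says so and
advises jitter or fewer components. Scale is deliberately *not* normalized
before the GMM — the covariances absorb it.

**Comparison.** Kolmogorov–Smirnov tests are two-sample per feature between
two conditions (cluster-wise comparison is available by subsetting on
assignments). Jensen–Shannon divergence between fitted mixtures has no
closed form, so it is estimated by Monte Carlo with an explicit seed and
sample count (default 10⁴; fewer than 100 is refused):

    JS = ½ E_a[log2 p_a/p_m] + ½ E_b[log2 p_b/p_m],   p_m = (p_a + p_b)/2

computed entirely in log space to survive far-separated models. Base 2
bounds divergence and distance (its square root) in [0, 1]; the base is a
package decision, made so that "identical" and "disjoint" map to 0 and 1.
The tests calibrate the estimator against a dense-grid quadrature oracle
(agreement within 0.02 at 10⁴ samples) and check symmetry and bounds on
random model pairs.

## Plot geometry

Each window position n occupies the unit x-interval [n, n+1); a base with
k samples is drawn at the left-aligned, evenly spaced coordinates
`x_j = n + j/k`. Left alignment is a choice — "evenly spaced between n and
n+1" does not fix endpoint handling — made so that concatenated segments
remain continuous across base boundaries. Amplitudes are never resampled or
smoothed. Consecutive samples are connected across base boundaries by
default (one continuous trace per read; switchable). The automatic
transparency rule is `alpha = 10/n_reads` clamped to [0.05, 1] — invented
plumbing for "adjusted based on read count", chosen so ~10 reads are fully
opaque and dense overlays stay readable. Vector (SVG) output is
byte-reproducible for identical input, which the tests assert.

## The synthetic generator: what it emulates and what it does not

`write_fixture_pair()` writes exactly the inputs the extraction contract
requires: per-read raw integer signals with calibration (directories of
Parquet files with the standard read-table schema — read id, signal,
calibration offset/scale, sample rate), and coordinate-sorted, indexed BAMs
carrying `mv`/`ts`/`ns`/`MD` (plus `pi`/`sp` on designated split reads),
with correct CIGAR/MD for injected mismatches, insertions and deletions,
and a truth manifest recording every generating parameter.

The signal model is deliberately minimal:

* per-base current level = a deterministic hash of the 5-mer context into
  [70, 130] pA; noise is Gaussian with sd 2.5 pA; stride 6; dwell is
  1 + Geometric(0.55) blocks (mean ≈ 2.2 blocks ≈ 13 samples); sampling
  rate 4 kHz; calibration offset 10, scale 0.25 pA/DAC. These values are
  fixed, recorded in the manifest, and make no claim of biophysical
  realism — they are chosen so that segment means are estimable from
  realistic dwells and a +8 pA condition shift (a typical order for a
  strongly signal-perturbing modification) is clearly but not trivially
  separable from noise.
* levels are keyed to the *reference-forward* k-mer at each reference
  position, not the molecule-orientation k-mer. Real pores see the
  traversing strand, so this is non-physical — but it makes forward- and
  reverse-strand simulations of one locus estimate the same level table,
  turning strand-handling correctness into an exactly testable property.
* modification effects are pure level shifts at designated positions; no
  dwell effects, no basecall-error model beyond injected edits, no quality
  strings, no realistic pore physics.

Passing tests on these fixtures therefore demonstrate that the
*bookkeeping* — indexing, calibration, segmentation, orientation,
coordinate composition, filtering, statistics, clustering — is correct,
and that injected effects of known size are recovered at the expected
precision. They do not validate detection power on real chemistry, where
modification signatures span neighboring k-mers, perturb dwell, and
co-occur with basecall errors.

Standard study conditions used throughout the tests and the acceptance
script: 2 conditions × 50 reads (20 in the faster unit tests), one 300 bp
reference, reads spanning ≥ 12 bases around the target, K = 13, +8 pA at
the center position. Statistical calibrations use 1000 random move tables,
20 mixture-recovery replicates of n = 2000, 200 KS replicates of n = 500 a
side, and 10⁴ Monte-Carlo samples for JS — sizes at which every check is
both sharp and quick to rerun.

## Numerical and boundary conventions

* All internal coordinates are 0-based, half-open; sample intervals are
  half-open; the window is inclusive on base positions. The CLI accepts
  1-based positions (what genome browsers display) and converts once at
  the boundary.
* `max_reads` truncates in BAM iteration order (deterministic for a given
  file), not by random subsampling.
* Reads missing required tags are skipped with a warning and counted —
  real basecaller BAMs mix tagged and untagged records — rather than
  failing the whole fetch.
* One user seed fans out to per-stage seeds through a fixed derivation
  (`stage_seed()`), so simulation, UMAP, GMM and Monte-Carlo stages are
  individually reproducible; derived seeds stay within 32-bit range.

## Known limitations

* The native POD5 container is not read directly; raw signals are consumed
  from the package's Parquet signal store, which carries the same read
  table (id, signal, calibration, sample rate). Converting a POD5
  directory to this layout is a few lines with the format's Python
  bindings, but is outside this package.
* UMAP requires a `python` interpreter with umap-learn at run time; all
  other functionality is pure R.
* Reads with a deletion at a window position are excluded from extraction
  rather than drawn with a gap; trace plots therefore show only
  full-coverage reads.
* The KS module tests marginal features one at a time and applies no
  multiple-testing correction — it is an exploration aid, not an
  inference procedure.
* Dwell-based statistics inherit move-table granularity (multiples of the
  stride, last block truncated); they are coarser than event-level
  resquiggling would give.
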