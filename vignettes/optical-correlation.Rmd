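---
title: "Sequence alignment as optical image correlation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence alignment as optical image correlation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opticorr)
```

## The model

`opticorr` recasts DNA database search as template matching between
images. A nucleotide sequence is coded one base per pixel into a
grayscale raster: the database becomes a series of fixed-size *scenes*
(default 100 × 100 pixels, 10,000 bases), the query a smaller *object*
image. A digitally simulated Vander-Lugt correlator then asks, scene by
scene, "is the object in this scene, and where?":

1. both images are transformed with the 2-D FFT;
2. the scene spectrum is multiplied elementwise by the object's
   **phase-only filter** `H = conj(G)/|G|`;
3. the product is inverse-transformed, and the magnitude of the result is
   the correlation plane;
4. the plane's global maximum (the *peak*) is compared with a threshold:
   above means present, and the peak pixel `(r, c)` maps to the database
   start `offset + r·width + c`.

The phase-only filter, rather than the classical matched filter
`conj(G)`, is used because it whitens the object spectrum: correlation
peaks are much sharper, and — in the physical optical implementation this
simulation mirrors — it maximizes luminous efficiency at the correlation
plane. The package keeps the classical filter available (`cmf()`) because
correlation with it equals plain spatial circular cross-correlation, which
is the independent oracle the test suite checks the FFT path against.

### Assumptions

* **Forward strand, substitutions only.** There is no reverse-complement
  search, and the divergence model is substitution-only (no indels): a
  single mismatch shifts nothing, so correlation peaks stay put, which is
  exactly the regime where plain (non-elastic) correlation is informative.
* **Circular correlation.** The FFT product implements wraparound
  correlation with no extra zero-padding. Matches that would straddle a
  scene boundary are handled by tiling the database with an overlap at
  least the query length, not by linear-correlation padding.
* **Global decision variable.** Peak magnitude is compared across queries
  of very different lengths against a single threshold. Peak height grows
  with query length and information content, so a single threshold is a
  genuine modelling choice (see *Limitations*).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| gray mapping | A=0, C=85, G=170, T=255 | the unique equispaced 4-level partition of \[0, 255\], in alphabetical base order; an `"ascii"` preset (A=65, C=67, G=71, T=84) codes bases by their ASCII bytes; any distinct 4-level map is accepted |
| scene size | 100 × 100 px | 10,000 bases per scene; free parameters — the package behaves the same at, e.g., 1000 × 1000 (one scene per 1 Mbp), as one acceptance property checks |
| pad value | 0 (black) | object tail padding and final-scene padding; the POF's magnitude normalization damps the DC consequence of this choice |
| overlap | query length (search); 0 (benchmark) | searching uses overlap ≥ query length so no occurrence spans a boundary unseen; the benchmark uses disjoint scenes with queries drawn inside single scenes so each query has exactly one positive scene |
| threshold | `"auto"` | calibrated on labelled clean-run peaks by maximizing exactitude, ties toward higher specificity then the higher threshold; always recalibrate — absolute peak values depend on the FFT scaling convention |
| noise levels | 0–0.6 by 0.1 | substitution fractions of the mutated query sets; `round(rate × length)` distinct loci, substitute drawn from the other three bases |
| ambiguity policy | `"strict"` | non-ACGT symbols error by default; `"mask"` replaces them with the pad value |

## The synthetic benchmark

`build_benchmark()` / `run_correlation_benchmark()` emulate a complete
study: a 1 Mbp database, 100 scenes, 303 queries of 50–4,500 bp per noise
level, seven noise levels (2,121 query records), ~30,300 (query, scene)
decisions per level. Two design points deserve explanation:

* **Database = i.i.d. uniform ACGT.** The generator draws every base
  independently with probability 1/4. This preserves the things the
  method's mechanics depend on — alphabet, pixel dynamics, peak formation,
  the length–intensity relation, threshold separability — and makes every
  query's ground truth exact by construction. It does **not** emulate real
  genomic structure: GC skew, repeats, low-complexity tracts and
  long-range correlation are all absent. Background peaks on a real genome
  are heavier-tailed (repeats resemble queries), and positive peaks scale
  differently (see *Limitations*). An optional FASTA path in the CLI lets
  users rerun everything on a real genome.
* **Queries inside single scenes.** Benchmark queries are drawn wholly
  inside one scene-sized block, so with disjoint scenes each query is
  present in exactly one of 100 scenes (one positive versus 99 negative
  decisions per query). This is what makes sensitivity and specificity
  cleanly defined per (query, scene) pair. The search *tool* does not make
  this assumption — it tiles with overlap and deduplicates double hits in
  overlap regions by estimated start, keeping the higher peak.

### What a passing benchmark does and does not show

Passing at 0% noise shows the codec–correlator–calibration chain separates
true embeddings from uniform background almost perfectly at all query
lengths ≥ 50 bp. It does not show robustness to genomic repeats, indels,
or strand issues — none of which the generator produces.

A specific, load-bearing divergence from behavior reported on real data:
under forced substitution at rate *m*, the expected pixel correlation
between a query and its mutated copy is `1 − 4m/3` (independent of the
gray mapping), so at 60% mutation a fifth of the clean peak survives. On
an i.i.d. database the clean positive peak grows like √(query length)
without saturating, so long mutated queries can remain above a threshold
calibrated at 0% noise: sensitivity at 60% mutation is substantial
(≈ 50% at full scale) rather than collapsing to zero as observed on real
genomic data, where the positive-peak distribution is narrower (the
peak–length relation saturates). The package reports what the synthetic
conditions actually produce; the 60%-collapse behavior should be expected
only with realistic database structure.

## Numerical choices

* **FFT convention:** unnormalized forward transform; inverse divided by
  `W·H`. Under this convention correlation with the classical matched
  filter reproduces raw spatial correlation sums exactly, and all peak
  values and thresholds in this package are on that scale. Absolute
  thresholds are not portable across conventions, which is why
  calibration is built in rather than a constant.
* **Peak ties** break lexicographically — smallest row, then smallest
  column — so the pipeline is deterministic and bit-for-bit reproducible
  under a fixed seed.
* **Threshold candidates** are the midpoints between consecutive distinct
  sorted peak intensities plus ±∞; the exactitude-optimal candidate is
  found by cumulative counting (O(n log n)), and the test suite checks it
  against an exhaustive scan.
* **Zero spectra:** filter entries where `|G| = 0` are set to zero (an
  all-zero object yields a flagged all-zero filter, never NaN). Note that
  with the default mapping a poly-A object is all-zero — A codes to black,
  the same level as the padding.
* **Degenerate inputs:** empty sequences, out-of-alphabet symbols under
  the strict policy, objects larger than the frame, overlap ≥ scene
  capacity, and single-class calibration input all raise immediate errors
  naming the offending position or record.

## The one-row localization shift

Row-major coding makes a one-pixel vertical displacement equal exactly
`width` bases, and it creates a characteristic artifact: an object
starting at column `c` of a row is split by the raster wrap between 2-D
circular shifts `(r, c)` and `(r + 1, c)`. The correlation peak lands on
the alignment holding more pixels, so when the wrapped part dominates —
start column in the right half of the row, for objects long enough to
wrap — the estimated start is exactly one row (100 bases at default
width) past the truth. `detect()` flags this condition from the observed
peak column and the object length (`wrapped pixels > length/2`), and an
optional `shift_correct` mode subtracts one row when flagged; it is off
by default so that reported positions stay raw measurements. Localization
reports therefore classify hits as exact / one-row-shift / wrong, and the
one-row class is an artifact of the coding geometry, not a near-miss of
the correlator.

## Design choices that were genuinely open

* **Base-to-level assignment.** Only "four equispaced levels in
  \[0, 255\]" pins the codification; which base receives which level is
  free. Alphabetical order was fixed as the default and the mapping left
  configurable; on an i.i.d. database all assignments are statistically
  equivalent.
* **`round` versus `floor`** for the mutated-locus count: `round` chosen;
  the worked 10%-of-60-bases = 6 example is consistent with both.
* **Forced-change substitution.** A mutated locus never redraws its
  original base (a `lenient` option exists for sensitivity analyses where
  substitutes are drawn from all four bases, making the effective
  mismatch rate 0.75 × rate).
* **Calibration scope.** The threshold is calibrated once, on the clean
  run, and held fixed across noise levels — the single-threshold protocol
  the benchmark is designed around; per-level recalibration would
  conflate detector and threshold drift.
* **Coordinates** are 0-based with half-open intervals throughout, making
  the raster identity `base = row·width + col` exact.

## Problem sizes used in the test suite

Module tests run on reduced instances (10–30 scenes, tens of queries,
8 × 8 oracles) chosen so each property is still exercised across its
regimes; the acceptance tests run one full-scale replication — 1 Mbp,
100 scenes, 303 queries per level, all seven noise levels, ~212,000
correlations — which completes in a few minutes on one CPU; the
standalone acceptance script runs the two noise levels it reports
(0% and 60%) in well under a minute.

## Known limitations

* No indels, rearrangements or realistic evolutionary models; no
  reverse-complement or protein/RNA alphabets.
* Single global threshold across query lengths: the shortest queries
  (~50 bp) peak inside the background distribution and are genuinely
  undetectable at any threshold that preserves specificity — the few
  misses in a clean full-scale run are always the shortest queries.
* The i.i.d. synthetic database understates false positives and
  overstates heavy-mutation sensitivity relative to real genomes (see
  above).
* The simulation is digital throughout; nothing here models the physical
  optics (lenses, modulators, camera capture) of a hardware correlator.
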