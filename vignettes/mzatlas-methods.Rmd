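---
title: "mzatlas: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mzatlas: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzatlas)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The data model: nine attributes per point

Modern high-resolution instruments centroid their spectra on acquisition:
each detected mass peak is reduced to a single (m/z, intensity) pair, and
low-intensity signals are removed vendor-side. `mzatlas` therefore treats a
run as a cloud of **raw points**, each carrying nine attributes — m/z,
retention time, intensity, ms-level, polarity, precursor m/z, precursor
intensity, collision energy and file id. The three precursor attributes
exist only for fragmentation spectra (ms-level > 1); for MS1 points they
are `NA`, never `0`, so a genuine zero can never be mistaken for "absent".
Profile-mode spectra are rejected with the offending spectrum index rather
than silently centroided: centroiding is an instrument-calibrated step this
package should not improvise.

Retention time is normalized to **minutes** on ingest regardless of the
file's native unit (the unit found in the file is kept in the run
metadata). Minutes are the unit practitioners quote bounds in ("elutes at
9.4 min"), and using one unit everywhere removes a whole class of
silent 60× errors.

## The two-step query

Every data access is the same two-step plan:

1. **Slice**: select raw points by ranges — closed intervals `[min, max]`
   on the numeric axes, equality on ms-level/polarity, membership on file
   id. Closed intervals were chosen because the query surface exposes
   min/max pairs with no exclusivity convention; making both ends inclusive
   means a user who types the exact m/z of an observed centroid will get
   it back.
2. **Histogram**: partition the binning domain into `nsteps` equal bins,
   half-open `[lo, hi)` with the final bin closed (so a point exactly at
   the domain maximum is kept, and a point on an interior edge lands in
   exactly one bin). Per-bin aggregation is **sum** — the natural
   chromatogram/spectrum semantics, where binning at coarser resolution
   merges counts — with max available behind an option. Within a bin,
   points are added in ascending (rt, m/z) order so floating-point totals
   are reproducible run to run; with integer-valued intensities (detector
   counts) bin totals conserve the sliced total exactly.

Bin **centers** are reported rather than edges: a chromatogram is consumed
as a sampled curve (plotting, fitting, integration), and the center is the
unbiased abscissa for a bin's content.

Precursor-axis ranges are accepted in queries and filter exactly like the
other axes, but the extraction pipeline itself is MS1-only; MS2-indexed
queries are deliberately out of scope.

## Atlases and their update semantics

A compound entry has a typed core — `name`, `mz`, `mz_tolerance_ppm`,
`rt_min`, `rt_peak`, `rt_max`, optional `polarity` — because extraction
needs exactly those fields, and arbitrary free-form fields beyond them,
because annotation metadata is open-ended. The tolerance is expressed in
**ppm** (default 20 in examples) since instrument mass accuracy scales with
m/z; an absolute Thomson override (`mz_tolerance_da`) is honoured per entry
when chromatography or charge-state quirks call for a fixed window.

Updates follow document-store conventions: PUT is full replacement (fields
absent from the payload are gone afterwards — tested against randomized
payloads), PATCH is merge-then-delete (`removed_fields`), and both are
atomic: a payload that would violate `rt_min ≤ rt_peak ≤ rt_max`, a
non-positive m/z or tolerance, or removal of a required field leaves the
stored state untouched. Retention-time refinement is routine enough to get
its own audited operation, `adjust_rt_bounds()`, which appends a
timestamped before/after record even when the values are unchanged — an
adjustment that confirms the current bounds is still a review event worth
recording.

Dictionaries replace only their **membership list** on PUT; member entries
are never deleted by dictionary operations, so a compound dropped from one
atlas remains retrievable and usable by others.

## Extraction and quadrature

A compound's query window is `mz·(1 ± ppm·10⁻⁶)` by `[rt_min, rt_max]`,
MS1 only. When the entry carries a polarity the query filters on it;
otherwise both polarities are combined — on mixed-polarity acquisitions
this changes areas, so entries for alternating-mode methods should set
their polarity explicitly.

**Bin count.** The binned XIC is a faithful sampled curve only when bins
and scans correspond roughly one-to-one. Bins finer than the scan spacing
leave empty bins between scans and bias trapezoidal integrals low (at two
bins per scan the integral halves); coarser bins stack multiple scans per
bin and bias them high. `extract_xic()` therefore defaults `nsteps` to the
window width divided by the store's **median MS1 scan spacing** — one bin
per scan. At the acquisition rates the simulator emulates (0.005-min scans,
σ = 0.1-min peaks, ±3σ windows) this yields 120 bins per window; windows
narrower than ~100 scans are better widened than upsampled.

**Integration.** `integrate_peak()` applies the trapezoidal rule to the
bin centers inside the window, plus a half-bin rectangular extension at
each end so the quadrature spans the full window: a constant signal `h`
over a window of width `w` integrates to exactly `h·w`, and for a
well-contained Gaussian the end corrections vanish. Areas are in
counts·minutes. Intensities are non-negative, so enlarging a window can
never decrease an area — a property the tests exercise directly.

**Peak fitting.** `fit_peak()` fits `b + A·exp(−(t−μ)²/(2σ²))` by
Levenberg–Marquardt least squares (via `minpack.lm`), initialized from
moments (μ = intensity-weighted mean, σ = weighted SD, A = max − min,
b = min) with bounds `A, b ≥ 0`, `μ` inside the domain, `σ > 0`. Inputs
that cannot support a fit — fewer than 5 non-zero bins, a flat trace, or a
solver failure — return `converged = FALSE` rather than raising: in a
compounds × files sweep, an unfittable cell is data, not an exception.

**Missing values.** Cells with no signal in the window are recorded as
**0 with a below-detection flag** rather than `NA`, keeping the matrix
rectangular for clustering and testing; peak-shape-based imputation of
low-intensity signals is an explicit non-goal.

## Downstream statistics

`group_test()` runs Welch's two-sample t-test per compound with
Benjamini–Hochberg adjustment across compounds — the minimal defensible
default for a two-group targeted panel; both the test and the adjustment
are standard `stats` routines. Degenerate-variance convention: if both
groups are constant, `p = 1` when the means agree and `p = 0` when they do
not (perfect separation); the statistic is `NA` either way. Zero/flagged
cells are kept as zeros by default — down-weighting or excluding them is a
modelling decision the caller should make explicitly via
`normalize_table()` or subsetting.

`cluster_features()` delegates to `stats::dist`/`stats::hclust` (Euclidean
or 1 − Pearson distances; average, complete or Ward.D2 linkage). For
tie-free dissimilarities the result is independent of input row order;
exact distance ties are resolved by `hclust`'s deterministic (but
order-sensitive) policy, which matters only for pathological inputs such
as exactly duplicated profiles. Constant rows under the correlation metric
are an error naming the offending row, not a silent `NA`.

## The simulator: what it emulates, and what it does not

`simulate_run()` generates scans every `scan_interval` minutes across
`rt_span`; each compound contributes one centroid per scan at
`mz·(1 + ε)`, `ε ~ N(0, jitter_ppm·10⁻⁶)`, with intensity
`A·fold·exp(−(t−μ)²/(2σ²))` times **unit-mean** log-normal noise
(`sdlog = √log(1 + cv²)`, `meanlog = −sdlog²/2` — unit mean so expected
areas are unbiased). Uniform background centroids emulate chemical noise,
and a detection floor (default 1 count) emulates vendor-side removal of
low-intensity signals. Ground truth is the analytic Gaussian area
`A·fold·σ·√(2π)`. All randomness derives from `(seed, file_index)`, so a
run is exactly reproducible, and the generator restores the caller's RNG
state.

Defaults describe a plausible desk-scale acquisition: a 10-min gradient at
0.005-min scans (~3.3 Hz), 6-second peaks (σ = 0.1 min), 5 ppm mass
jitter, 10% intensity noise, 10 background centroids per scan.
`simulate_experiment()` writes each run to mzML and emits a matching atlas
with RT bounds μ ± 3σ and a ppm tolerance of `max(3·jitter, 5)` — windows
that bracket 99.7% of each peak's signal, so recovered areas sit ~0.5%
below the analytic truth before noise.

What the simulator does **not** model — and what passing tests therefore do
not demonstrate about real data: isotope patterns and adduct series,
retention-time drift between runs, peak tailing (exponentially modified
Gaussians), detector saturation, ion suppression, and MS2 spectra. The
pipeline's correctness claims are about storage, querying, windowing,
quadrature and bookkeeping; chromatographic pathology is upstream of them.

## Numerical conventions and problem sizes

* Intensity sums are ordered (rt, m/z ascending) before accumulation;
  conservation checks in the randomized suites use integer-valued
  intensities, for which sums are exact in double precision under any
  grouping.
* mzML is written as 64-bit uncompressed little-endian arrays with
  retention times in minutes at full precision (`%.17g`); round trips
  preserve the point multiset to machine precision (the read path tolerates
  zlib compression and 32-bit arrays produced elsewhere).
* The randomized verification suites use 50 stores of ≤ ~900 points with
  mixed MS levels and polarities, 100 simulated peaks for fit recovery,
  and 500 replicate null tables (20 compounds, 4 + 4 files) for the
  type-I-error check — sizes chosen to make the whole suite run in well
  under a minute while keeping Monte-Carlo error on the measured rates
  small relative to the bands being checked.
* File ids are assigned sequentially from 0 at load time; a source path
  may be loaded once per store, so a run maps to exactly one slice of the
  collection.

## Known limitations

* The point store is in-memory (the on-disk container is a plain
  registry.json + points.csv directory); hundreds of millions of points
  want a real array database, which is exactly the regime this desk-scale
  implementation trades away for inspectability.
* Extraction quantifies MS1 only; MS2 attributes are stored and sliceable
  but not used for quantification.
* `group_test()` supports the two-group Welch design only; richer designs
  should take the feature table into `limma` or a mixed-model framework.
* The Gaussian peak model has no tailing term; strongly tailed peaks will
  fit with inflated σ and the area (which does not depend on the fit)
  should be preferred over fitted amplitudes for quantification.
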