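---
title: "Ordering static snapshots of the segmentation clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering static snapshots of the segmentation clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoclock)
```

## The model

Fixed PSM explants are snapshots of a periodic process: the
segmentation clock sweeps a band of expression posterior→anterior once
per cycle. Each sample j contributes a spatial profile, and the cohort
forms an intensity matrix f(i, j) — intensity at axial bin i of sample
j. If the samples were arranged in true temporal order and the cohort
covered exactly one cycle, each spatial bin's intensity, read across
the ordered samples, would trace one period of an oscillation. The
ordering objective scores exactly that:

$$g(\pi) \;=\; \sum_{i} \sum_{k}
  \bigl[ A(f_{i}\circ\pi;\,k) - A_T(k) \bigr]^2 ,
  \qquad A_T(k) = \cos(2\pi k / P),$$

where $A(\cdot;k)$ is the circular (wrap-around), mean-removed,
variance-normalized autocorrelation of spatial row i under the column
ordering $\pi$, evaluated at integer lags k (default $1..\lfloor M/2
\rfloor$; longer lags duplicate information under circularity), and the
target period P defaults to M samples. The true order of a noise-free
sinusoidal cohort gives $A(k) = \cos(2\pi k/M) = A_T(k)$ at every lag
and row, hence $g = 0$ — this closed form anchors the unit tests.

Two readings of "autocorrelation of the j-th column" are conceivable;
the autocorrelation of a single sample's *spatial* profile is invariant
to re-ordering the samples and would make g constant, so the objective
here runs the autocorrelation along the ordered *sample* axis for each
spatial bin — the only reading under which rearranging columns can
create a periodic pattern. Likewise the cosine form of $A_T$ is a
reconstruction from the requirement that it "enforce temporal
periodicity"; P is exposed as a parameter for cohorts believed to span
other fractions of the cycle, though only P = M is exercised by the
validation suite.

### Symmetry

Circular autocorrelation is blind to cyclic rotation and to reversal of
$\pi$: g has a $2M$-fold dihedral degeneracy, confirmed to $10^{-12}$
by the test suite. Temporal order is therefore only identifiable up to
"where the cycle starts" and "which way time runs". Recovery is scored
with `ordering_distance()`, the minimum normalized Kendall-tau distance
over the whole orbit. The returned fit is canonicalized — smallest
sample id first, direction chosen so the expression-band centroid
(intensity-weighted mean position of the bins at ≥ 50 % of each
column's maximum) drifts posterior→anterior, the physiological wave
direction. The band centroid rather than the whole-column centroid is
used because a static rostro-caudal gradient compresses the latter into
a narrow range where the drift's winding number can vanish.
Canonicalization never changes g.

## Optimization

`infer_order()` minimizes g by Metropolis annealing over permutations:
proposals are segment reversals (swap-two is available; reversals mix
better on permutation spaces because they preserve most adjacencies),
acceptance is $\min(1, e^{-\Delta g/T})$, and T cools geometrically
(default factor 0.999 per step). The initial temperature defaults to
the median $|\Delta g|$ over 100 random swap proposals — a scale at
which roughly half of early uphill moves are accepted. Five restarts
from random permutations guard against trapping; the best-ever state
across chains is returned, with its per-iteration trace. Identical
seed and settings give bit-identical results (the chain consumes R's
RNG stream). The objective kernel is compiled (Rcpp); a full
re-evaluation per proposal costs O(rows × M × lags), which keeps the
default 5 × 20 000 iterations at a few seconds for M = 24 cohorts with
100 bins.

`method = "exhaustive"` enumerates permutations (fixing the first
sample at rank 1, which is complete by rotation invariance and verified
against full enumeration) and serves as the global-optimum oracle up to
M = 9; exact ties resolve to the lexicographically smallest canonical
permutation. On twenty 7-sample band cohorts at 5 % noise the annealer
attains the exhaustive minimum in 20/20 cases in the acceptance run.

Rows whose variance does not exceed `min_row_variance` (default
1e-12) are excluded from g — their autocorrelation is undefined and
they carry no ordering signal; the count of admissible rows is
reported on the fit.

## Profile extraction

`extract_profile()` implements the quantification conventions:

* Pixel centers sit at integer + 0.5; ROI membership is
  center-in-polygon (via `mgcv::in.out`).
* Each pixel's axial coordinate is the arclength of its orthogonal
  projection onto the axis polyline, measured from the origin's own
  projection and divided by the per-sample unit length; coordinates
  outside [0, 1] are discarded. The full ROI width contributes to each
  axial bin (no fixed-width band around the axis is imposed).
* Bins are half-open [i/n, (i+1)/n) with the last bin closed; the bin
  value is the mean of its pixels, which makes extraction exactly
  linear under constant image shifts.
* Empty bins are filled by linear interpolation between non-empty
  neighbors (nearest value at the ends) and flagged — this preserves
  matrix rectangularity without inventing a smoothing step.
* Background handling is image-level: `subtract_background()` maps each
  pixel to max(p − level, 0), with the level summarized from a
  no-primary control ROI (mean by default, percentile optional). The
  subtraction is applied before binning; the order matters only through
  the thresholding nonlinearity.
* Per-profile normalization defaults to max (peak = 1), keeping band
  shape while making columns commensurable; area normalization (unit
  trapezoidal integral) is available.
* Stacks are z-projected by maximum by default — thin expression bands
  survive a max projection that a mean would dilute; mean and sum are
  flags.

`build_matrix()` resamples profiles onto a common bin grid by
piecewise-linear interpolation with linear end-extrapolation, which is
exact for affine profiles on any grid pair (the test suite checks this
to 1e-12).

`assign_phase()` classifies a clock-gene profile into the conventional
thirds of the cycle by the centroid of its ≥ 50 %-of-max band:
centroid < 1/3 → Phase 1, < 2/3 → Phase 2, else Phase 3. The cut-offs
are an explicit convention standing in for by-eye phase calls; the
centroid and fractional band width are returned so other rules can be
applied downstream.

## The synthetic cohort generator

`wave_model()` / `simulate_cohort()` generate the statistical structure
the ordering method assumes, with known ground truth. The default
("band") mode is a Gaussian band of expression (sd 0.12 of the axis —
roughly the quarter-axis width of a nascent-transcription band) whose
center sweeps 0→1 over one cycle, on top of a static linear gradient
(slope 0.5 toward the anterior, emulating the rostral-strong Dll1/Notch1
protein gradient) and baseline 0.1, with additive Gaussian noise of sd
= 0.1 × amplitude, clipped at zero, on 100 axial bins. The "sinusoid"
mode matches the cosine target exactly and anchors the closed-form
tests. `paired_cohort()` emulates contralateral explant halves: one
phase draw shared by two channels (optionally offset), independent
noise per channel, shared sample ids.

These defaults were fixed once as plausible study conditions and are
not tuned per test. The generator emulates profiles, not pixels; it
does not model shot noise, segmentation errors in ROI/axis annotation,
embryo-to-embryo amplitude variation, or cohorts spanning several
cycles — so passing tests demonstrate correctness of the ordering
machinery under the stated model, not robustness to every failure mode
of real imaging data. Phase-classification accuracy near the axial
boundaries is also limited: a band centered within ~2 sd of either end
is truncated, which biases its centroid inward, so centroid-vs-phase
agreement is asserted for interior phases only.

## Numerical choices

* CSV writers print 17 significant digits: deterministic output that
  round-trips doubles exactly (the kymograph CSV round-trip test is
  bit-exact).
* Provenance JSONs record the package version, resolved settings, seed
  and input digests, but no timestamps, so re-running a pipeline with
  the same seed reproduces every output byte for byte.
* The annealing trace records (iteration, current g, best g,
  temperature) every 10 steps by default.
* Degenerate inputs fail loudly: all-zero profiles cannot be normalized
  or phase-classified, zero-variance matrices cannot be ordered, ROIs
  without interior pixels and axes that project no pixel into [0, 1]
  are errors rather than silently empty profiles.

## Problem sizes

The validation suite runs entirely on synthetic cohorts at desk scale:
M = 24 samples × 100 bins for recovery and separation checks, M = 7
for annealing-vs-exhaustive agreement (20 cohorts), 50 random matrices
for the symmetry property, and a 10-sample contralateral pair for the
end-to-end pipeline. These sizes mirror realistic explant cohorts
(tens of samples) while keeping the full suite under two minutes.

## Known limitations

* The cohort is assumed to span one clock cycle with roughly uniform
  phase coverage; P ≠ M is exposed but untested beyond invariants, and
  strongly clustered phases will frustrate any autocorrelation target.
* Absolute time, clock period in hours, and wave velocity are out of
  scope — only order is inferred.
* Tile stitching, flat-field correction and anatomical detection of the
  PSM or its axis are not attempted; annotations are taken as given.
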