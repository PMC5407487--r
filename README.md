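# kymoclock

Temporal ordering of static snapshots of oscillatory gene expression in
the presomitic mesoderm (PSM).

## The problem

The segmentation clock drives waves of gene expression that sweep the
PSM from posterior to anterior once per cycle (about 2 h in mouse).
Fixed, stained explants are single snapshots of this process: each
sample sits at some unknown phase of the cycle. Given a cohort of M
such snapshots — each reduced to a fluorescence-intensity profile along
the normalized rostro-caudal axis — this package reconstructs their
temporal order, so that a library of static images becomes a kymograph
of the oscillation. It is aimed at anyone quantifying clock-driven
expression (e.g. *Lfng* intron probes for nascent transcription, Dll1 or
Notch1 protein) in whole-mount PSM explants, where contralateral explant
halves let a clock-gene channel date the partner channel.

## The method

Profiles are extracted per sample: pixels inside an ROI polygon are
projected orthogonally onto an annotated posterior→anterior axis
polyline, their arclength coordinate is normalized by a per-sample unit
length, and mean intensity is taken in axial bins after background
subtraction to a no-primary control level. Normalized profiles placed
side by side give the intensity matrix *f(i, j)* — intensity at spatial
bin *i* of sample *j*.

Ordering minimizes, over permutations π of the M samples,

    g(π) = Σ_i Σ_k [ A(f_i ∘ π; k) − A_T(k) ]²,

where *A*(·; k) is the circular, mean-removed, variance-normalized
autocorrelation of spatial row *i* read along the ordered sample axis at
lag *k*, and *A_T*(k) = cos(2πk/P) is the target autocorrelation of a
pattern that is periodic over P samples (P = M by default: the cohort
spans one clock cycle). g is minimized by Metropolis annealing over
permutations (with an exhaustive enumerator as validation oracle for
small M). Because g is invariant to cyclic rotation and reversal,
orders are recovered — and scored — up to that dihedral symmetry; the
returned order is canonicalized so the expression band drifts
posterior→anterior with increasing rank.

The inferred order of the clock channel is transferred to the partnered
channel by shared sample id, and ordered kymographs (optionally tiled
over several cycles, i.e. periodically extended) are written as CSV and
PNG.

## Worked example

```r
library(kymoclock)

model  <- wave_model(noise_fraction = 0.1)        # band sweeping the axis
cohort <- simulate_cohort(model, n_samples = 24, phase_scheme = "grid",
                          seed = 11, shuffle = TRUE)
m   <- cohort_matrix(cohort, normalize = "max")
fit <- infer_order(m, seed = 1)
fit
#> Snapshot temporal ordering (anneal), channel Lfng_i
#>   M = 24 samples, g = 100.125 over 100 admissible rows
#>   rank order: S001 S002 S004 S003 S005 S006 S007 S008...

ordering_distance(fit, cohort$true_order)
#> [1] 0.007246377
```

The fit report reads: 24 snapshots were ordered by annealing on the
`Lfng_i` channel; the minimized periodicity objective is g = 100.1,
summed over the 100 spatial bins that carry ordering signal. The rank
order lists sample ids from the start of the inferred cycle — here the
true order was `S001 S002 S003 ...` (ids are assigned in phase order
before shuffling), so the fit is exact apart from one local swap of the
near-identical neighbors S003/S004. `ordering_distance` confirms this:
0.7 % of sample pairs are discordant with the ground truth, after
discounting the rotation/reflection the objective cannot see.
`summary(fit)` adds the lag set, the annealing schedule and the
per-restart optima (all five restarts converge to the same g here);
`plot(fit)` shows the annealing trace and the band-centroid drift;
`build_kymograph(m, fit) |> periodic_extension(3) |> plot()` draws the
ordered kymograph over three simulated cycles.

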