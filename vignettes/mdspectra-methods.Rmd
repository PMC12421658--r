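---
title: "Methods: replica statistics, densities and circular analyses in mdspectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replica statistics, densities and circular analyses in mdspectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdspectra)
```

mdspectra post-processes GROMACS analysis output — never trajectories. This
vignette documents the statistical model behind each analysis family, the
parameters that matter, the numerical choices made where conventions differ,
and what the synthetic-data generator does and does not emulate.

## Input model

Three dialects are read. `.xvg` files are whitespace tables with `#`
comments and `@` xmgrace directives; only `title`, `xaxis label`,
`yaxis label` and `s<N> legend` are interpreted (they are the only
directives any analysis needs), every other `@` line is carried through
verbatim so a round trip loses nothing. All data columns, including frame
indices, parse as double — a uniform numeric contract — and both fixed and
exponent notation are accepted, with `.` as the only decimal separator
regardless of locale. `.dat` files follow the same contract with no
directives. `.xpm` files are GROMACS XPixMaps: a `ncols nrows ncolors cpp`
header, `ncolors` legend lines, `nrows` pixel rows; parsing rejects any
grid code missing from the legend and any row whose length disagrees with
the header, because silent truncation of a DSSP matrix would bias every
downstream fraction.

Distance legends of the form `lo-hi` map to the bin midpoint: GROMACS
quantises distances into colour levels, and the midpoint is the unbiased
representative of a uniform bin. Single-number labels map to that number;
categorical labels (DSSP letters) are refused by the numeric path and
directed to the secondary-structure classifier.

## Replica aggregation

A simulation group is an unlimited set of replicas of one property. The
summary statistic is the per-timepoint arithmetic mean with the sample
(n−1) standard deviation; with one replica the band is identically zero.
The sample estimator is the natural choice for a small number of
independent repetitions treated descriptively; no inferential statistics
(CIs, tests) are attached, deliberately.

Replica grids rarely disagree in practice, but when they do the package
truncates all series to the overlapping time range and resamples onto the
coarsest replica's grid by nearest-neighbour lookup. Truncation plus
nearest neighbour was chosen over interpolation because interpolation
manufactures values at times no replica sampled, which then understate the
band; nearest neighbour only reuses measured values. Grids that agree
pointwise within 1% of the sampling interval (`rel_tol`) are treated as
identical and the first replica's axis is adopted.

Time units: GROMACS writes ps by default, plots are in ns. The unit is
read from the x-axis label (`(ps)`/`(ns)`); absent a label ps is assumed,
and `as_time_series(unit = )` overrides. RMSF-style traces use a
residue/atom index axis (`unit = "index"`) and are never converted.

## Kernel density estimation

The 1D estimate is the textbook Gaussian KDE
f̂(x) = (1/(n·h·√2π)) Σ exp(−(x−xᵢ)²/2h²), evaluated on 512 evenly spaced
points spanning the observations ± 4h, so ≥ 99.99% of each kernel's mass
lies inside the grid and the trapezoidal integral is 1 within 5%. The
default bandwidth is Silverman's rule 0.9·min(σ̂, IQR/1.349)·n^(−1/5) —
the standard unopinionated default; it is a plain argument (`h`) for exact
matching against any other tool, and Scott-style choices can be passed
directly. When all observations coincide both spread measures vanish; the
estimate falls back to h = 1 with a warning rather than erroring, since a
perfectly flat trace is a legitimate (if dull) simulation outcome.

The 2D estimate is the product Gaussian kernel with per-axis Silverman
bandwidths on a 128 × 128 default grid. Angular data (Ramachandran,
rotamers) are wrapped to [−180, 180) before estimation; the kernel itself
is **not** periodic. For densities with appreciable mass at the seam,
`augment_periodic()` replicates each observation at ±360° so the kernel
sees its wrap-around neighbours; it is off by default because typical
basins (α, β, χ rotamer wells) sit far from ±180° and augmentation triples
the cost.

## Secondary structure

DSSP codes map to six classes: H→α-helix, G→3-helix, E→β-sheet, T→turn,
S→bend, C/`~`/blank→coil/loop. B (isolated β-bridge) folds into β-sheet
and I (π-helix) into coil/loop: the six-class partition has no slot for
either, and an exhaustive partition is required for per-frame
probabilities to sum to 100. The mapping is an argument for users who
disagree. GROMACS `do_dssp` puts residues on y and frames on x; the
orientation is auto-detected from axis-tick counts when both are present
and unambiguous, else frames-on-x is assumed.

Per frame i and class s, P(i,s) = N(i,s)/N_total × 100 and
F(i,s) = P(i,s)/100. Probability boxplots pool all frames of all replicas
within a group — the alternative (summarising replicas first) hides
between-replica variance inside the box; pooling shows the full sampled
distribution. Quartiles are type-7 (linear interpolation, the most common
default; exposed as `quartile_type`), whiskers at the most extreme data
within 1.5·IQR. The per-frame fraction table is exported as a CSV plus a
single-file SpreadsheetML (XML) workbook, which Excel and LibreOffice open
directly; the XML form keeps the artifact plain text. All six class
columns are always present, even for classes that never occur.

## Circular statistics

Angles are canonicalised to [−180, 180) (the Ramachandran/GROMACS
convention), with 180 mapping to −180. The circular mean is
atan2(mean sin, mean cos); the mean resultant length R accompanies every
mean. When R < 1e−9 (antipodal data such as {0°, 180°}) the mean is
reported as NaN with a warning — an arbitrary finite angle would silently
corrupt averaged rotamer traces, and NaN propagates visibly instead.
Per-timepoint circular means across replicas require identical grids; a
single replica passes through unchanged.

Ramachandran analysis concatenates (pools) the (φ,ψ) pairs of all replicas
of a group rather than averaging them: the mean of two basins is not a
conformation, while pooling depicts the whole sampled space. Both
per-replica and combined density plots are written. Rotamer analysis
averages χ1/χ2 across replicas with circular means, supports a closed
`[t0, t1]` time window, and reports dot plots, 2D densities and histograms
(equal-width bins over [−180, 180), counts conserved by construction).

## Interactions, occupancy, distance matrices, PCA

Contact and minimum-distance traces are replica-summarised like any time
series, with sign validation (counts and distances are non-negative).
Hydrophobic contacts consume one contact `.xvg` per residue per replica —
the only residue-resolved signal available without topology access — and
sum the user-selected residues per timepoint before summarising, so the
full-selection result is exactly the sum of the per-residue sums. Mean
minimum distances above a configurable 0.6 nm threshold are flagged in the
run log as potential dissociation events; the flag is advisory and never a
plot element, because a universal dissociation criterion does not exist.

The occupancy map projects pooled ligand atom positions onto the XY plane
(z is discarded: pooling all frames' (x, y) is what yields a 2D density)
and bins them over the **box** dimensions, not the data range, so the map
is in the box's physical coordinates. Counts are max-normalised to a
relative density in [0, 1] — the natural reading of "relative density"
with a hottest-spot of 1. Coordinates outside the box are wrapped modulo
the box length with a warning (periodic images), rather than rejected.

Distance matrices come from `gmx mdmat` `.xpm` via the legend-midpoint
rule; the rendered heatmap always has a CSV sidecar equal to the plotted
matrix. PCA is consumed, not computed: the package reads 2D projections
(`gmx anaeig -2d`) in keeping with the no-trajectory input contract, drops
a leading time column when present, and colours points by frame order.

## The synthetic-data generator

Fixtures emulate the *statistical* shape of GROMACS output with known
truth: deterministic trend + Gaussian noise for time series; categorical
draws with known class probabilities for DSSP grids (written in the
do_dssp residues-on-y layout); von Mises draws (Best–Fisher rejection
sampling, implemented in-package) with known mean direction for dihedrals;
Gaussian mixtures for φ/ψ basins, PCA clusters and ligand hot spots;
separation-dependent symmetric matrices for distances. Headers
deliberately vary (title/legend present or absent) to harden the parsers.
Each fixture kind draws from its own stream derived from (seed, kind), so
any file regenerates bit-identically in isolation.

What the fixtures do **not** emulate: autocorrelation along time,
force-field physics, correlated secondary-structure runs along the chain,
or anything about real conformational kinetics. Passing tests therefore
demonstrate that the statistics and parsers are computed correctly, not
that any biological conclusion holds.

## Numerical choices and problem sizes

Round-trip fidelity is 12 significant digits (`%.12g`), well beyond the
precision GROMACS prints. Test and acceptance problem sizes — chosen as
the smallest that make the statistical checks sharp — are 5 replicas ×
10,000 points for replica statistics (CLT tolerance 4σ/√N), 200–500
observations against a naive double-loop KDE oracle at 1e−12, 100 × 30
DSSP grids with exact count recovery, 10,000 von Mises draws at κ = 4
recovering μ within 2°, and 10,000 uniform points × 100 bins within
5σ binomial bands for occupancy.

## Known limitations

Only Gaussian (non-adaptive, non-periodic) kernels; no inferential
statistics; no per-residue secondary-structure timelines (per-frame
aggregation only); no topology-aware contact computation; heatmap colour
fidelity is delegated to ggplot2 and untested beyond the sidecar numbers.
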