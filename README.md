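# mdspectra

Replica-averaged post-processing of GROMACS molecular-dynamics output, in R.

Molecular-dynamics workflows end with a pile of GROMACS text files — `.xvg`
time series from `gmx rms`, `gmx rmsf`, `gmx gyrate`, `gmx sasa`, `gmx hbond`,
`gmx mindist`; `.xpm` colour matrices from `do_dssp` and `gmx mdmat`; plain
`.dat` tables — usually one set per independent replica. mdspectra is for the
structural bioinformatician or medicinal chemist who runs several replicas
per condition and wants publication-grade descriptive statistics and figures
without touching trajectories again: the package consumes only post-processed
GROMACS output (never `.xtc`/`.tpr`), aggregates any number of replicas, and
computes eleven analysis families — time-dependent property profiles,
kernel densities, DSSP secondary-structure probabilities and fractions,
PCA conformational landscapes, protein–ligand contacts and minimum
distances, ligand occupancy maps, ligand dihedral monitoring, inter-residue
distance matrices, Ramachandran (φ/ψ) densities, χ1/χ2 rotamers, and
thermodynamic monitoring (T, P, ρ).

## The statistics at the core

**Replica aggregation.** For a property y sampled at times t across n
replicas, every time-dependent analysis reports the arithmetic mean
ȳ(t) = (1/n) Σᵢ yᵢ(t) with the sample standard deviation
s(t) = √( Σᵢ (yᵢ(t) − ȳ(t))² / (n−1) ) as a shaded band (zero band for a
single replica). Replicas on mismatched grids are truncated to their
overlap and resampled onto the coarsest grid by nearest neighbour.

**Gaussian kernel density estimation.** Distributions of any metric are
estimated as

    f̂(x) = 1/(n·h·√(2π)) · Σᵢ exp(−(x − xᵢ)² / (2h²))

with Silverman's rule-of-thumb bandwidth h = 0.9·min(σ̂, IQR/1.349)·n^(−1/5)
by default; the 2D product-kernel analogue backs Ramachandran, rotamer and
time-resolved dihedral heatmaps.

**Secondary structure.** From a DSSP `.xpm`, the per-frame probability of
class s is P(i,s) = N(i,s)/N_total × 100 and the fraction
F(i,s) = N(i,s)/N_total over the six-class partition α-helix, β-sheet,
coil/loop, turn, bend, 3-helix; per-class distributions are summarised as
boxplots (type-7 quartiles, 1.5·IQR whiskers) and exported per frame as a
spreadsheet workbook plus CSV.

**Circular statistics.** Dihedral angles live on a circle (0° ≡ 360°), so
averages use the circular mean atan2(mean sin, mean cos) with the mean
resultant length R as a concentration diagnostic; a vanishing resultant
(e.g. {0°, 180°}) is reported as an explicit undefined value, never a
silently wrong number. Ramachandran densities pool (concatenate) replicas
rather than averaging them.

Every figure (PNG + SVG) is backed by a CSV sidecar with its exact numbers,
and a seeded synthetic-data generator emits all the input dialects with
known ground truth, so the whole pipeline is testable without a simulation.

## Worked example

Generate a three-replica RMSD fixture (exponential equilibration from
0.15 nm towards 0.25 nm, 0.02 nm noise), then aggregate:

```r
library(mdspectra)

dir <- tempfile(); dir.create(dir)
fx <- gen_timeseries(dir, property = "RMSD", n_points = 2000, n_replicas = 3,
                     trend = function(t) 0.15 + 0.1 * (1 - exp(-t / 2000)),
                     noise_sd = 0.02, seed = 42)

series <- lapply(seq_along(fx$paths), function(i)
  as_time_series(read_xvg(fx$paths[i]), replica = paste0("rep", i),
                 property = "RMSD"))
rs <- to_nanoseconds(replica_set(series, group_label = "wild-type"))
st <- summarize_replicas(align_replicas(rs))
glance(st)
#> # A tibble: 1 × 6
#>   group     property n_replicas n_points mean_overall sd_overall
#> 1 wild-type RMSD              3     2000        0.240     0.0236
```

The overall mean of 0.240 nm sits between the start (0.15 nm) and the
asymptote (0.25 nm) of the generating trend, as it should for a trace that
spends most of its 20 ns equilibrated; the 0.024 nm spread reflects the
trend drift plus the injected noise. The density companion:

```r
glance(kde_1d(rs$value))
#> # A tibble: 1 × 6
#>   n_obs bandwidth n_grid integral  mode  peak
#> 1  6000   0.00379    512    1.000 0.249  17.4
```

The estimate integrates to 1.000 (a well-formed density) and its mode,
0.249 nm, is the equilibrated RMSD plateau. `autoplot(st)` draws the
mean ± SD band; `run_analysis("rmsd", config, out_dir)` does all of the
above from a YAML profile and writes figure, sidecar and log. A circular
mean near the ±180° seam, where a naive average would fail:

```r
circular_mean(c(-170, 175, -165))
#> [1] -173.32  (resultant length 0.989)
```

## Command line

```sh
mdspectra fixtures --kind all --seed 1 --out fixtures/
mdspectra rmsd --config rmsd_config.yaml --out results/
mdspectra list
```

(`mdspectra` is installed under the package's `exec/` directory; prefix with
`$(Rscript -e 'cat(find.package("mdspectra"))')/exec/` or symlink it onto
your PATH.)

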