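# fathom

Persistent homology of epicardial fat texture in cardiac CT patches.

Excess epicardial adipose tissue on the left atrium is associated with
atrial fibrillation, and on CT it occupies a characteristic attenuation
window (about −190 to −30 Hounsfield units). `fathom` asks a shape
question rather than a volume question: does the *topology* of the
fat-window texture — how many connected components and loops appear as a
threshold sweeps through the attenuation range — separate epicardial-fat
patches from non-fat patches?

The package is aimed at medical-image analysts who want a small,
fully-tested topological-data-analysis pipeline for 2D patch data:
HU-window masking, patch tiling, two filtration backends, persistent
homology from first principles, Betti curves, persistence
diagrams/barcodes, bottleneck distances, and a descriptive two-group
comparison. Because no patient imaging ships with the package, a seeded
synthetic generator emulates the two tissue groups.

## The method

For a filtration — a nested family of complexes `K_t` indexed by a scale
parameter `t` — persistent homology records each topological feature as an
interval `[birth, death)`: the k-th Betti number `β_k(t)` (components for
`k = 0`, loops for `k = 1`) is the number of dim-`k` intervals containing
`t`. Two filtrations are provided:

* **Vietoris–Rips** on the masked-pixel point cloud: vertices at scale 0,
  an edge when two pixels are within distance `t` (the filtration is
  indexed by *diameter*, so one unit of `t` is one pixel of distance),
  triangles by the flag rule at the maximum of their edge scales.
* **Cubical sublevel-set** (V-construction, 4-adjacency) on the patch
  itself: one vertex per pixel at its HU value, edges and squares at the
  maximum of their vertices. Sweeping `t` through HU values reproduces the
  image-thresholding sweep natively, and is the default backend.

Persistence is computed by the standard boundary-matrix column reduction
over GF(2) (with the clearing optimisation), implemented in C++. Every
pairing is cross-checked in the test suite against brute-force Betti
numbers: union-find for `β_0` and either the planar Euler characteristic
`β_1 = β_0 − (V − E + F)` or GF(2) boundary-matrix ranks
`β_1 = E − rank ∂_1 − rank ∂_2` for `β_1`.

Per tissue group the pipeline reports the Betti-number range
`(min β_k, max β_k)` over the sweep and how far the diagram points sit
from the diagonal (median of `(death − birth)/2`): smooth connected fat
blobs yield a narrow Betti range with near-diagonal points, while
fragmented non-fat texture yields a wide range and more scattered
diagrams.

## Worked example

```r
library(fathom)

report <- run_pipeline(pipeline_config(seed = 0, log_level = "quiet"))
report
#> <topo_comparison>
#>
#> Per-group summaries:
#> # A tibble: 2 × 6
#>   group  betti_min betti_max mean_persistence median_diagonal_dist…¹ n_intervals
#>   <chr>      <int>     <int>            <dbl>                  <dbl>       <int>
#> 1 fat            0       238             19.7                   6.16        3595
#> 2 nonfat         0      4848             39.8                  17.1        32160
#>
#> Contrasts:
#> # A tibble: 2 × 3
#>   metric                   ordering     difference
#>   <chr>                    <chr>             <dbl>
#> 1 betti_max                fat < nonfat     4610
#> 2 median_diagonal_distance fat < nonfat       10.9
```

This runs the default study: two synthetic groups of 8 subjects × 36
patches of 32×32 HU pixels each, one concatenated 192×192 patch per
subject, cubical backend, `β_0` ranges and dim-1 diagonal statistics. The
fat group's Betti numbers stay in a narrow band (0–238 here) with diagram
points close to the diagonal (median L∞ distance 6.2 HU), while the
non-fat group sweeps a far wider range (0–4848) with points further from
the diagonal (17.1 HU) — the fat group has the "smaller range, many small
holes" signature, the non-fat group the wider, rougher one. Absolute
magnitudes depend on patch size and texture model; the contrast direction
is the reproducible finding.

Smaller building blocks compose with the pipe:

```r
make_fixture("circle") |>
  vietoris_rips(eps_max = 2.1) |>
  persistence()
#> <persistence_diagram> 21 interval(s): 20 in dim 0, 1 in dim 1
```

`autoplot()` draws diagrams and Betti curves; `plot_barcode()` draws
barcodes; `tidy()`/`glance()` give tabular views of a comparison.

A command-line interface with subcommands `generate`, `mask`, `ph`,
`betti`, `compare` and `run` is installed at `inst/cli/fathom`
(`Rscript <library>/fathom/cli/fathom run --seed 0 --out out/`).

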