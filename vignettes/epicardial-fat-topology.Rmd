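---
title: "Topological analysis of epicardial fat texture: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of epicardial fat texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fathom)
```

## The scientific question

Epicardial adipose tissue — fat between the visceral pericardium and the
myocardium — accumulates on the left atrium in patients with atrial
fibrillation. On CT, fat occupies a characteristic attenuation band,
conventionally −190 to −30 Hounsfield units (HU). `fathom` studies the
*texture topology* of small CT patches: as an attenuation threshold sweeps
upward, connected components of sub-threshold pixels appear, merge, and
enclose loops. Persistent homology summarises that whole sweep as a
multiset of `[birth, death)` intervals per homology dimension, from which
we derive two group-level discriminators:

* the **Betti-number range** `(min, max)` of `β_k(t)` over the sweep —
  smooth, connected fat texture stays in a narrow band, fragmented non-fat
  texture sweeps a wide one; and
* the **diagram-versus-diagonal statistics** — fat diagrams concentrate
  near the diagonal (many short-lived features), non-fat diagrams scatter
  further from it.

No hypothesis test is attached: the contrast is descriptive, and the
package reports the direction and size of each contrast rather than a
p-value.

## Pipeline and models

The pipeline is `generate → mask → filter → persist → summarise`, with
each stage an exported, separately tested function.

### HU masking and point clouds

`mask_hu()` flags pixels inside the window (endpoints inclusive — the
standard convention for fat thresholds). `points_from_mask()` turns the
true pixels into a planar point cloud at 0-based `(x, y) = (column, row)`
coordinates with the Euclidean pixel metric. `concatenate_patches()` tiles
a subject's 36 patches of 32×32 row-major into one 192×192 patch (6×6
tiling keeps the composite compact and isotropic; the layout is a design
choice, since only "concatenation" itself is fixed by the analysis).

### Vietoris–Rips filtration

`vietoris_rips()` realises the "growing balls" picture: balls of radius
`ε` around two pixels first intersect when their distance is `2ε`. We
index the filtration by **diameter** (the distance itself), the dominant
convention in TDA software, so filtration units equal pixel distances;
users thinking in radii should halve the axis. Triangles enter at the
maximum of their edge values (flag-complex rule). `eps_max` (default 10
px for image-derived clouds) truncates the quadratic edge set; classes
alive at the end are reported with death `+Inf` regardless of truncation.

### Cubical sublevel-set filtration

`lower_star_cubical()` builds the vertex-based (V-construction) cubical
complex with 4-adjacency: vertex per pixel at its HU value, edge per
4-adjacent pair and square per 2×2 block, each at the maximum of its
vertices. Its sublevel set at `t` is exactly the set of pixels with value
≤ `t` together with the adjacencies among them, so the filtration *is*
the thresholding sweep. We chose the V-construction because its planar
`β_1` has an exact independent oracle via the Euler characteristic, which
anchors the test suite. Stored filtration values are shifted so the
minimum maps to 0 when negative HU appear; the shift is recorded and
undone in every user-facing threshold and diagram, so diagrams are in HU
and remain comparable across patches (this also preserves the stability
bound between a patch and its perturbation).

### Which backend drives the group comparison?

The pipeline's default backend is **cubical**. A Rips complex on masked
pixel clouds degenerates for the range statistic: every masked pixel is a
vertex at scale 0, so the maximum of the dim-0 Betti curve equals the
masked-pixel count — a pixel-counting statistic, not a topological one,
and one that points in the *opposite* direction for fat (whose in-window
fraction is near 1). The cubical sweep over HU values measures how
components of sub-threshold pixels appear and merge, which is the
threshold sweep the analysis describes and yields the fat < non-fat range
ordering robustly. The Rips backend remains available (`backend =
"rips"`) for genuine point-cloud inputs and for the analytic fixtures.

### Persistence computation

`persistence()` performs the textbook column reduction of the boundary
matrix over GF(2): process cells in filtration order (ties broken by
`(value, dim, id)`, so runs are deterministic), repeatedly add earlier
columns sharing the current column's lowest nonzero row, and read pairs
off the reduced lows. The inner loop is C++ (via Rcpp) with the clearing
refinement — columns already paired as births by a higher dimension are
provably zero and are skipped — which keeps the ~147,000-cell complexes of
a 192×192 patch at around a tenth of a second without changing any
pairing. Coefficients are GF(2), the universal default. Zero-length
intervals are retained internally (interval-conservation checks need
them) but excluded from reported diagrams by default (`keep_zero = TRUE`
to keep). Homology is reported for dimensions 0 and 1; the data are
planar, so nothing higher is meaningful.

`betti_at()` is the *independent oracle*: union-find for `β_0`, the Euler
formula (cubical) or GF(2) boundary ranks (any complex) for `β_1`. It
shares no code with the reduction, and the central correctness test
asserts that Betti curves read off diagrams agree with it at every
critical value and midpoint for randomized clouds (≤ 12 points) and
images (≤ 8×8) — small enough that the quadratic rank oracle is exact and
fast, large enough to exercise every merge/loop pattern.

`bottleneck_distance()` computes the exact bottleneck distance by binary
search over candidate costs with an augmenting-path perfect-matching
feasibility test, after capping essential deaths at a shared finite value.
Exhaustive matching enumeration would cap diagrams at a handful of
points; the matching formulation is still exact and handles the ~100
intervals of a 16×16 noise patch, so diagram stability can be verified on
realistic sizes (a 500-point guard errs towards dedicated tools beyond
that).

### Betti curves and summaries

`betti_curve()` uses the half-open convention `birth ≤ t < death`. The
default threshold grid is every critical value plus one value below the
minimum, so the curve attains 0 and the range statistic starts at 0; the
range is invariant under any refinement of that grid (tested). Group
`betti_max`/`betti_min` aggregate per-subject curves as max of maxima and
min of minima; diagonal statistics pool intervals across subjects (whether
ranges should be per-patient or pooled is genuinely open — the per-subject
diagrams are all retained, so either view can be recomputed). The
Betti-range dimension defaults to 0: component counts plausibly span the
wide ranges the contrast concerns, while planar loop counts are bounded
and less discriminative; `homology_dim = 1` overrides. Diagonal statistics
default to dimension 1, where "small holes near the diagonal" live.

## The synthetic generator

No patient imaging is distributed, so `generator_config()` /
`generate_cohort()` emulate the study conditions: 8 subjects per group,
36 patches of 32×32 per subject. Each patch is a Gaussian random field —
the simplest stationary texture model with a tunable correlation length:

| group  | mean (HU) | sd (HU) | smoothing σ (px) | rationale |
|--------|-----------|---------|------------------|-----------|
| fat    | −110      | 25      | 2                | N(−110, 25) puts ~99.8% of pixel mass inside −190..−30; 2-px correlation makes the in-window region one smooth blob |
| nonfat | −10       | 45      | 0                | only the lower tail dips into the window, as independent scattered pixels |

Smoothing renormalises the marginal variance (divide by `Σk²` of the
separable kernel) so `sd_hu` is the pixelwise sd either way; values are
clipped to the valid CT range [−1024, 3071]. Per-patch seeds are a
deterministic polynomial hash of (base seed, group, subject, patch), so
cohorts are bit-identical under a fixed seed while patches stay mutually
independent. The convolution is a hand-written separable pass with
reflection padding because the variance renormalisation needs the exact
kernel weights.

What the generator does *not* emulate: anatomy (no organs, vessels or
partial-volume gradients), scanner noise spectra, contrast-medium
dynamics, or 3D slice structure. Passing tests therefore show that the
pipeline recovers the topology its inputs actually have and that the
group contrast follows from the assumed intensity statistics — not that
those statistics match clinical CT. Absolute Betti magnitudes scale with
patch area and texture roughness and should not be compared against
small-cohort clinical numbers; the *direction* of the contrasts is the
transportable result.

`make_fixture()` provides analytic inputs with known homology (circle,
annulus image, two clusters, unit-square corners) used throughout the
tests.

## Numerical choices and degenerate inputs

* Window endpoints inclusive; masks cannot produce duplicate points, and
  general point-cloud construction deduplicates with a warning.
* Filtration ties broken by `(value, dim, id)`; constant patches collapse
  to a single filtration value and still validate.
* Empty clouds are an input error for Rips; empty masks yield empty
  clouds; diagrams with no finite dim-k interval yield an NA
  ("not-available") diagonal-statistics row rather than an error.
* Essential deaths are `+Inf` in all numeric outputs ("inf" in TSV) and
  are capped only for plotting and bottleneck computation.
* Rips construction guards at 5000 points (the edge set is quadratic)
  and directs dense image data to the cubical backend.

## Validation scale

The shipped suite validates: oracle equivalence on 50 random clouds (3–12
points) and 50 random images (up to 8×8) at every critical and midpoint
threshold; exact fixture homology; conservation laws (one dim-0 interval
per vertex, edges splitting into component-killers and loop-births, the
Euler identity at every threshold, `n(n−1)/2` untruncated Rips edges);
bottleneck stability of 16×16 patches under sup-norm perturbations of
0.5, 1 and 5 HU; and the fat-versus-nonfat direction over seeds 0–19 at
the full default study size. These sizes were chosen so the independent
oracles stay exact and the whole suite runs comfortably on a laptop core.

## Limitations

Synthetic cohorts stipulate the group intensity statistics; the analysis
demonstrates internal validity of the topological machinery, not clinical
discrimination. Homology is planar (dims 0–1) by design. Bottleneck
distances beyond 500 off-diagonal points, cohomology, representative
cycles, Wasserstein distances and any 3D/volumetric analysis are out of
scope.
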