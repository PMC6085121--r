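# celldistr

Shape-normalized spatial statistics for intracellular events in fluorescence
microscopy.

## What it does, and for whom

Cell biologists quantifying membrane trafficking (e.g. Rab6 exocytic
carriers, Rab11 recycling vesicles) end up with per-cell sets of
*intracellular events* — detected particles, segmented regions, or tracked
trajectories — and two recurring questions: **do experimental conditions
differ** in where the events sit inside the cell, and **is there an
organizing center** (emitter/attractor hub) around which the events are
uniformly distributed?

`celldistr` answers both without pooling cells and without assuming cells
share a shape. Events inside a 3D binary cell mask Ω are expressed in
cylindrical coordinates (r, θ, z) about a reference point O and reference
direction, then normalized by per-event distances to the cell boundary
∂Ω: the radius becomes r/d<sub>θ</sub> ∈ [0, 1] (d<sub>θ</sub> = ray-cast
distance from O to ∂Ω along the event's angle) and the height becomes the
relative position within the event's z-column. Per axis, a weighted kernel
density is estimated as

f(r) ∝ Σᵢ G<sub>σ̂</sub>(rᵢ/d<sub>θᵢ</sub> − r) wᵢ d<sub>θᵢ</sub>,
f(θ) ∝ Σᵢ H<sub>κ̂</sub>(θᵢ − θ) wᵢ d<sub>θᵢ</sub>,
f(z) ∝ Σᵢ G<sub>σ̂</sub>(z̃ᵢ − z) wᵢ d<sub>zᵢ</sub>,

with Gaussian kernels G (Silverman bandwidth, weighted) on the linear axes
and the von Mises kernel H<sub>κ</sub>(θ) = e^{κ cos θ}/(2π I₀(κ))
(circular plug-in concentration) on the angular axis; every density is
renormalized to unit mass.

Conditions are compared per axis with the Earth Mover's distance
EMD(f₁, f₂) = Σᵢ |F₁(i) − F₂(i)| (circular EMD on θ, minimizing the wrapped
cumulative difference over all start bins), and replicate structure is
respected: each experiment e gets a *condition difference*
Δₑ = inter-condition − intra-condition mean distance, and a one-sided
Wilcoxon signed-rank test on {Δₑ} yields the per-axis p value.

The organizing center is located as the point O\* maximizing the entropy
−Σ f(θ) log f(θ) dθ of the angular density recomputed about each candidate
point — exhaustively on a lattice (entropy map) or via a deterministic
hierarchical refinement that reaches the same maximum with 10–30× fewer
evaluations — and can be tracked over time.

A synthetic-data module (masks, events, trajectories with ground truth)
makes the whole pipeline testable without any imaging data. Trajectory
tooling includes the gated distance between tracks, a cross-tracker
consensus filter, confinement ratio / path length / lifetime, outward-vs-
inward classification, and spatially binned feature profiles.

## Worked example

Six replicate "cells" per condition, events uniform in angle (control)
versus concentrated at θ = π (treated), then a full study:

```r
library(celldistr)
cell <- make_cell_mask("disk", 25)
write_mask(cell, "mask.tif")
ctr <- (cell$dim[1] - 1) / 2

mkexp <- function(seed, angular, mu = 0, kappa = 1) {
  E <- sample_events(cell, event_model(300, angular = angular, mu = mu,
                                       kappa = kappa, seed = seed),
                     frame = reference_frame(c(ctr, ctr, 0)))
  write_events(E, sprintf("events_%02d.csv", seed))
  list(mask = "mask.tif", events = sprintf("events_%02d.csv", seed),
       origin = c(ctr, ctr, 0), direction = c(1, 0))
}
cfg <- list(conditions = list(
  control = lapply(1:6,  function(s) mkexp(s, "uniform")),
  treated = lapply(7:12, function(s) mkexp(s, "vonmises", mu = pi, kappa = 4))))
yaml::write_yaml(cfg, "study.yaml")

run_study("study.yaml")
#> <condition_study> 12 experiments, 2 conditions
#>   radius  p = 0.883301
#>   angle   p = 0.000244141 *
#>   depth   p = 1
```

The conditions differ only in their angular law, and only the angular axis
rejects: p = 0.000244 = 1/2¹², the exact one-sided minimum for 12
all-positive condition differences — every treated and control cell is
closer to its own condition than to the other. The radial test correctly
sees nothing (both laws share the radial distribution), and the depth test
is inert on single-plane masks.

Locating the organizing center of one replicate:

```r
E <- read_events("events_01.csv")
find_uniform_center(E, cell)
#> $origin  30 30  0         # the true emitter (mask center) recovered
#> $entropy 1.8379           # log(2*pi) = 1.8379: maximally uniform
#> $n_eval  97               # vs ~1960 lattice points in the exhaustive map
```

## Command line

A thin CLI over the package functions ships in `inst/cli/`:

```sh
celldistr simulate --shape crossbow --size 30 --n 500 --out fixture/
celldistr density --mask cell.tif --events events.csv --origin 30,30,0 --direction 1,0
celldistr compare --study study.yaml --out report/
celldistr uniformity --mask cell.tif --events events.csv --method bisection
```

See `vignettes/celldistr-methods.Rmd` for the full model description,
parameter choices and limitations.
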