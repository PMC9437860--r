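# orgaprof

Quantitative microscopy tools for two common questions about organelles in
single cells:

1. **Where are they?** Lysosomes (and other puncta-forming organelles)
   redistribute between the perinuclear region and the cell periphery under
   many perturbations. `orgaprof` measures this with a cell-shape-aware
   **cumulative radial intensity profile**: the cell is segmented, its
   boundary simplified to a polygon, and concentric shells are drawn at 10%
   increments from a chosen cell center to the periphery by scaling the
   contour about the center. The readout per cell is the fraction of total
   organelle-channel intensity inside each scaled shell — a curve from the
   center (fraction 0.1) to the edge (1.0). A left-shifted curve means a
   perinuclear distribution, a right-shifted curve a peripheral one.
2. **How do they move?** From time-lapse stacks, `orgaprof` builds
   **kymographs** along user-drawn segmented lines (e.g. a 25 μm stretch of
   an axon), extracts the loci of moving puncta, and counts
   **anterograde / retrograde / stationary** transport events; a minimal
   difference-of-Gaussians detector with nearest-neighbour linking provides
   comet-style track statistics (duration, displacement, speed) for e.g.
   EB3-GFP microtubule growth measurements.

A seeded synthetic-data module generates star-convex cells with puncta
placed by a controllable radial law, and transport time-lapses with planted
velocities, so every stage of the pipeline is testable against known ground
truth with no external data.

## The measurement

For a cell contour with vertices `p_periphery(i)` and a center `p_center`,
shell polygon vertices at distance fraction `d ∈ {0.1, …, 1.0}` are

```
p_new(i, d) = p_center + d · (p_periphery(i) − p_center)
```

Each pixel inside the cell is assigned to the innermost shell polygon
containing it; per-shell intensity sums are normalized by the total so the
cumulative curve ends at 1. The scalar summary per cell is the curve's AUC
(mean of the cumulative values): higher = more perinuclear. Groups of cells
are compared by Welch's t-test (two groups) or one-way ANOVA on the AUC.

Segmentation preprocessing follows the classic chain: threshold (Otsu by
default) → disk erosion (severs thin intercellular processes) →
connected-component clustering (8-connectivity, size-sorted) → hole
patching and small-cluster removal → Moore boundary tracing →
Douglas–Peucker approximation with tolerance `0.009 × perimeter`.

## Worked example

```r
library(orgaprof)

# two synthetic cohorts with known radial bias, 200 puncta per cell
prof_for <- function(a, b, seed) {
  cell <- generate_cell(synthetic_cell_spec(beta_a = a, beta_b = b,
                                            n_puncta = 200, seed = seed))
  profile_cell(cell$organelle, cell$contour, cell_id = seed)
}
peri   <- lapply(1:20,         function(s) prof_for(1, 3, s))      # perinuclear
periph <- lapply(101:120 - 100, function(s) prof_for(3, 1, 100 + s)) # peripheral
compare_groups(list(perinuclear = peri, peripheral = periph), "t_test")
#> <group_comparison: perinuclear vs peripheral>
#>   perinuclear: n = 20, mean AUC = 0.4720
#>   peripheral: n = 20, mean AUC = 0.3689
#>   t_test: statistic = 92.0222, p = 2.79e-36; shift: peripheral in peripheral
```

The perinuclear cohort's higher AUC (0.472 vs 0.369) is the left-shifted
cumulative curve; the t-test confirms the shift direction printed in
`shift`.

Transport counting end to end (70 frames, 1 s/frame, planted
10 anterograde / 10 retrograde / 10 stationary puncta, peak SNR ≈ 16):

```r
path <- path_spec(rbind(c(8, 15), c(376, 15)))   # proximal -> distal
sim  <- generate_timelapse(synthetic_motion_spec(seed = 1), path)
km   <- build_kymograph(sim$stack, path)
count_events(trace_kymograph(km), stationary_threshold = 2)
#> <transport events [none]: 10 anterograde, 10 retrograde, 10 stationary>
```

## Command line

```sh
inst/cli/orgaprof simulate cell --preset perinuclear --n-cells 5 --seed 7 --out sim/
inst/cli/orgaprof profile --image sim/cell001_organelle.tif \
    --shape-image sim/cell001_shape.tif --out prof/
inst/cli/orgaprof compare --group A:profA --group B:profB --test t_test --out cmp.csv
inst/cli/orgaprof kymo --stack stack.tif --path path.csv --dt 1 \
    --pixel-size 0.1 --stationary-px 2 --out kymo_out/
inst/cli/orgaprof track --stack eb3.tif --sigma 1.5:3 --threshold 10 --out tracks/
```

Exit codes: 0 success, 2 usage error, 3 data error. Runs with a fixed
config and seed are byte-identical.

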