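# anttrail

Quantifying trail-following behaviour of individual ants from video.

In a trail-following assay, a candidate trail-pheromone compound is applied
along a printed grey line on a paper arena, a single ant is released, and its
tendency to walk along the line is measured from a 3-minute overhead video
(720 × 1280 px, 25 frames/s in the original recordings). `anttrail`
implements the full analysis chain for such assays, together with a seeded
synthetic-data generator that provides ground truth for every stage:

1. **Video compression** — spatio-temporal binning (4 × 4 pixels and
   4 frames), giving ≈1 mm spatial and 160 ms temporal resolution.
2. **Tracking** — per-pixel temporal-median background estimation,
   background-subtraction segmentation (8-connected components,
   intensity-weighted centroid), and gap-tolerant trajectory assembly.
3. **Trail metrics** — the distance from the ant's body centre to the trail
   segment; a sample is *on-trail* when that distance is strictly below
   5 mm; the response variable *y* is the distance walked on the trail
   (sum of step lengths whose endpoints are both on-trail). Group occupancy
   heatmaps accumulate the trajectories of all ants of a group.
4. **Statistics** — walking distances are transformed to *Y* = ln(*y* + 1);
   a one-way ANOVA tests the overall dependence on the preparation
   (*F* = MSB/MSW on (*k* − 1, *N* − *k*) df); Dunnett's many-to-one
   procedure compares each concentration against the control with
   family-wise error control; unpaired *t*-tests compare compounds at
   matched concentrations.

The Dunnett adjustment is computed from the multivariate-*t* distribution
with the product correlation structure of the common-control design,
evaluated by deterministic Gauss–Legendre quadrature (it agrees with
`multcomp::glht` to ~10⁻⁴ and costs microseconds per comparison, which makes
large Monte-Carlo calibrations practical).

## Worked example

Simulate one trail-attracted ant, render and track it, and compare the
recovered metrics with the ground truth:

```r
library(anttrail)

arena <- arena_config(width_mm = 160, height_mm = 90, px_per_mm = 2,
                      frame_rate_hz = 25, duration_s = 20)
trail <- trail_line(c(10, 45), c(150, 45))

truth   <- simulate_trajectory(walk_params(trail_attraction = 0.35, seed = 3),
                               arena, trail)
video   <- render_frames(truth, arena, render_params(), trail)
binned  <- bin_video(video, 4, 4)        # binned$frame_period_ms == 160
tracked <- build_trajectory(track_video(binned, seg_params()),
                            seg_params(), binned$frame_period_ms)

trail_distance(on_trail_series(tracked, trail))
#> # A tibble: 1 × 5
#>   total_path_mm on_trail_mm on_trail_fraction n_valid duration_s
#>           <dbl>       <dbl>             <dbl>   <int>      <dbl>
#> 1          376.        370.             0.984     125         20

trail_distance(on_trail_series(truth, trail))
#> # A tibble: 1 × 5
#>   total_path_mm on_trail_mm on_trail_fraction n_valid duration_s
#>           <dbl>       <dbl>             <dbl>   <int>      <dbl>
#> 1          380         374.             0.984     500         20
```

The tracked on-trail distance (370 mm) recovers the ground truth (374 mm)
to within 2 %. With a full experiment table, `run_experiment()` performs
the whole chain per ant and returns per-ant metrics, per-group heatmaps
(`autoplot()` renders the passage-probability map), and the statistical
battery:

```r
g <- simulate_group_distances(group_design(assay_groups(), n_per_group = 15,
                                           seed = 42))
one_way_anova(g)
#> One-way ANOVA on log1p-transformed distances: F(12, 182) = 1.193, p = 0.291
tidy(dunnett_vs_control(g))   # per-comparison estimates, adjusted p, stars
```

A thin command-line front end (`inst/cli/anttrail.R`) exposes the verbs
`run`, `fixtures`, `simulate` and `stats` over a YAML config.

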