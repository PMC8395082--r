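# dtctrack

Detect, Track and Colocalize: spot-based organelle association
analysis for two-channel 2D live-cell imaging.

Membrane contact sites and transient organelle interactions show up in
fluorescence time-lapse data as pairs of diffraction-limited spots
("dots") that approach each other, stay within contact range for a few
frames, and separate. `dtctrack` turns two-channel movies into
quantitative answers to three questions:

1. **How many dots are there, and how bright?** Threshold
   segmentation with 8-connected labeling and a circularity filter
   (`4πA/P² > 0.1`) that excludes tubular structures; per-dot,
   plasma-membrane-band, and per-area ROI intensity quantification.
2. **Are the two channels colocalized or merely close?** Object-based
   (centroid-distance) colocalization against the optical resolution
   limit `0.61·λ/NA/X` (146 nm → working limit 140 nm for GFP on an
   Airyscan-class system), and *association* calling in the closed
   window of 1–5 px (125–625 nm at 0.125 µm/px). The two states are
   mutually exclusive.
3. **How long do contacts last?** Nearest-neighbour tracking of
   channel-A dots under a maximum displacement of 10 px per frame
   (minimum track length 3 frames = 4 s at 2 s intervals), per-track
   association profiles against channel B, and run durations
   `(n_frames − 1)·Δt` with censoring flags at track boundaries.

A synthetic movie simulator with exact ground truth closes the loop:
the test suite demonstrates that the full pipeline inverts the
generative model (counts exact, centroids < 0.5 px RMS, planted
association runs recovered within ±1 frame at SNR 10). Nonparametric
statistics (Wilcoxon rank-sum, Kruskal–Wallis,
Dwass–Steel–Critchlow–Fligner with Monte-Carlo permutation p-values)
compare conditions.

## Worked example

```r
library(dtctrack)

opt <- optics_spec(lambda_em = 529, na = 1.3, airyscan_factor = 1.7)
resolution_limit(opt)
#> [1] 146.0136
resolution_limit(opt, floor_to_tens = TRUE)
#> [1] 140

# Simulate a two-channel movie with 3 planted association events,
# then run the full pipeline blind to the truth.
sim <- simulate_movie(simulation_config(
  image_size = 128, n_frames = 20, n_spots = 10, n_pairs = 3, seed = 7))
res <- dtc_run(sim$movie, analysis_config(threshold = 25))
str(res$summary[c("n_tracks", "n_runs", "mean_run_duration_s")])
#> List of 3
#>  $ n_tracks           : int 10
#>  $ n_runs             : int 3
#>  $ mean_run_duration_s: num 2.67

res$runs[, c("start_frame", "length_frames", "duration_s")]
#>   start_frame length_frames duration_s
#> 1          14             2          2
#> 2          16             2          2
#> 3           9             3          4

# The planted ground truth — recovered exactly:
emit_truth_tables(sim$truth)$runs[, c("start_frame", "length_frames",
                                      "duration_s")]
#>   start_frame length_frames duration_s
#> 1           9             3          4
#> 2          14             2          2
#> 3          16             2          2

# Condition comparison
g <- list(ctrl = c(5.1, 6.0, 4.8, 5.5), t1 = c(7.2, 8.1, 7.7, 6.9),
          t2 = c(5.0, 5.4, 6.1, 5.2))
kruskal_wallis(g)
#> kruskal-wallis: statistic = 7.423, p = 0.02444
dscf_montecarlo(g, n_iter = 2000, seed = 1)
#> dscf-montecarlo: statistic = 2.309, p = 0.07146
#>  group1 group2  statistic    p_value
#>    ctrl     t1 -2.3094011 0.07146427
#>    ctrl     t2 -0.2886751 0.99600200
#>      t1     t2  2.3094011 0.07146427
```

Real movies enter through `read_movie()` (multi-page 16-bit TIFF,
interleaved or split channels); `inst/scripts/dtc-tools` wraps the
same pipeline as a command line tool
(`dtc-tools simulate|detect|dtc|coloc|stats`).

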