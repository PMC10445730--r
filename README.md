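# perifish

Quantifies where a fluorescently labelled genomic locus sits relative to the
nuclear periphery, from 3-channel 3D fluorescence stacks: a DNA counterstain,
a DNA-FISH probe marking the locus, and an anti-lamin immunostain marking the
nuclear envelope. It is written for the common question in nuclear
organization — *is this locus tethered to the lamina, and does it move under
a perturbation?* — where the answer is a per-condition distribution of locus
positions, not a single number.

The pipeline:

1. **3D nucleus segmentation** — median filter (13×13×5 voxels),
   Otsu threshold, morphological dilation (5×5×3 box) so the mask covers the
   lamin shell, then 26-connected instance labelling.
2. **Spot detection** — Difference of Gaussians
   (DoG = G(σ₁)∗I − G(σ₂)∗I, σ₂ = 1.6 σ₁), strict 26-neighbourhood maxima
   above a robust threshold, refined to sub-voxel precision by a local 3D
   centre of mass. The same detector in a dense mode samples the lamin shell
   as a per-nucleus point cloud.
3. **Distance readouts** — either the 3D shortest Euclidean distance (µm)
   from each locus to its nucleus's lamin point cloud,
   d = min₍c∈cloud₎ ‖x − c‖ after per-axis rescaling by the voxel size, or a
   2D normalized radial position: the Euclidean distance transform of a
   closed-spline nucleus contour divided by its per-nucleus maximum, giving
   0 at the periphery and 1 at the centre.
4. **Reporting** — probability-density histograms whose bars sum to one, and
   descriptive two-condition comparisons (n, median, mean, difference of
   medians) with ggplot2 `autoplot()` methods.

A synthetic-scene generator renders nuclei, lamin shells and probe spots with
exact ground truth (positions, radial coordinates, analytic surface
distances), so every stage of the pipeline is testable end to end. See the
vignette `vignettes/periphery-quantification.Rmd` for the model, parameter
defaults and their rationale.

## Worked example

Simulate a small scene with known spot positions, run the 3D readout, and
summarise:

```r
library(perifish)

spec   <- draw_spots_spec(n_nuclei = 4, spots_per_nucleus = 2,
                          r_mean = 0.2, r_sd = 0.05, amplitude = 500, seed = 2)
params <- scene_params(shape_zyx = c(24, 160, 160), n_nuclei = 4,
                       spots_spec = spec, seed = 1)
scene  <- generate_scene(params)

nuclei <- segment_nuclei(scene$stack)
#> <labeled_nuclei> 4 nuclei, Otsu threshold 46.31

spots  <- localize_spots(scene$stack, "probe", nuclei,
                         dog_params(sigma_small_zyx =
                                      params$psf_sigma_um / params$voxel_size_zyx))
cloud  <- lamin_point_cloud(scene$stack, nuclei)
records <- spot_lamin_distances(spots, cloud, condition = "control")
records
#> # A tibble: 8 × 4
#>   nucleus  spot distance_3d_um condition
#>     <int> <int>          <dbl> <chr>
#> 1       4     1          0.344 control
#> 2       2     2          0.316 control
#> 3       1     3          0.385 control
#> 4       4     4          0.360 control
#> 5       2     5          0.550 control
#> 6       1     6          0.510 control
#> 7       3     7          0.371 control
#> 8       3     8          0.269 control
```

All 8 requested spots (2 per nucleus, placed at normalized radial position
≈ 0.2, i.e. near the periphery of ~2 µm nuclei) are recovered with distances
of 0.27–0.55 µm from the lamina. The distribution as a
probability-density histogram:

```r
h <- pdf_histogram(records$distance_3d_um,
                   bin_edges = fd_bin_edges(records$distance_3d_um))
h
#> <pdf_histogram> 8 observations, 4 bins, sum of heights = 1
#> # A tibble: 4 × 4
#>   bin_lo bin_hi count height
#> *  <dbl>  <dbl> <int>  <dbl>
#> 1  0.269  0.349     3  0.375
#> 2  0.349  0.428     3  0.375
#> 3  0.428  0.507     0  0
#> 4  0.507  0.587     2  0.25
autoplot(h)
```

Bar heights are counts over the total, so they sum to exactly one. For a
two-condition experiment, run the pipeline once per condition and compare:

```r
res_a <- run_pipeline(list(condition = "control", seed = 1, readout = "2d",
                           scene = list(spots = list(spots_per_nucleus = 10,
                                                     r_mean = 0.15, r_sd = 0.05))))
res_b <- run_pipeline(list(condition = "knockdown", seed = 2, readout = "2d",
                           scene = list(spots = list(spots_per_nucleus = 10,
                                                     r_mean = 0.45, r_sd = 0.05))))
compare_conditions(tidy(res_a), tidy(res_b), labels = c("control", "knockdown"))
```

A command-line wrapper with `simulate` / `segment` / `spots` / `distance3d` /
`radial2d` / `pdf` / `run` subcommands is installed at
`system.file("cli", "perifish", package = "perifish")`.

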