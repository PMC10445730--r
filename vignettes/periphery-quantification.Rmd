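---
title: "Quantifying locus position relative to the nuclear periphery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locus position relative to the nuclear periphery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perifish)
```

## The measurement

Genes tethered to the nuclear lamina tend to be repressed, and their release
from the periphery accompanies activation. DNA FISH against a locus, combined
with an anti-lamin immunostain, lets one measure this directly: in each
nucleus the labelled locus appears as a diffraction-limited dot, and the
lamina as a thin bright shell. perifish turns 3-channel 3D stacks
(DNA counterstain, FISH probe, lamin) into per-locus position readouts and
per-condition probability-density histograms.

Two readouts are implemented, because both are in routine use and they answer
slightly different questions:

* **3D shortest distance (µm).** Nuclei are segmented in 3D; dots are
  detected in the probe and lamin channels; each probe spot is scored by the
  Euclidean distance to the nearest detected lamin point of its own nucleus,
  after rescaling voxel indices by the physical voxel size per axis. This is
  an absolute distance, unaffected by nucleus size, but it needs a
  well-resolved z axis.
* **2D normalized radial position.** A closed cubic spline (five or more
  control points) is traced around each nucleus on the maximum projection,
  rasterized to a mask, and the Euclidean distance transform of the mask —
  distance of each pixel to the segmentation contour — is divided by its
  per-nucleus maximum. The resulting map runs from 0 at the periphery to
  exactly 1 at the deepest interior point, and each spot is scored by
  bilinear interpolation at its (y, x) coordinate. This readout is
  dimensionless and comparable across nuclei of different sizes, but, being a
  projection, it compresses positions toward the centre: a spot at 3D radial
  position $r$ along a random direction projects to a 2D position that is
  closer to 1 than $r$ on average (by a factor $\pi/4$ on the peripheral
  offset, for a sphere). Comparisons between conditions are unaffected
  because the compression applies to both; absolute 2D values should not be
  read as 3D positions.

Distributions are presented as probability-density histograms in which bar
heights are counts divided by the total, so the bars of each plot sum to
exactly one — a probability mass per bin, not a density per unit length.
No hypothesis test is attached to the two-condition comparison; the output is
the pair of histograms plus n, median, mean and the difference of medians.

## Segmentation

The automatic 3D segmentation is a deliberately simple, classical chain:

1. **Median filter**, default window 13×13×5 voxels (x, y, z) — fine in
   plane, coarse axially, matching anisotropic voxels. Borders are handled by
   symmetric reflection, which avoids the edge darkening a zero pad would
   introduce and that would bias the global threshold. The filter is exact:
   an integer-histogram sliding implementation is used when the volume is
   integer-valued (the common case for camera counts) and a sort-based path
   otherwise; both agree with a brute-force per-voxel median to the last bit,
   and the tests enforce this.
2. **Otsu threshold** over a 256-bin equal-width histogram, maximizing the
   between-class variance; binarization is `voxel > threshold`. Ties are
   broken toward the lowest qualifying threshold, which makes the result
   deterministic. A constant volume has no separable classes and raises an
   explicit error rather than returning an arbitrary value.
3. **Morphological dilation** with a 5×5×3 box (x, y, z). The DNA
   counterstain fills the nucleoplasm but the lamin shell sits just outside
   it; the dilation grows the mask slightly so that the shell voxels fall
   inside the mask and lamin detections can be assigned to their nucleus.
4. **26-connected component labelling**, discarding components below
   `min_nucleus_voxels` (default 1000, the volume of a ~1 µm-radius sphere at
   the default voxel sizes) as speckle. Labels are consecutive integers in
   scan order. Touching nuclei merge into one label; no watershed splitting
   is attempted, and scenes are expected to provide (or the simulator
   enforces) inter-nucleus gaps larger than the dilation extent.

The channel that is segmented is configurable and defaults to the DNA
counterstain: growing the mask "to cover the lamin" only makes sense if the
mask was not derived from the lamin channel itself.

## Spot detection and refinement

Dots are detected as local maxima of a Difference-of-Gaussians band-pass,
`G(σ_small) − G(σ_large)`, computed with separable Gaussian blurs per axis so
the anisotropic z step is handled naturally. Defaults: `σ_small` equals the
PSF sigma expressed in voxels, `σ_large = 1.6 σ_small` (the classic blob
ratio). The response threshold defaults to `median + k·MAD` of the response
(k = 6), a robust background estimate that adapts to the noise level.
Candidates are strict 26-neighbourhood maxima, sorted by descending response;
detection is fully deterministic.

Each candidate is refined to sub-voxel precision by the intensity-weighted
centroid of an odd window centred on the detection voxel (default
`2·⌈2σ_small⌉+1` per axis). The window minimum is subtracted before
weighting: a centre of mass on raw counts under uniform background is biased
toward the window centre. A window with zero mass after subtraction returns
the unrefined coordinate, flagged. Physical coordinates are the 0-based
refined voxel index times the per-axis voxel size (voxel-centre convention);
nucleus assignment uses the label at the integer detection voxel, which
avoids ambiguity when the sub-voxel shift crosses a label boundary. Spots
with label 0 are reported but excluded from distance analysis.

The lamin channel uses the same detector in a different regime. A smooth
shell has almost no strict local maxima — tangentially the response is flat —
so `candidate_mode = "dense"` keeps *every* voxel whose response clears the
threshold, turning the shell into a cloud of thousands of points ("any dot"
along the lamina). Two details matter here:

* the centre-of-mass window for these points is small (3×5×5): a
  σ-derived window averages over the curved shell and drags points toward
  the nucleus interior, which systematically shortens distances for
  interior loci;
* in dense mode the automatic threshold is floored at
  `median + 0.1·(max − median)` of the response. On low-noise data the MAD
  collapses toward zero and a pure `median + k·MAD` rule would admit the
  faint inner side-lobe of the band-pass around the shell, again placing
  points inside the nucleus. The relative floor removes that halo while the
  shell, whose response is far above 10 % of the peak, stays densely
  sampled. Nuclei with no lamin point are excluded from 3D distances and
  reported.

## The synthetic scene generator

Every stage is validated against simulated scenes with exact ground truth.
The generator emulates what matters for this pipeline on early-embryo
material: near-ellipsoidal nuclei, densely placed but non-overlapping
(placement is rejection-sampled with a bounded number of re-draws and a
minimum surface gap, 0.8 µm by default); a thin bright lamin shell (0.2 µm)
centred on each ellipsoid surface; one or two probe spots per nucleus at
*requested* normalized radial positions along random directions; anisotropic
voxels (defaults 0.1 µm in x/y, 0.3 µm in z, a 100× oil objective with a
typical z step — the acquisition itself does not fix these values, so they
are configurable, never asserted); Poisson shot noise over a uniform
background plus Gaussian read noise, quantized to 16-bit counts, the sCMOS
model. Nucleus semi-axes default to 1.6–2.2 µm, the scale of a blastoderm
nucleus; markedly smaller nuclei would not survive a 13×13×5 median filter
intact, which is a property of the method, not of the simulator.

Ground truth records each spot's exact position, its requested normalized
radial position r (1 = centre, 0 = boundary) and its exact Euclidean distance
to the ellipsoid surface, computed from the Lagrange condition of the
point-to-ellipsoid projection (closed form for spheres, bracketed root search
otherwise; the spherical identity `shell distance = r · radius` is asserted
to 1e-9 µm in the tests).

Deliberate simplifications: the PSF is applied only to point sources (the
probe spots are rendered as anisotropic Gaussians); the interior and shell
are rendered at their apparent sizes with sharp edges. There is no optical
sectioning or defocus model, no chromatic aberration, no embryo curvature,
no mitotic figures, and nuclei are perfect ellipsoids. Passing recovery
tests therefore demonstrates the correctness of the measurement chain —
segmentation, detection, refinement, distance computation, normalization —
not robustness to every artefact of real embryo stacks; on real data the
thresholds and sigmas exposed in the configuration are the knobs that absorb
those differences.

Scales used in the validation suite: the full-scale recovery scenes are
256×256×32 voxels with 10 nuclei (peak-SNR ≈ 20 for the noisy variant), the
distance-recovery scenes 224×224×32 with 8 spherical nuclei, and the
two-condition comparison uses 100 spots per condition (10 nuclei × 10 spots)
with true normalized positions drawn around 0.15 (peripheral, "tethered")
versus 0.45 ("released"). On these scenes every ground-truth spot is
recovered within one voxel, the noiseless RMS localization error is about
0.03 voxels, the worst-case 3D distance error is well under one in-plane
voxel, the mean 2D normalized-position error on disk ROIs is below 0.01, and
the recovered medians of the two conditions separate by more than 0.2 in the
correct direction. `scripts/acceptance.R` recomputes all of these from
scratch.

## Numerical choices and edge cases

* **Otsu ties** go to the lowest maximizing threshold; the returned value is
  the upper edge of the chosen histogram bin.
* **Spline ROIs** use a natural periodic cubic through the control points
  with uniform parameterization, densified to ≥ 8 samples per pixel of arc
  before scanline filling (even–odd rule on pixel centres). Self-intersecting
  curves are rejected with an error naming the nucleus.
* **Distance-map lookups** are bilinear, with a nearest-pixel fallback where
  one of the four neighbours is background; a spot outside its ROI mask is an
  error, not a silent NA.
* **Histogram bins** default to 20 uniform bins on [0, 1] for normalized
  positions and Freedman–Diaconis for micrometre distances.
* **Determinism**: every stochastic step (placement, spot directions, noise)
  runs under a caller-supplied seed, and the caller's RNG state is restored
  afterwards; re-running a pipeline with the same config and seed reproduces
  the distance table byte for byte.
* **Degenerate inputs** fail loudly and early: constant volumes in Otsu,
  empty masks in the distance transform, empty point clouds in the 3D
  distance, nuclei without lamin points (excluded and reported).

## Known limitations

Touching nuclei are not split; the 2D readout inherits the projection
compression described above; the 3D readout depends on the lamin staining
being dense enough that the nearest detected dot approximates the nearest
point of the lamina; and the simulator's idealizations mean that parameter
defaults, while sensible starting points, are not a substitute for inspecting
segmentation masks and detections on real stacks (`max_project_composite()`
exists for exactly that).
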