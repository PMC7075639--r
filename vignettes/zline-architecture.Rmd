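---
title: "Quantifying sarcomeric z-line architecture with zlinekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcomeric z-line architecture with zlinekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zlinekit)
```

## The measurement problem

In striated myocytes the z-lines anchor the actin thin filaments of
adjacent sarcomeres; force is produced approximately perpendicular to
them. α-actinin immunostains visualize z-lines as short striations
perpendicular to the myofibril (actin) direction, but the same protein
also decorates immature stress fibers and cell boundaries, where the
staining runs *parallel* to actin. Any orientation statistic computed on
the raw stain therefore mixes two very different structures. `zlinekit`
separates them using the actin co-stain and then summarizes the isolated
z-lines with a small set of scalar metrics.

All orientations in the package are *nematic*: θ and θ + π describe the
same structure, and every angle is canonicalized to [0, π). Angles are
measured counter-clockwise from the image x (column) axis in a y-up frame;
the raster row direction is converted internally. Every metric is invariant
under θ → θ + π, which the test suite checks by property.

## Skeleton extraction

The α-actinin channel is rescaled to unit maximum and passed through:

1. **Coherence-enhancing anisotropic diffusion.** Per pixel the structure
   tensor (Gaussian-smoothed outer product of intensity gradients, gradient
   scale σ, tensor scale ρ) is eigendecomposed. Diffusivity across the
   dominant-gradient direction is a small constant α; along the coherent
   (ridge) direction it grows toward 1 with the eigenvalue gap,
   λ₂ = α + (1 − α)·exp(−C/(μ₁ − μ₂)²). Integration is an explicit
   central-difference scheme in divergence form with replicate boundaries.
   With diffusivities bounded by 1 the scheme is stable for time steps
   dt ≤ 0.25; the constructor enforces this and the default is dt = 0.2.
   Defaults: time 3, σ = 0.5 px, ρ = 4 px, α = 0.05, C = 10⁻⁶. Diffusion
   time is the single most consequential parameter for downstream
   continuous-line lengths (too much smoothing fuses striations, too
   little fragments them), which is why the tuning module selects it
   against reference traces rather than hard-coding a universal value.
2. **White top-hat** (disc radius 6 px ≈ 1 μm): keeps bright structures
   thinner than the disc — striations — and removes broad blobs.
3. **Background surface removal**: a 10th-percentile estimate per
   32 px block, interpolated bilinearly (linear extrapolation at the
   borders) and subtracted, clipping at zero. The low percentile makes the
   estimate insensitive to sparse bright foreground; its cost is a small
   uniform under-subtraction, which the adaptive threshold absorbs.
4. **Adaptive thresholding**: pixel > local mean + offset over a
   49 px window (roughly four sarcomere spacings at 6 px/μm, so the window
   always contains both striations and gaps), offset 0.01.
5. **Thinning and trimming**: Zhang–Suen topology-preserving thinning,
   removal of residual 2×2 blocks (deleting only simple points), pruning
   of dangling branches strictly shorter than 4 px that terminate at a
   branch point, a final thinning pass to clean the pixels where a pruned
   spur met the line diagonally, and removal of connected components
   smaller than 4 px. Bare segments are never pruned, so isolated short
   z-lines survive. Closed loops are left intact by the pruning (only
   endpoint-rooted branches are traced).

Per-pixel orientation is estimated from the *diffusion-filtered* image by
the least-mean-square/structure-tensor estimator: gradient products are
summed over a 9 px window and the ridge orientation is the
dominant-gradient direction rotated by π/2. Windows whose gradient energy
falls below 1% of the image maximum are marked invalid and excluded from
every downstream computation — flat regions carry no orientation.

A note on exactness: thinning resolves a ridge of even width to one of its
two central pixel columns, and which column it picks depends on the scan
direction. Rotating an image by 90° therefore reproduces the skeleton only
up to a one-pixel lateral ambiguity; the test suite checks rotation
equivariance with a 1 px tolerance-F1 of 0.95 rather than bit equality,
while the orientation field itself rotates exactly.

## Actin-guided segmentation

The actin channel is Gaussian-filtered (σ = 1.5 px), normalized to zero
mean and unit standard deviation, and its orientation field estimated as
above. The image is tiled into non-overlapping 5 μm grid tiles (≈ 30 px;
the scale of two sarcomeres) anchored at the image origin; edge tiles may
be partial and are used as-is. Per tile the mean nematic tensor

T = ⟨ 2 r rᵀ − I ⟩,  r = (cos θ, sin θ)

is averaged over the valid actin pixels; the *director* is the eigenvector
of its maximum eigenvalue. In 2-D this reduces to closed form: the maximum
eigenvalue is √(⟨cos 2θ⟩² + ⟨sin 2θ⟩²) and the director angle is
½·atan2(⟨sin 2θ⟩, ⟨cos 2θ⟩).

Each skeleton pixel is scored against its tile's director:

γ = |cos(θ_actin − θ_zline)| ∈ [0, 1].

The absolute value enforces nematic symmetry — the underlying unit
pseudo-vectors have an arbitrary sign, so a signed dot product would be
ambiguous. Pixels with γ ≥ 0.7 are classified off-target (too parallel to
actin); γ < 0.7 z-line. The boundary case γ = 0.7 is off-target. Pixels in
tiles with no valid actin, in tiles whose tensor is degenerate (maximum
eigenvalue ≈ 0, e.g. equal mass at two perpendicular orientations), or
without a valid own orientation are left *unassigned* and excluded from
both counts: there is no evidence to classify them, and counting them only
in the denominator would bias the z-line fraction downward.

The **z-line fraction** is N_z / N_α over the assigned pixels: 1 when every
skeleton pixel is approximately perpendicular to its local actin, 0 when
none is, and undefined (reported as missing, never 0) when nothing could
be assigned. Lowering the threshold can only shrink N_z — monotonicity that
the tests verify by property, along with exact agreement with a
brute-force per-pixel reclassification oracle on small images.

Without an actin channel the two metrics cannot be decoupled: the tool
then reports the plain α-actinin OOP, computes striation lengths on the
unsegmented skeleton, and leaves the z-line fraction missing.

## Continuous z-lines

Each z-line pixel has eight neighbors. The two lying in the compass
directions nearest to θ ± π/2 — perpendicular to the z-line — are excluded,
leaving at most six *candidate neighbors* (ties at exactly 22.5° round
half-up, deterministically). Candidates split into two half-planes along
±θ; in each half the occupied candidate with the largest |cos Δθ| is
preferred, ties going to the straighter geometric continuation and then to
the lexicographically smaller coordinate. A link is kept only when the
preference is mutual. Mutual best-matching guarantees vertex degree ≤ 2,
so groups are simple paths (or, rarely, cycles, which are broken at the
link with the smallest |cos Δθ|); the canonical grouping rule follows:
collinear 7-pixel segments offset laterally by one pixel merge into one
line, an offset of two or more always splits. True three-way junctions
cannot occur under mutual linking; the losing branch simply starts its own
line, which is logged implicitly by the partition. Every z-line pixel ends
up in exactly one line, an invariant the tests check against an exhaustive
mutual-link enumeration oracle.

Both the pixel count and the Euclidean path length of each line are first
class: pixel counts match the synthetic-validation convention, micrometre
lengths (path length / resolution) feed the reported medians. The median —
not the mean — summarizes the strongly skewed length distributions of real
tissue; lines below 2 px are excluded from the median by default.

## Other metrics

- **OOP**: maximum eigenvalue of T over any orientation set; 1 = aligned,
  0 = isotropic. Pooled (coverslip) OOPs are recomputed from concatenated
  angle lists, never by averaging per-field eigenvalues.
- **Stress estimate**: σ̃x = Σ cos²(θᵢ + π/2)/N_T over z-line pixels,
  with N_T the pixel count of the cell area. Images are assumed
  pre-aligned with the major axis along x; `major_axis_deg` rotates the
  frame otherwise. In tissue mode no cell mask exists and N_T defaults to
  the full image area, making σ̃x comparable only across equal-sized
  fields. 0 ≤ σ̃x ≤ N_z/N_T with equality at parallel/perpendicular
  extremes.
- **Sarcomere spacing**: per populated grid tile, z-line pixel positions
  are projected onto the actin director; projections are binned at 1 px
  and the spacing is the first local autocorrelation maximum at lag ≥ 4 px
  with height ≥ 30% of the zero-lag value. Tiles with fewer than two
  pixels or no qualifying peak are skipped, so random scatter produces no
  spurious spacing. The autocorrelation choice is ours; alternatives
  (e.g. Fourier peaks) would serve equally, but autocorrelation of the
  binned point set is robust to the small per-tile counts.
- **Nuclei**: Gaussian blur, Otsu threshold, hole filling, watershed
  splitting of touching nuclei, area floor 30 px; density is the summed
  count over the summed field area (per mm²), pooled per coverslip.

Pooling across fields (`aggregate_report`) always recomputes from raw
counts, angles and lengths — medians and eigenvalues do not average.

## Parameter tuning

`skeleton_similarity` scores two skeletons by tolerance-F1: pixels match
within Chebyshev distance 1 (configurable), matches are one-to-one, and
S = 2·matches/(|a| + |b|). One-to-one matching is computed as a maximum
bipartite matching, which makes S exactly symmetric and independent of
operand order — a greedy scan cannot guarantee that. Multiple tracers per
image are averaged at the S level. `parameter_error` turns a similarity
matrix into E_p = (1/n)Σᵢ(S_{i,p} − S_{i,max})², and `grid_search` runs the
preprocessing chain over a declared parameter grid and returns the
argmin (first row on ties, so results are reproducible for a fixed grid
order).

## Synthetic data: what it does and does not show

`make_segment_fixture` renders the segment constructions used to validate
the continuity rule: n segments of exactly `segment_len_px` pixels
(one pixel per step of the dominant raster axis, so rotation never changes
the per-segment pixel count), laterally shifted, with ground-truth
grouping derived from the rasterized junction adjacency — at rotation 0
this is exactly "shift ≤ 1 px merges, ≥ 2 px splits".

`make_tissue_phantom` emulates the two-channel image model of α-actinin
stained tissue: actin fibrils as periodic stripes at 1 μm pitch (a typical
myofibril width) along a constant or smoothly varying direction field;
myofibril bands of the z-line length (2 μm default) stacked across the
fibrils; mature bands carry z-line bars perpendicular to the fibrils on a
2 μm sarcomere lattice, laterally registered across bands up to a 1 px
jitter; immature bands carry a fibril-parallel off-target line. The
declared off-target fraction is realized exactly in band counts (randomly
placed). Both channels receive a Gaussian PSF (σ = 1 px), Poisson shot
noise (200 photons at unit intensity) and Gaussian read noise (σ = 0.01),
all under a mandatory seed; truth masks stay unblurred.

The phantoms exercise every pipeline stage at realistic geometry and
noise, but they are not photorealistic microscopy: no uneven illumination
beyond the background model, no out-of-focus fibroblast actin above or
below the monolayer, no 3-D effects, no staining variability. Passing the
phantom-recovery tests therefore demonstrates correctness of the
algorithms under the stated image model, not performance bounds on
arbitrary real data — for real images the tuning module against manual
traces is the intended calibration path.

Problem sizes used in the shipped tests: phantoms of 96–192 px (16–32 μm)
fields, fixtures of tens of pixels, and oracle comparisons on ≤ 64×64
grids; these sizes keep the whole suite fast while covering several grid
tiles and dozens of z-lines per phantom.

## Degenerate inputs and numerical choices

Constant images diffuse to themselves and yield empty skeletons with a
warning; empty inputs produce missing metrics, never silent zeros. Flat
orientation windows are invalid rather than NaN. Ties in compass rounding
and in link preference are broken deterministically (round half-up;
straighter continuation; lexicographic order), and every pipeline stage is
deterministic given its inputs, so identical runs produce byte-identical
skeletons and reports — the config hash recorded with every report makes
that provenance checkable.

## Limitations

Actin-guided segmentation assumes the actin in a tile belongs to the
myocyte being measured; fibroblast actin above or below a monolayer
misleads it. The stress estimate ignores continuity and registration
(each z-line pixel contributes independently). Lateral *registration*
lengths across gaps — as opposed to the strict continuity measured here —
are out of scope, as are confocal z-stacks and temporal linking across
video frames (frame-by-frame batch analysis works through the manifest
interface).
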