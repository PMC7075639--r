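# zlinekit

Automated detection and quantification of sarcomeric z-line architecture
in fluorescence micrographs of striated myocytes.

## The problem

Sarcomeres — the contractile units of cardiac and skeletal muscle — produce
force approximately perpendicular to their z-lines, the structures that
couple parallel myofibrils and give striated muscle its banded appearance.
Z-line architecture is routinely assessed by immunostaining the z-line
protein α-actinin, but α-actinin also accumulates *off target* along
immature stress fibers and cell boundaries, where it runs **parallel** to
the actin fibrils instead of perpendicular to them. Manual tracing and
manual removal of off-target staining is slow and observer-dependent.

`zlinekit` automates the whole analysis for researchers imaging z-lines at
~6 pixels/μm with an actin co-stain:

1. **Skeleton extraction** — coherence-enhancing anisotropic diffusion,
   white top-hat contrast enhancement, background-surface removal,
   adaptive thresholding, topology-preserving thinning and trimming give a
   one-pixel-wide α-actinin skeleton plus a per-pixel orientation field
   (structure-tensor / least-mean-square estimation).
2. **Actin-guided segmentation** — per ~5 μm grid tile the actin
   *director* is the eigenvector of the maximum eigenvalue of the mean
   nematic tensor **T** = ⟨2 **r r**ᵀ − **I**⟩ over actin unit vectors
   **r** = (cos θ, sin θ). Each skeleton pixel is scored by
   γ = |cos(θ_actin − θ_pixel)|; pixels with γ ≥ 0.7 (parallel to actin)
   are off-target, the rest are z-lines.
3. **Metrics** —
   - *orientational order parameter* (OOP): the maximum eigenvalue of
     **T** over the z-line orientations (1 = perfectly aligned,
     0 = isotropic);
   - *z-line fraction* = N_z / N_α, the fraction of the skeleton that
     survives segmentation (how little off-target staining the image has);
   - *continuous z-line lengths*: skeleton pixels are linked through six
     orientation-selected candidate neighbors (the two perpendicular
     compass directions are excluded; mutual best matches by
     |cos Δθ| are kept) and grouped into lines; a lateral offset of one
     pixel between segments is continuous, two or more is not. The median
     length summarizes the skewed distribution;
   - *sarcomere spacing*: first off-origin autocorrelation peak of z-line
     positions projected onto the local actin director;
   - *stress estimate* along the cell's major axis,
     σ̃x = Σᵢ cos²(θᵢ + π/2) / N_T;
   - *nuclei density* per mm², pooled over all fields of a coverslip.

Without an actin co-stain the tool degrades gracefully: it reports the
plain α-actinin OOP and striation lengths, and the z-line fraction is
reported as missing.

## Worked example

All inputs can be synthesized with ground truth, so the example is fully
reproducible:

```r
library(zlinekit)

phantom <- make_tissue_phantom(
  phantom_spec(size = 192, seed = 42, offtarget_fraction = 0.3))
analysis <- run_image(phantom$actinin, phantom$actin, image_id = "demo")
analysis$report
#> <zline_report> demo
#>   z-line OOP        0.9809
#>   alpha-actinin OOP 0.3541
#>   z-line fraction   0.6835  (N_z = 2041, N_alpha = 2986)
#>   median CZL        5.54 um
#>   sigma_x           0.05483
#>   sarcomere spacing 2 um (median of 36 tiles)
```

Reading the numbers: roughly 30% of the generated α-actinin skeleton is
off-target staining parallel to the fibrils, and the measured z-line
fraction 0.68 recovers that. The isolated z-lines are highly ordered
(OOP 0.98) even though the raw α-actinin OOP (0.35) is dragged down by the
off-target pixels — exactly the decoupling the segmentation exists for.
The 2 μm sarcomere spacing matches the generative lattice. `plot(analysis)`
overlays z-lines (red) and off-target staining (blue).

Batch analysis of real images goes through `run_image()` /
`run_coverslip()` or the command-line wrapper:

```sh
Rscript inst/cli/zlinekit.R run --manifest fields.csv --out results/
Rscript inst/cli/zlinekit.R synth phantom --seed 7 --out phantom/
Rscript inst/cli/zlinekit.R tune --manifest tune.csv --grid grid.yaml --out tuned/
```

Preprocessing parameters can be selected against manually traced
references with `grid_search()`, which minimizes the mean squared
shortfall E_p = (1/n) Σᵢ (S_{i,p} − S_{i,max})² of a tolerance-based
skeleton similarity score.

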