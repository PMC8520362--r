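# sonokr

Kernel-regression reconstruction of freehand 3D ultrasound volumes, with
clock-face morphometry of the anal sphincter complex and two-group
statistical comparison.

## What it does, and for whom

Freehand 3D ultrasound produces scattered intensity samples — positions
`X_i` (mm) with values `Y_i = r(X_i) + eps_i` — rather than a regular
volume. `sonokr` estimates the unknown field `r` on a voxel grid by
local polynomial kernel regression: around each voxel centre `X` the
field is expanded to order *N* and the coefficients minimize the
Gaussian-kernel-weighted least squares

    sum_i ( Y_i - x_i' beta )^2 * K((X_i - X)/h),
    K(u) = exp(-||u||^2 / (2 h^2)),

where `x_i` are the monomials of `X_i - X` up to degree *N* (default
*N* = 1, a local plane) and `h` is the bandwidth (mm). The intercept
`beta_0` is the estimate `r_hat(X)`. The kernel is truncated at `3h`
behind a spatial index, sparse neighbourhoods degrade the order
`2 -> 1 -> 0`, and voxels with no sample in support are flagged missing.

On top of the reconstruction the package implements the pelvic-floor
measurement protocol used to compare delivery modes in primiparae:
axial planes at fixed canal fractions (distal/mid/proximal), wall
thickness of the internal anal sphincter (IAS), external anal sphincter
(EAS) and puborectalis muscle (PRM) along clock-face rays by a
generalized full-width-at-half-maximum rule, and per-site
independent-sample t-tests (Welch or pooled) from raw values or
published mean/SD/n cells. A digital phantom of the sphincter complex
with exact ground truth drives validation end to end. The intended
audience is researchers prototyping freehand-3D-US reconstruction and
pelvic-floor morphometry pipelines.

## Worked example

Simulate a phantom acquisition, reconstruct, and measure the protocol
(a reduced-scale run; the full study uses 2e5 samples on a 0.2 mm
grid):

```r
library(sonokr)

gt    <- make_phantom(phantom_spec())        # IAS/EAS/PRM, known truth
cloud <- sample_cloud(gt, n = 60000, noise_sd = 5, seed = 11)
grid  <- phantom_grid(gt, spacing = 0.4)
rec   <- reconstruct_volume(cloud, grid, kernel_spec(0.6, order = 1))
rec$report
#> reconstruction: 60000 points -> 729904 voxels (0 missing)
#>   h = 0.6 mm, order 1, neighbours min/median/max 1/30/61

th <- measure_complex(rec$volume, list(center = gt$center))
head(th[, c("structure", "plane", "clock", "thickness_mm")], 6)
#>   structure    plane clock thickness_mm
#> 1       IAS proximal     3         2.06
#> 2       IAS      mid     3         2.12
#> 3       IAS   distal     3         2.07
#> 4       IAS proximal     6         1.87
#> 5       IAS      mid     6         1.91
#> 6       IAS   distal     6         1.99
```

The true wall thicknesses are IAS 2 mm, EAS 2 mm, PRM 7 mm; the
measured values recover them to about a tenth of a millimetre at this
scale. Reproduce the published group comparison from the bundled
summary tables (cells whose printed t cannot be recomputed from their
own mean/SD/n are marked `consistent = FALSE` and excluded):

```r
tab    <- delivery_tables()
report <- compare_table(tab[tab$consistent, ])
report[report$significant, c("site", "t", "df", "p_label")]
#>                     site          t       df p_label
#>   IAS proximal 6 o'clock  -2.398083 141.4610    0.02
#>  IAS proximal 12 o'clock  -2.718584 152.6115   <0.01
#>        IAS mid 9 o'clock  -2.232002 152.0513    0.03
#>       IAS mid 12 o'clock  -3.750042 152.1028   <0.01
#>    EAS distal 12 o'clock -12.070888 115.9564   <0.01
```

Exactly the five sites reported as significant come out significant at
alpha = 0.05, with negative t because the vaginal-delivery group
(group 1) has the thinner walls. A single cell from summary statistics:

```r
t_from_summary(group_summary("vaginal delivery",  1.04, 0.27, 77),
               group_summary("Caesarean section", 1.87, 0.55, 80))
#> welch two-sample t-test: t = -12.07, df = 116, p = <0.01 *
```

A command-line front end covers the same pipeline
(`simulate`, `reconstruct`, `measure`, `compare`, `pipeline`):

```sh
Rscript inst/cli/sonokr pipeline --outdir run1 --n 60000 --spacing 0.4 \
    --bandwidth 0.6 --seed 11
```

writing `cloud.csv`, `vol.nii.gz` (+ mask), `thickness.csv`,
`report.csv` and a JSON run manifest.

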