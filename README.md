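# xylotomo

Xylogenesis (wood-formation) phenology from X-ray CT gray-value profiles of
wood microcores.

## The problem

Monitoring how a tree ring forms through a growing season classically means
biweekly microcores, histological sectioning, staining and manual microscopy.
High-resolution X-ray computed tomography (HRXCT) offers a faster route: CT
gray values are linearly related to material density, so the radial profile
of mean *cell-wall* gray value across a forming ring carries the signature of
wall maturation. Within the maturing xylem the secondary wall is still being
deposited and lignified, so cell-wall density — hence gray value — rises with
distance from the cambium; in mature xylem the wall is complete and its basic
density (~1.4–1.5 g/cm³) is constant. The profile is therefore two-phased:

* a minimum at the cambium (thin primary walls),
* a monotone rise across the maturing zone,
* a plateau across the mature zone, out to the previous ring boundary.

`xylotomo` turns that observation into measurements and seasonal statistics:

1. **Profile extraction** — two-pass thresholding of each tangential slice of
   a volume of interest (Otsu sample/background split with hole filling, then
   a per-slice Otsu wall/lumen split) gives the *xylem* and *cell-wall* radial
   gray profiles.
2. **Boundary detection** — a penalized B-spline is fitted to the cell-wall
   profile; where the pointwise 95% confidence band of its derivative
   contains zero the profile is flat. The cambium is the median of the flat
   part at the density minimum; the maturing→mature transition is the
   bark-ward edge of the flat part closest to the cambium (refined by a
   broken-stick fit). Widths follow: `w_incr = boundary − cambium`,
   `w_mat = w_incr − w_maturing`.
3. **Phenology** — per-tree seasonal width series, corrected for
   circumferential heterogeneity (`w_cor = w_obs · w_prev / mean(w_prev)`),
   are fitted with monotone-increasing P-splines. Critical dates `tb`/`te`
   are the days the curve first reaches 5%/95% of the final width (median
   prediction of the last three sampling dates); durations `d = te − tb`,
   mean rates `r = (we − wb)/(te − tb)`, whole-xylogenesis duration
   `d_xylo = te_mat − tb_incr`.
4. **Biomass dynamics** — `b_trunk`, the summed xylem-profile gray over the
   forming ring, proxies accumulated biomass. Completion curves (normalized
   to the late-season median) give the time lag between size growth and
   biomass production at each completion fraction 0, 0.01, …, 1, and the lag
   between their peak daily rates.
5. **Method comparison** — major-axis (model II) regression with CI-based
   fixed/proportional bias flags, and a case-based bootstrap of median
   parameter differences (ASL, two-tailed, 10,000 resamples).

A synthetic-data module generates gray profiles, wall/lumen lattice VOI
stacks (~2.49 µm voxel pitch, 16-bit) and logistic seasonal series with known
ground truth, so the whole chain is testable without scan data.

## Worked example

```r
library(xylotomo)

# a synthetic ring: cambium at 150 um, transition at 500 um, boundary at 1050 um,
# 1% measurement noise on a 16-bit scale
tr <- ring_truth(150, 500, 1050, noise_sd = 300, seed = 1)
p  <- generate_profile(tr, n_points = 500)
cam <- detect_cambium(p, window = c(20, 300))
w  <- measure_widths(p, cam$cambium_pos, 1050)
w
#> Ring widths (um): incr 900.6 = maturing 352.7 + mature 547.9
#>   cambium 149.4 | transition 502.1 | boundary 1050.0
```

The detected transition (502.1 µm) sits 2.1 µm — under one voxel — from the
true 500 µm. A full season:

```r
season <- generate_season(season_truth(seed = 1))
phenology_table(season$widths)[1, c("tree", "tb_incr", "te_incr", "d_incr", "r_incr")]
#>   tree  tb_incr  te_incr   d_incr   r_incr
#> 1   t1 100.3034 228.8542 128.5508 7.078748
```

Tree t1 began size growth on DOY 100, ended on DOY 229 (the true noise-free
crossing dates are 101.1 and 218.9), grew for 129 days at a mean 7.1 µm/day.
Printed values are what the code above produces under seed 1.

## Command line

```sh
Rscript -e 'xylotomo::xylotomo_cli()' simulate --seed 4 --out season.csv
Rscript -e 'xylotomo::xylotomo_cli()' all --widths season.csv --out-dir out/
```
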