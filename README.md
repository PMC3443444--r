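# octgraft

Segmentation and area measurement of DSAEK corneal grafts in
anterior-segment OCT B-scans, with the observer-agreement statistics used
to validate such measurements.

## The problem

After Descemet stripping automated endothelial keratoplasty (DSAEK), a
thin (50–150 µm) lamella of donor cornea is attached to the posterior
surface of the recipient cornea. Graft thickness is a surrogate for graft
health — failing grafts swell — but single-point caliper readings on an
OCT scan miss the thickness variation across an irregularly cut graft.
The alternative is to segment the whole graft band in the B-scan and
report its **cross-sectional area** in µm², which integrates thickness
over the full lateral extent.

`octgraft` implements that measurement for ophthalmic researchers:

* **Automated segmentation** in four steps: (1) the image is filtered and
  binarised with a Canny edge detector, and the extracted boundary is
  sampled every 10 pixels to suppress interference (speckle) noise;
  (2) the four graft corner points are located from local curvature
  properties of the sampled boundary; (3) the low-contrast host–graft
  interface is extracted as the strongest anterior-directed intensity
  drop consistent with a smooth path between the anterior corners;
  (4) corner-anchored cubic smoothing splines close the segmentation.
* **Semi-automated refinement**: every spline control point (and the four
  corners) can be moved; invariants (single-valuedness, non-negative
  thickness) are re-checked on every edit.
* **Metrics**: shoelace polygon area *A* in px² scaled to µm² by the
  lateral × axial calibration, the thickness profile *t(x) =
  (y_post(x) − y_ant(x)) · cal_ax*, and the trephine volume estimate
  *V = A × d* (d = trephine diameter).
* **Agreement statistics** for paired measurement series: Bland–Altman
  bias and 95 % limits of agreement (bias ± 1.96 × SD of differences,
  with t-based confidence intervals), two-way mixed-effects ICC
  (absolute agreement, single measures, F-based CI), Pearson r, paired t.
* **Synthetic phantoms**: B-scan-like images with a bright corneal band,
  a lens-shaped graft bounded by two circular arcs with a closed-form
  area, an interface-contrast knob and multiplicative log-normal speckle
  — ground truth for every pipeline stage.

Calibration is never implicit: every image carries its µm-per-pixel
factors and metric outputs fail loudly without them.

## Worked example

```r
library(octgraft)

spec <- phantomSpec(seed = 7, speckleSigma = 0.1)   # 512x384 px, 18 um/px
ph   <- generatePhantom(spec)

seg  <- segmentAutomated(ph$image)
area <- computeArea(seg, calibration(spec))
area
#> AreaMeasurement [automated] 'phantom_seed7': 1860294.3 um^2
truthAreaUm2(ph$truth)
#> [1] 1862587                         # recovered within 0.13%

thicknessProfile(seg, calibration(spec), nSamples = 7)
#>   lateral_um thickness_um
#> 1          0        178.5
#> 2        888        322.2
#> 3       1776        407.2
#> 4       2664        431.9            # thickest at the graft apex
#> 5       3552        402.4
#> 6       4440        322.5
#> 7       5328        179.5

estimateVolume(area, 8.5)$value       # area x trephine diameter, as printed
#> [1] 15812502
```

Agreement between two simulated observers reading the same grafts with
independent N(0, 6000 µm²) noise:

```r
set.seed(1)
tru <- rnorm(50, 150000, 40000)
s <- measurementSeries(tru + rnorm(50, 0, 6000), tru + rnorm(50, 0, 6000),
                       c("obs1", "obs2"))
agreementReport(s)
#> AgreementReport 'obs1' - 'obs2' (n = 50)
#>   bias 1618.87 (95% CI -631.69 to 3869.43), SD of differences 7919.01
#>   LoA -13902.40 to 17140.14
#>   ICC 0.972 (95% CI 0.951 to 0.984)
#>   r 0.972
#>   paired t 1.446, p 0.1547
```

`agreementTable()` lays several comparisons out in the standard published
format (mean ± SD per arm, p, r, ICC with CI, bias and both limits with
CIs).

## Command line

A thin CLI over the same functions lives at `inst/scripts/octgraft.R`
with subcommands `phantom`, `segment`, `refine`, `area`, `agree` and
`batch` (exit code 2 when a batch had per-image failures):

```sh
Rscript inst/scripts/octgraft.R segment --input scan.png \
    --cal-lat 18 --cal-ax 18 --out seg.json
Rscript inst/scripts/octgraft.R area --seg seg.json \
    --cal-lat 18 --cal-ax 18 --out area.csv
```

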