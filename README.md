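# mandivol

Landmark-driven 3D volumetry of the mandible from CBCT-style volumes, with a
focus on quantifying condylar and ramal volume deficits in juvenile
idiopathic arthritis (JIA) with temporomandibular-joint involvement.

JIA commonly damages the mandibular condyle — the jaw's main growth site —
and clinicians need to know *which* part of the mandible is smaller on an
affected side: the condyle, the ramus, the body, or all of them. `mandivol`
implements the 3D cephalometric workflow that answers this: a reference
frame is built from skull-base landmarks, five cutting planes partition a
segmented mandible into condyle, coronoid, ramus and hemibody per side, and
the per-segment volumes feed a classical statistical battery (paired and
independent t tests, one-way ANOVA with Tukey/Bonferroni post hoc
comparisons, ICC and Dahlberg method error, noncentral-t sample size).

## The partition

World coordinates are LPS millimetres. From the landmark set
(Sella S, Nasion N, Basion Ba; Menton Me, Down's B point, mental-spine
point; per-side Condylion Co, Gonion Go, sigmoid-notch C-point):

- **mid-sagittal plane** through S, N, Ba;
- **horizontal plane** through S: the S–N plane (normal to the mid-sagittal
  plane) tilted 6° down at its anterior end;
- **C-point plane** through the C-point, parallel to the horizontal plane;
- **Condylion–Gonion plane** through Co and Go, perpendicular to the
  mid-sagittal plane (the 2D ramus line swept laterally);
- **Gonion–Menton plane** through both gonia and Menton (mandibular base);
- **median plane** through Menton, B point and the mental-spine point;
- **mandibular-angle plane**: the bisector of the Condylion–Gonion and
  Gonion–Menton planes through the Gonion — the plane that halves the
  gonial angle.

Each foreground voxel `v` (classified at its centre, signed distance
`d(p, v) = n·v − o`) receives exactly one label:

```
side      = L if d(median, v) >= 0 else R
condyle*  if d(c_point_side, v) > 0          (* split below)
ramus     else if d(angle_side, v) > 0
hemibody  otherwise
```

Supra-notch voxels are split into condyle and coronoid by 26-connected
components keyed to Condylion. Volumes are voxel counts times the voxel
volume; `hemimandible = condyle + coronoid + ramus + hemibody` holds as an
exact integer identity and `total = L + R`.

## Worked example

```r
library(mandivol)

# a 0.4 mm phantom with exact ground truth, segmented end-to-end
ph  <- generate_phantom(phantom_spec())
res <- segment_phantom(ph)
res$measured
#> <segment_volumes> (mm^3)
#>                     L        R
#> condyle       1464.77  1464.77
#> coronoid       832.00   832.00
#> ramus         9245.63  9245.63
#> hemibody     14584.00 14584.00
#> hemimandible 26126.40 26126.40
#>   total mandible: 52252.80 mm^3
identical(res$measured$voxel_counts, res$truth$voxel_counts)
#> [1] TRUE
```

The measured volumes equal the phantom's brute-force ground truth voxel for
voxel: with exact landmarks the plane partition is deterministic, so the
only error on real data comes from landmark placement and segmentation.

```r
# simulate a unilateral-JIA cohort at the published calibration
cal <- default_calibration()
co  <- simulate_cohort(cal$uni_jia, seed = 42)
head(cohort_group_means(co))
#>        segment    stratum  n       mean        sd
#> 1 hemimandible   affected 29 21287.2125 4911.6389
#> 2 hemimandible unaffected 29 23746.0365 4791.8401
#> 3      condyle   affected 29   922.0713  238.8424
#> 4      condyle unaffected 29  1398.6602  361.8531
#> 5        ramus   affected 29  4749.1828 1306.7426
#> 6        ramus unaffected 29  5600.4774 1705.0420
```

Affected-side condyles are ~35% smaller than unaffected ones, the signature
deficit this workflow was designed to measure. `full_study_report()` runs
the whole statistical battery over three simulated arms (unilateral JIA,
bilateral JIA, controls); `cmd_run_study()` writes the complete report
bundle to disk.

A thin command-line front end is installed at `inst/cli/mandivol`
(subcommands `phantom`, `segment`, `simulate-cohort`, `stats`,
`reliability`, `run-study`).

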