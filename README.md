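# pelvir

Pelvic incidence (PI) is the key anatomical parameter of sagittal
spinopelvic alignment: the angle between the perpendicular to the S1 (sacral)
endplate at its midpoint and the line joining that midpoint to the midpoint
of the bicoxofemoral axis (the line connecting the two femoral head
centres). Although PI is position-independent by definition, it is measured
in practice on 2D lateral radiographs, and a pelvis that is rotated relative
to the viewing plane projects a *different* angle than its anatomical PI.
`pelvir` is for spine-surgery and radiographic-measurement researchers who
want to quantify that projection error: how fast measured PI drifts as the
pelvis rotates about the vertical (superoinferior) or horizontal
(anteroposterior) axis, and how much rotation keeps the error inside a given
acceptability bound (6° by default).

## What it computes

The package builds the entire measurement chain in software:

1. **Synthetic pelvis generator** — labeled 3D point clouds (left/right
   femoral head hemispheres, planar elliptical S1 endplate patch) posed with
   a known anatomical PI = `ss_frame + pt_frame` (the endplate inclination
   and tilt of the sacro-femoral line in the scan frame), with optional
   Gaussian coordinate noise and asymmetry — a stand-in for CT segmentation.
2. **Landmark fitting** — least-squares sphere (or deterministic three-point
   circle) head centres, principal-axis endplate plane, hip-axis midpoint.
3. **Projection** — orthographic projection onto a sagittal viewing plane
   rotated by θ about the vertical or horizontal reference axis.
4. **2D PI measurement** — the angle a measurer would draw on the projected
   image, with a closed-form oracle for the idealized symmetric pelvis:

   cos PI(θ) = cos θ · cos(ss + pt) / √(A·B),

   where for vertical rotation A = 1 − cos²(ss)·sin²θ, B = 1 − sin²(pt)·sin²θ,
   and for horizontal rotation A = 1 − sin²(ss)·sin²θ, B = 1 − cos²(pt)·sin²θ.
5. **Rotation analysis** — per-angle sweep tables (PI, change, % change),
   cohort means, the largest rotation whose error stays within tolerance,
   and ICC(3,1) interobserver reliability from a subjects × raters matrix.

Vertical rotation inflates projected PI; horizontal rotation deflates it.

## Worked example

```r
library(pelvir)

params <- pelvis_params(ss_frame = 40, pt_frame = 8.8, noise_sd = 0)
model  <- generate_pelvis(params, seed = 1)
sw     <- pi_sweep(model, "vertical")
glance(sw)
#> # A tibble: 1 × 6
#>   axis_kind  pi_0 angle_max pi_at_max delta_at_max threshold
#>   <chr>     <dbl>     <dbl>     <dbl>        <dbl>     <dbl>
#> 1 vertical   48.8        40      54.4         5.57        40

writeLines(format_sweep_report(sw))
#> Effect of vertical pelvic rotation on PI
#> Rotation (deg)                0        5       10       15       20       25       30       35       40
#> Pelvic incidence           48.8     48.9     49.1     49.5     50.0     50.8     51.7     52.9     54.4
#> Change (%)                    -    +0.15    +0.62    +1.40    +2.54    +4.06    +6.01    +8.44   +11.41
#> Acceptable (|error| <= 6 deg) up to: 40 deg vertical rotation
```

At 0° the pipeline returns exactly the anatomical PI (48.8°); by 40° of
vertical rotation the projected value has inflated to 54.4°. For this single
idealized pelvis the drift stays within 6° up to 40°; a published cohort of
real anatomies crosses the 6° bound at 30° of vertical rotation, because the
drift rate depends on each patient's endplate/tilt split. `autoplot(sw)`
draws the curve with the acceptability band.

Cohort and reliability analysis follow the same grammar:

```r
cohort <- generate_cohort(n = 30, pi_mean = 48.8, pi_sd = 10, seed = 5,
                          base = pelvis_params(ss_frame = 40, pt_frame = 8.8))
summ <- cohort_sweep(cohort, "horizontal")
acceptable_threshold(summ)          # largest rotation within 6 degrees

ratings <- simulate_ratings(cohort, n_raters = 2, rater_sd = 0.5, seed = 6)
icc(ratings)
#> <icc_result> ICC(3,1) = 0.995 (excellent); 30 subjects x 2 raters
```

A thin command-line wrapper (`inst/cli/pelvir.R`) exposes `generate`,
`sweep`, `reliability` and `report` subcommands over YAML configs for
file-based workflows.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch: it measures the
projected PI of a noiseless symmetric pelvis at 0° through the full
generate → fit → project → measure chain, and sweeps a seeded 30-member
synthetic cohort (PI ~ Normal(48.8°, 10°), frame tilt ~ U[0°, 15°]) to the
40° extremes of both rotation axes, writing the resulting values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
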