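# gazeflow

Forward modelling of instantaneous optic flow under **active gaze control**,
and of the local flow-derivative signatures that make obstacle edges
segmentable.

A walking observer who fixates a point in the scene rotates the eyes to keep
that point stationary on the retina. The resulting image flow differs
systematically between two behavioural strategies:

* **Target approach** — gaze locked on the centre of the target, heading
  aligned with gaze. The flow is a pure expansion whose focus of expansion
  (FOE) marks the point being approached; locally, only the divergence of
  the flow is nonzero (`div = 2 v_z / Z`), so steering reduces to aligning
  the FOE with the target.
* **Obstacle avoidance** — gaze grazing the obstacle's outer (apical) edge
  while heading points elsewhere. Foreground and background flow separate
  into a fast, coherent translational stream and a rotation-dominated
  stream pointing the opposite way; divergence, curl and shear become
  singular at the depth discontinuity, turning the edge into a strong,
  directly detectable flow feature.

`gazeflow` implements the full analysis pipeline in R:

* the instantaneous motion-field equations for a pinhole camera
  (translation `v`, rotation `ω`), and the gaze-stabilizing variant in
  which `ω` is derived from `v` and the fixated point (zero roll),
  \
  `u = (x v_z − f v_x)/Z + ω_x xy/f − ω_y (f + x²/f) + ω_z y`
  \
  `v = (y v_z − f v_y)/Z + ω_x (f + y²/f) − ω_y xy/f − ω_z x`
* analytic ray-cast depth maps (ground plane, box and cylinder posts) with
  exact depth partials and depth-discontinuity flags;
* the Jacobian of the flow and its decomposition into **divergence, curl,
  Type I shear and Type II shear**, with closed forms for a tilted plane, a
  gaze-parallel plane (tangential fixation), a cylindrical edge and an
  apical edge;
* qualitative response-curve classification (linear `/`, constant `−`,
  hyperbolic `∩`, absent `0`) and the sensor/strategy signature tables;
* a Schwartz-type monopole mapping to cortical coordinates with
  fovea/periphery limit behaviour;
* a biologically inspired antagonistic center-surround derivative operator
  bank and the circuit wiring its outputs into component maps;
* flow-discontinuity detection and obstacle segmentation, plus Middlebury
  `.flo` I/O for externally estimated flow.

## Worked example

```r
library(gazeflow)

# target approach: 240x240 px, 5-degree fovea, post 2 m ahead
ap  <- make_scenario("approach")
foe <- find_foe(ap$motion$v, ap$camera)
com <- find_com(ap$flow)
comp <- decompose(jacobian_analytic(ap$camera, ap$depth, ap$motion))
median(comp$div, na.rm = TRUE)   # 1.018  (2 v_z / Z at ~1.96 m)
c(foe$x, foe$y, com$x, com$y)    # 0 0 0 0 — FOE = COM = fixated centre

# obstacle avoidance: gaze at the post's outer edge
av <- make_scenario("avoidance")
histogram_modes(direction_histograms(av$flow))$separation
#> 173.2   # two flow-direction modes ~180 degrees apart

seg <- detect_discontinuities(decompose(jacobian_fd(av$flow)))
edge_metrics(seg, av$depth$disc, tol_px = 2)[c("precision", "recall")]
#> 1.00 1.00 — the fixated edge is recovered pixel-sharp

sensor_row_classes("pinhole", "tilted_plane")      # "/" "-" "/" "-"
sensor_row_classes("monopole_periphery", "parallel_plane")  # "∩" "0" "∩" "0"
```

The first block says: approaching the fixated post face produces a
divergence of about `2 v_z / Z ≈ 1.02 s⁻¹` and essentially nothing else,
with the expansion centre exactly at the fixated point. The second block
shows the avoidance signature — a bimodal direction histogram with modes
about 180° apart and a flow discontinuity localized on the obstacle's edge.
The last two calls recompute rows of the qualitative response tables:
fixating a tilted surface never produces hyperbolic (edge-like) responses,
while tangential fixation does.

## Command-line use

```sh
Rscript inst/cli/gazeflow.R simulate  --scenario avoidance --out out/
Rscript inst/cli/gazeflow.R decompose --flow out/flow.flo --out out/comp/
Rscript inst/cli/gazeflow.R segment   --flow out/flow.flo --percentile 99 --out out/seg/
```

`simulate` writes the rendered flow as `.flo` plus depth/speed previews and
a JSON provenance record; `decompose`/`operators`/`cortical` write the four
component rasters with a JSON summary; `segment` writes the edge list and
object mask.
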