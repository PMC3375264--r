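---
title: "Flow derivatives under active gaze control: models, conventions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow derivatives under active gaze control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeflow)
```

## The model

`gazeflow` is a forward model: given a rigid scene, a camera, and an
observer's instantaneous self-motion, it computes the image flow and its
local spatial derivatives. Nothing is estimated from images; the package's
question is what *structure* the flow has under different gaze strategies,
and whether that structure suffices to steer toward a target or to segment
an obstacle.

### Passive and fixating flow

For a pinhole camera with focal length $f$ looking down $+Z$ (image $y$ up
in analytic coordinates), a scene point at depth $Z$ projecting to $(x,y)$
moves on the image with

$$\dot x = \frac{x v_z - f v_x}{Z} + \omega_x \frac{xy}{f}
  - \omega_y\left(f + \frac{x^2}{f}\right) + \omega_z y,$$
$$\dot y = \frac{y v_z - f v_y}{Z} + \omega_x\left(f + \frac{y^2}{f}\right)
  - \omega_y \frac{xy}{f} - \omega_z x,$$

the sum of a depth-dependent translational term and a depth-free rotational
term. The sign conventions are *pinned by an oracle*, not by transcription:
the test suite projects scene points, advances the camera by a micro-step
of its motion, reprojects, and compares the finite-difference displacement
with the model — a construction that cannot inherit a sign error from any
written form of the equations.

A *fixating* observer is one whose eyes rotate to keep a chosen scene point
stationary on the image. We require zero roll (people do not keep horizons
level with their eyes while walking), leaving yaw and pitch. Setting both
flow components to zero at the fixated point's projection gives a
$2\times2$ linear system for $(\omega_x,\omega_y)$ whose determinant
$f^2 + x_F^2 + y_F^2$ is always positive, so the compensatory rates are
unique (`fixation_rates()`). Consequences verified in the tests: the flow
vanishes at the fixated point (the *centre of motion*, COM); as
$Z_F\to\infty$ the flow tends to the pure translational field; the
equations are symmetric under a consistent swap of $x$ and $y$; and the
fixating field equals the passive field evaluated at the derived rates. The
trajectory oracle for the fixating case re-centres the fixated point by a
yaw-then-pitch rotation solved numerically per micro-step; that composition
order (yaw about the world vertical, then pitch about the rotated
horizontal axis, roll identically zero) is the package-wide convention for
camera orientations (`camera_pose()`).

### Units and rasters

Analytic math uses image-plane units with $y$ up; pixel rasters are $y$
down with half-integer pixel centres and the principal point exactly at the
image centre. The conversion layer (`flow_pixels()`, and the raster
handling in `apply_bank()`) flips the sign of $v$ and of $\partial/\partial
y$; divergence and Type I shear are invariant under this flip while curl
and Type II shear change sign, which is why raster-side quantities are
always converted back to the analytic convention before being reported.
The flow Jacobian is dimensionally $1/\mathrm{s}$ and is invariant to the
common length unit of flow and coordinates, so operator responses on pixel
rasters are directly comparable to analytic components.

## The decomposition

The local Jacobian
$J = \begin{pmatrix}\partial_x u & \partial_y u\\ \partial_x v & \partial_y v\end{pmatrix}$
is re-expressed in the basis

* $\mathrm{div} = \partial_x u + \partial_y v$ — isotropic expansion
  (positive = sources, as generated by forward motion),
* $\mathrm{curl} = \partial_x v - \partial_y u$ — rotation (positive =
  counterclockwise),
* $\mathrm{shear}_I = \partial_x u - \partial_y v$ — expansion along $x$
  with contraction along $y$,
* $\mathrm{shear}_{II} = \partial_y u + \partial_x v$ — the same
  deformation with axes rotated 45° counterclockwise.

This is a linear bijection; `recompose()` inverts it exactly. The sign
semantics are pinned by generated canonical fields (`u = x, v = y` is pure
positive divergence; `u = -y, v = x` pure positive curl; `u = ay, v = ax`
pure Type II shear of magnitude $2a$), and the 45° relation between the two
shear axes is verified by eigen-decomposition of the symmetric Jacobian
part. Analytic Jacobians (`jacobian_analytic()`) evaluate the exact
partials given a depth map with analytic depth gradients; no partial
derivatives of the fixation depth $Z_F$ occur because $Z_F$ does not vary
with image position. Where analytic partials are unavailable the package
falls back to central differences and says so in the `provenance` tag.

## Closed-form surface cases

All closed forms derive from the translation-only component algebra with
$t_u = x v_z - f v_x$, $t_v = y v_z - f v_y$ and a surface $Z(x,y)$; the
components are linear in $(Z_x, Z_y, 1/Z)$. Fixating eye-rotation adds
terms of order $\omega$ that are an order of magnitude smaller in the
behavioural regimes and are omitted from the closed forms (they are present
in the rendered fields against which the closed forms are cross-checked on
smooth regions).

**Tilted plane** (`components_translation_plane()`): normal tilted by
$\alpha$ from gaze, distance $d$. Divergence and Type I shear are affine in
the declination $x$; curl and Type II shear do not depend on it. At
$\alpha = 0$ with forward motion only $\mathrm{div} = 2 v_z / d$ survives.

**Gaze-parallel plane** (`components_parallel_plane()`): the tangential
configuration. The response variable `x_off` parametrizes the plane's
lateral offset from the gaze line, and the components are evaluated at a
fixed, slightly off-axis image point (default about a degree off-centre so
that no component vanishes by meridian symmetry). Every component is then
*exactly* proportional to $1/x_\mathrm{off}$ — the hyperbola law
$|c(x_\mathrm{off})|\cdot|x_\mathrm{off}| = \mathrm{const}$ holds to
machine precision — and curl $\equiv$ Type II shear. The alternative
reading, evaluating at image coordinate $x_\mathrm{off}$ itself, makes
forward-motion responses constant and contradicts the per-axis strategy
table, so it was rejected; the finite-difference oracle on ray-cast
gaze-parallel planes confirms the adopted form.

**Cylindrical (curved) edge** (`components_cylinder()`): a vertical
cylinder of radius $R$ whose near surface reaches the camera, silhouette
at $(X,Z)=(R,d)$; under the small-angle parallel projection the visible
depth is $Z(x) = d - \sqrt{R^2 - x^2}$. In the tangential configuration
$d = R$ the depth itself vanishes as $x\to 0$ and the depth slope diverges
at the silhouette $x\to R$, so all four components blow up at both ends of
$(0,R)$ with a magnitude minimum between — the geometry that makes the
domain $(0,R)$ and both caption limits come out right. General $d \ge R$
is supported; the tangential preset is the default.

**Apical edge** (`components_apical_edge()`): an object's outer vertical
edge with an abrupt depth jump to the background. The edge line is
projected onto the ground as a "shadow" cast from the camera's nodal
point; each shadow point therefore lies on the *same visual ray* as its
edge point, and the pair measures the depth jump across the edge at one
image location. At the edge the depth derivative is undefined; it is
approximated by that jump divided by the across-edge sampling offset `dx`
(default one pixel, signed toward the background side). The structural
consequences — sideward motion excites only divergence and Type I shear,
vertical motion only curl and Type II shear, forward motion all four, and
contributions combine additively over motion axes — follow from which of
$t_u$, $t_v$ each component multiplies, and every edge contribution scales
as $1/\mathrm{dx}$, diverging as the sampling tightens onto the
discontinuity.

## Response-curve classification

`classify_curve()` assigns one of four families to samples of a component
against a declination: absent (`0`), constant (`−`), affine (`/`), or
hyperbolic (`∩`, a reciprocal-polynomial $a + c_1/x + c_2/x^2 + c_3/x^3$
capturing reciprocal decays steeper than $1/x$). Numerical conventions:

* models are accepted at relative residual $10^{-6}$ on noiseless input;
  "zero" means a maximum below $10^{-9}$ of the configuration's scale;
* `∩` additionally requires *divergence evidence* — the small-$x$ end of
  the window must exceed the large-$x$ end by a factor (default 3). A
  regularized foveal response like $C/(x+a)$ inside the fovea is finite
  and classifies as affine, which is exactly the distinction the sensor
  table draws;
* when no model fits exactly (numerically transformed cortical curves),
  the better of affine/hyperbolic wins if its residual beats the other by
  a factor of two, otherwise the result is `"ambiguous"` rather than a
  guess.

Two alphabets are in use. The sensor table (`response_table()`)
distinguishes constant from linear responses; the strategy table
(`predict_signature()`) opposes *finite* (printed `/`, including
constants) to *hyperbolic* responses, because its claim is precisely that
target approach yields finite responses and obstacle avoidance singular
ones regardless of the motion axis. `coarse_class()` maps the fine
alphabet onto the strategy alphabet. End-to-end tests recompute every row
of both tables from the closed forms.

## The cortical (monopole) representation

`monopole_map()` implements the Schwartz-type transform
$w = k\,\log(z + a)$ on the complex retinal position $z$ in angular units,
with foveal regularization $a$ (default $0.5°$) and scale $k = 1$. The map
is smooth and invertible (round-trip error below $10^{-9}$), compressive,
and handles the exact centre through the shifted logarithm. Cortical
velocity is the push-forward $V = w'(z)\,U$.

The exact cortical derivations behind the sensor table's monopole rows are
not available as closed forms, so the package *operationalizes their limit
statements* and checks them numerically, with two documented conventions
matching the natural metric of each region:

* **fovea** (probe eccentricity $0.1°$): derivatives of $V$ per unit
  *cortical* distance (`frame = "cortical"`). The map is near-linear
  there, but its second derivative already converts foveal expansion into
  a linearly position-dependent curl — which is why the fovea row for the
  tilted plane reads `/ / − −` rather than the retinal `/ − / −`.
* **periphery** (probe eccentricity $20°$, trends followed across doubled
  eccentricities): derivatives of $V$ per unit *retinal* distance
  (`frame = "retinal"`, i.e. magnification-normalized cortical
  derivatives). On the horizontal meridian the $u$-related terms grow with
  eccentricity while the $v$-related terms do not, so the $1/e$
  magnification factor leaves divergence and Type I shear finite and sends
  curl and Type II shear to zero — the periphery rows `− 0 − 0` and
  `∩ 0 ∩ 0`.

For the tangential scenarios the hyperbolic character lives in the
tangential offset (the transform is linear in the flow, so $1/x_\mathrm{off}$
is preserved exactly); a component classifies as `0` in the periphery when
its amplitude decays under eccentricity doubling. The headline qualitative
claim — a tilted plane is never hyperbolic for any sensor, so fixating a
surface's centre is categorically distinguishable from fixating its edge —
is asserted directly for all three sensors.

These conventions are the package's own operationalization of limit-only
source material; they are fixed, documented here, and exercised by the
table-reproduction tests rather than tuned per row.

## The operator bank

`build_bank()` constructs the biologically inspired derivative estimators:
each partial is the difference of correlations with two juxtaposed
elliptical Gaussian subfields — a 9×5 px centre ($\sigma_x = 1$,
$\sigma_y = 2$ px) whose correlation is shifted one pixel left, and a 9×13
px surround ($\sigma_x = 3$, $\sigma_y = 2$ px) shifted two pixels right;
the y-pair is the same circuit rotated 90°. Two design decisions:

* **subfield normalization to unit sum** before subtraction. This makes
  the response to constant fields exactly zero and turns the ramp response
  into a single measurable gain — the distance between effective lobe
  centres, exactly 3 px — so operator outputs divide by a known scalar
  instead of requiring an ad-hoc rescale against the analytic model.
* **no padding**: outputs within kernel reach of the border or of masked
  pixels are masked, avoiding fabricated discontinuities at image edges.

The kernels' vertical elongation makes the x-pair maximally responsive to
vertical flow discontinuities, matching the vertical edge stripes of the
avoidance scenario. On smooth rendered fields the gain-corrected operator
components correlate with the analytic components at $r > 0.95$ (in
practice $\approx 1$); along the avoidance edge line the operator
magnitudes are smaller than the one-pixel-sampled analytic edge model —
the operator spreads the jump over its support — but the ordinal
relationships among the four components are preserved, which is the
property the circuit needs.

## Scenarios: the synthetic study conditions

The presets (`make_scenario()`, `wide_field_scenario()`) fix the study
conditions; they are deliberately *not* tuning knobs. The foveal sensor is
240×240 px on 1 cm × 1 cm with $f = 2748.45$ px — a 5°×5° field. The
camera walks 1 m above a ground plane at 1 m/s; the obstacle is a square
post 0.2 m wide and 1 m tall whose centre lies 2 m along the reference
axis. Where the source conditions were unrecoverable, values were chosen
once at human-walking scale and documented: the avoidance heading
$(-0.35, 0, 0.94)$ m/s puts about 20° between gaze and heading; the
wide-field sensor is 320×640 px spanning 50° with three posts at 2–5 m.

One modelling decision deserves emphasis. In the avoidance preset the gaze
ray grazes the post's outer vertical edge at mid-height, but the
*stabilized scene point* is the background (ground) point seen along that
ray — fixation "next to the edge". Stabilizing the background makes the
near post carry a strong, coherent translational flow while the distant
background is rotation-dominated in the opposite direction; stabilizing
the post face instead cancels the foreground flow around the fixated point
and produces a broad expansion fan whose direction histogram is not
bimodal. Only the background-stabilized reading yields the described
avoidance phenomenology — foreground "mainly translational", background
"dominated by rotational flow", two narrow direction modes ≈180° apart,
and a sharp speed discontinuity at the edge — so it is the preset. The
measured separation is 173°, not exactly 180°, because the foreground
translational direction is set by the FOE geometry rather than being the
exact negative of the rotational direction; the residual is a genuine
model value, not an artifact.

**What the generator emulates and what it does not.** Scenes are rigid,
textureless and noise-free; flow comes from geometry, not from images.
Passing tests therefore demonstrate properties of the *model* — signature
tables, singular edges, operator fidelity — and say nothing about flow
*estimation* from real video (sensor noise, aperture problems, independent
motion, non-rigidity). The `.flo` ingestion path (`load_external_flow()`)
exists precisely so externally estimated flow can be run through the same
derivative and segmentation machinery; the tests exercise it with
synthetic stand-ins for the two passive-video regimes (a depth-layered
lateral pan, and opposed laminar regions mimicking object motion).

## Segmentation

`detect_discontinuities()` z-scores each component over the valid region,
takes the per-pixel maximum absolute z as the combined response, and
thresholds at a percentile (default 99th) with an absolute floor of 3
standard deviations — the floor is what lets a smooth pure-expansion field
return an *empty* result instead of its top percentile. Candidate pixels
are labelled by 8-connected components; stripes of opposite dominant sign
within a 5 px dilation pair into one object (opponent-sign responses flank
a fully visible obstacle), lone stripes are flagged ungrouped rather than
merged, and the fixated obstacle is the group holding the global peak.
Z-scoring makes the segmentation exactly invariant to uniform rescaling of
the flow. Both the statistic (max of |z|) and the threshold are package
choices — the source material states no threshold — and both are exposed
as parameters. Edge localization is scored against the ray-caster's
ground-truth discontinuity flags with a 2 px tolerance, reflecting that
derivative responses necessarily straddle an edge.

## Numerical choices and problem sizes

* Finite differences: central, at the pixel pitch for rendered fields
  (about $3.6\times10^{-4} f$), adaptive steps for the cortical chain
  rule; analytic-vs-FD agreement on smooth preset regions is at machine
  precision, far inside the $10^{-5}$ bound asserted in the tests.
* Discontinuity flags compare each inter-pixel depth jump against the jump
  predicted by the analytic surface slope (factor 4), so steep-but-smooth
  ground toward the horizon is not flagged while silhouettes and box
  creases are.
* COM refinement fits local linear models of both flow components on the
  slow half of a 7×7 window (the discontinuity side is excluded) and
  solves for the common zero; accepted only when it stays near the grid
  minimum.
* Classification windows: pinhole declinations $x/f \in [0.05, 0.5]$;
  fovea $[0.5, 1.5]\times0.1°$; periphery trends at $20°\times\{1,2,4,8\}$;
  cylinder samples within $(0,R)$; apical offsets $0.5$–$5$ px.
* Test and acceptance problem sizes — 240×240 and 320×640 rasters, 12-point
  classification curves, 36-bin histograms — run the full suite in a few
  seconds; they are the sizes at which every qualitative property is
  already stable.

## Known limitations

* Forward model only: no estimation of $v$, $\omega$ or $Z$ from observed
  flow, and no second-order temporal derivatives.
* The closed forms omit the (small) fixating-rotation terms; oracle
  comparisons on rendered fields include them, which bounds the omission.
* The cortical module asserts limit behaviour under the documented
  operationalization, not exact cortical closed forms; a different
  monopole parametrization would change quantitative cortical values
  (though not the reproduced qualitative rows, which are
  parameter-robust).
* Grouping assumes fully visible, non-overlapping obstacles; overlapping
  configurations are deliberately left ungrouped.
* No fixation-point selection policy: choosing *what* to fixate requires
  task context outside a flow model.
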