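---
title: "Guide-based AR registration: models, noise and the virtual validation study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-based AR registration: models, noise and the virtual validation study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arguide)
```

## The registration model

Everything in this package hangs off one identity between rigid transforms.
A patient-specific surgical guide is designed on the virtual bone so that its
contact surface is the negative of a bone patch; if the patch is asymmetric
enough, the guide seats in a unique pose, and because it was designed *in the
anatomy frame* its nominal seating is the identity. A socket on the guide
holds a 30 mm cubic marker at a known pose. Writing `T_a←b` for the rigid map
from frame `b` to frame `a`,

```
T_anatomy←marker = T_anatomy←guide ∘ T_guide←marker
```

is fixed at design time, so a single camera observation of the marker
(`T_camera←marker`) registers every virtual model to the patient with no
manual interaction. The package represents each factor as a `rigid_transform`
with named parent/child frames, and composition checks the chain, so a
mis-ordered multiplication fails instead of silently producing a wrong pose.

Point-based registration (`horn_register`) is the classical closed-form
least-squares solution: centre both labelled point sets, take the SVD of the
cross-covariance, and guard against reflections by flipping the smallest
singular direction when the determinant is negative. Pairing is always by
label; nearest-neighbour pairing is deliberately not offered for fiducials.
The fiducial registration error (FRE) is the RMS residual after alignment,
and under independent per-axis localization noise of standard deviation
`sigma` it obeys the standard expectation
`E[FRE^2] = (1 - 2/N) * 3 sigma^2`, which the test-suite verifies by
Monte-Carlo at `N = 8`. Target errors away from the fiducials grow with the
lever arm, which is the reason the validation protocol measures targets all
over the phantom surface rather than at the fiducials only.

## From CT mask to guide

The imaging steps mirror a routine segmentation clean-up: intensity
thresholding, retention of the largest connected components (the scanner bed
is a large but *disconnected* structure), and binary closing with a 7×7×3
voxel box to remove small internal cavities before printing. Three choices
here were genuinely open and are fixed as follows:

* **Connectivity** is 26-neighbourhood. Island tools in clinical
  segmentation software do not document their connectivity; 26 is the more
  permissive choice and never splits a structure that 6-connectivity would
  join.
* **Closing** is implemented as dilation followed by erosion on a grid
  padded by the kernel radius, which makes the operation extensive
  (output ⊇ input) and idempotent even at the volume border. The kernel is
  interpreted in voxel units, axis order in-plane × in-plane × slice.
* **Surface extraction** meshes the 0.5 iso-level of the binary mask under
  nearest-neighbour interpolation: each foreground/background voxel face
  becomes two triangles on the half-spacing lattice. The mesh is watertight
  by construction and its enclosed volume is exactly the voxel volume, so it
  converges to the true volume as the spacing shrinks; the trade-off is a
  blocky surface normal field, which none of the downstream steps depend on.

Guide design selects the contact patch by *geodesic* distance on the mesh
edge graph (with the opposite-vertex shortcut edges added across each
interior edge, which cuts the systematic overestimate of graph geodesics to
the one-to-two-percent level). Geodesic rather than Euclidean selection
prevents a patch from jumping across thin gaps in the anatomy. The guide
body is the patch offset outward along its area-weighted vertex normals by
the guide thickness (default 3 mm — a typical printed-guide wall; the
protocol this package emulates does not quantify it) with the rim stitched
by quads; its inner surface therefore *is* the bone patch, which is what
makes the seating unique. If the offset self-intersects the body is rebuilt
by 0.5 mm voxel remeshing with a warning.

Boolean edits (Ø5 mm screw holes) subtract an analytic solid from a 0.5 mm
voxelization of the body and re-extract the surface; the voxel grid is
anchored at the bounding-box minimum plus half a voxel so axis-aligned
solids rasterize exactly. No exact mesh-boolean engine is used anywhere —
the voxel route is robust, always returns a watertight mesh, and its volume
error on cylinder-sized cuts is a few percent, well inside what matters for
a printed tool. Conical fiducials (Ø4 mm × 3 mm) are carved instead by local
mesh surgery — split the containing face, refine edges crossing the
footprint, displace footprint vertices onto the cone — because a voxel
boolean cannot place a cone apex to sub-voxel accuracy, while the surgical
route puts it exactly at `point − depth·normal` and preserves
watertightness.

Seating (`fit_guide`) is trimmed point-to-plane ICP from the contact-patch
vertices to the bone surface: closest points on the (bbox-restricted) bone,
worst 10 % of pairs dropped, small-angle 6-DOF solve, convergence when the
RMS contact distance changes by less than 1e-4 mm. The designed pose is a
zero-residual global optimum, so re-fitting from a perturbed pose is the
virtual analogue of removing and re-attaching the guide.

## The synthetic phantoms and what they do (not) emulate

`generate_phantom` builds six cases with the overall dimensions of the
printed validation phantoms (170×150×130 … 220×120×110 mm). Each has:

* a **bone primitive** — a tapered tube with a Gaussian side bump (long
  bones) or a bumpy ellipsoid (pelvis/scapula-like cases). The taper and
  bump are what make the contact patch asymmetric, hence the seating unique;
  a perfect cylinder or sphere would leave unconstrained degrees of freedom,
  which is exactly the failure mode guide designers avoid on real anatomy;
* a **tumor** ellipsoid adjacent to the bone;
* a **stand base and two supports**, with the volume-weighted centre of mass
  of the solids projecting inside the base footprint (the stand-upright
  contract);
* **8 conical surface fiducials** (Ø4 mm × 3 mm), well spread by greedy
  farthest-point selection, opening centres snapped onto the surface;
* a **seated guide** with 3–5 of its own cones, two screw axes and the
  marker-holder socket. The dimension contract covers the printed phantom
  body; the resin guide with its 30 mm marker is a separate print seated on
  it and may extend above the stated box.

The generator is deterministic given its seed. What it does *not* emulate:
printing tolerances and material warp, segmentation error in the source
masks, optical-tracker calibration error, camera lens distortion, and human
variability beyond independent noise streams. Passing the simulated
protocol therefore demonstrates that the *computational chain* —
registration algebra, seating, error propagation, statistics — is correct
and that the error budget behaves as theory predicts; it does not certify
the physical accuracy of any printed system.

## The two virtual experiments and the noise model

All noise parameters live in one `noise_model` object (defaults 0.5 mm per
axis and 0.5°, the simulation's stated operating point; the protocol this
package emulates does not publish SDK pose-noise magnitudes, so these are
simulation parameters, not measured values):

| parameter | meaning | default |
|---|---|---|
| `fiducial_sigma` | per-axis FLE touching conical fiducials | 0.5 mm |
| `pointer_sigma` | per-axis pointer error on displayed targets | 0.5 mm |
| `seating_sigma_trans/rot` | guide seating perturbation before ICP re-fit | 0.5 mm / 0.5° |
| `marker_sigma_trans/rot` | marker pose observation noise | 0.5 mm / 0.5° |

**Placement trial**: perturb the seating, re-fit by ICP, touch the guide
cones with a noisy pointer in a random tracker frame, register the phantom
to its model through the 8 surface fiducials, and report the per-cone
distance to the designed positions. **Tracking trial**: sample 14 targets
uniformly by area on the phantom surface, display them through the *designed*
chain applied to the *observed* (noisy) marker pose, compare against the
physical chain with the actually-seated guide, and add pointer noise. With
every sigma at zero both chains are exact to numerical precision — the
transform algebra cancels — which the acceptance suite asserts at 1e-6 mm
across all six phantoms. Rotational marker noise alone produces errors
proportional to the distance from the cube centre (the lever arm), giving
the positive distance–error rank correlation that the evaluation module
quantifies with Spearman's rho. Random tracker and camera frames are drawn
per trial, so error distributions are invariant to relocating the phantom in
the world by construction.

The full protocol is the factorial `6 cases × 2 users × 5 repetitions`, the
users being independent RNG streams with identical parameters (matching the
finding of no systematic user effect, which `paired_user_test` — a two-sided
paired t-test on per-phantom means — checks at its nominal 5 % level in the
test-suite's null simulations). Per-trial seeds are derived from one master
seed and stay below 2^31.

## Statistical conventions

* Standard deviations are sample (n−1); the protocol's figures do not state
  a convention and small physical samples make the sample convention the
  safer default.
* Box summaries report quartiles and median, with whiskers at
  mean ± 1.5 sd following the validation figures' caption convention;
  Tukey 1.5·IQR fences are available behind a flag.
* Likert tables round half-up to one decimal, matching printed survey
  tables (base `round()` is round-half-even and would print 4.45 as 4.4).
  The per-question and per-respondent averages of the packaged survey
  fixtures reproduce their printed values exactly; the single printed
  "overall" average covers an unenumerated question subset, so only the
  cell-wise grand mean is computed and asserted.
* `paired_user_test` reports identical vectors as t = 0, p = 1 rather than
  an undefined statistic; `distance_error_correlation` flags constant
  inputs as undefined instead of guessing.

## Problem sizes and degenerate inputs

The shipped study sizes keep every run interactive: phantom meshes of a few
thousand faces (44–48 angular segments), contact patches of a few hundred
vertices, 120 trials per full experiment, and Monte-Carlo loops of 10^3
draws in the tests (10^4 for the chi-distribution check). These are the
package's chosen operating sizes; all of them are parameters.

Degenerate inputs fail loudly: empty masks cannot be meshed, collinear
fiducial sets cannot be registered, non-odd closing kernels, zero-length
view directions, negative sigmas, seeds off the bone surface, sockets
colliding with the contact patch and mismatched frame chains are all
rejected with specific errors. Truncated STL/PLY files produce parse errors
naming the file, and LPS-flagged fiducial or volume files are converted to
RAS with a warning at the boundary — internally everything is RAS mm.

## Known limitations

* The voxel-boolean route re-meshes the whole body, so repeated edits
  accumulate resampling; carve cones before drilling holes if both are
  needed at maximal fidelity.
* Graph geodesics overestimate true geodesics by one to two percent even
  with shortcut edges; patch areas inherit that bias.
* The marker simulator models pose noise only — no imaging, lighting,
  occlusion-dependent accuracy or detection-range effects; face visibility
  is a purely geometric normal test.
* Segmentation is threshold-based; manual tumor painting is out of scope and
  tumor masks are expected as inputs.
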