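---
title: "Measuring root-crown architecture from field photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring root-crown architecture from field photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcrown)
```

## The measurement problem

Field phenotyping of root system architecture ("shovelomics") excavates a
root crown, washes it, and photographs it against a dark diffuse
background. The scene contains three things: the root crown itself, a
light circular scale marker of known physical diameter, and an
identification tag placed above the root. From that single 2-D
photograph, `rootcrown` computes a registry of 78 architectural traits in
four families — traits common to all root systems, traits for monocot
(fibrous) crowns, traits for dicot (taproot) crowns, and traits for
excised root samples — and writes them as Excel-compatible CSV together
with the measured root geometry as RSML.

The pipeline is deterministic and fully automatic:

1. **Segmentation.** A single global threshold in \[0,1\] separates light
   material from the dark background, followed by one binary opening with
   a 3×3 cross to remove speckle. Global (not adaptive) thresholding is
   deliberate: it matches the protocol's visual calibration workflow,
   where the user picks the threshold once per imaging campaign by
   inspecting a sweep of masks on a representative image
   (`calibration_sweep()`, `write_sweep_masks()`).
2. **Scene classification.** Connected components are labeled with
   8-connectivity. The scale marker is the most circular component with
   isoperimetric quotient \(4\pi A/P^2 \ge 0.7\) and area \(\ge 200\) px;
   the tag is the largest dense box (bounding-box fill \(\ge 0.75\))
   lying above the largest remaining component other than itself; the
   root is the largest component not claimed as marker or tag. A lone
   component is always the root: a scene must have a root, the marker is
   optional. When the marker is absent, all length traits degrade to
   pixel units with a `units = "px"` flag rather than failing the image.
3. **Calibration.** The marker's equivalent diameter
   \(d = 2\sqrt{A/\pi}\) divided by its known physical diameter gives
   `pixels_per_mm`. Equivalent diameter from area is preferred over
   fitted circles because it is parameter-free and accurate to well
   under 2% for rasterized discs of radius 20 px and up.
4. **Structure.** The Euclidean distance transform (EDT) of the root
   mask gives a medial radius at each interior pixel; topology-preserving
   thinning gives a 1-px skeleton; the skeleton becomes a graph of tips,
   junctions and degree-2 chains; short terminal spurs are pruned; the
   collar (stem–root junction, the origin of all paths) is the topmost
   skeleton tip; and each remaining tip gets its minimum-arclength
   collar-to-tip path (RTP). Angles along paths are measured from the
   secant over a centred window of 9 polyline points, reported as
   absolute degrees from the horizontal in \[0, 90\] (row numbers grow
   downward, so vertical = 90°); the side of each path relative to the
   collar column is kept separately for the paired monocot traits.
5. **Traits.** The four families are computed from the width profile
   (per-row horizontal extents), the boundary pixels, the skeleton radii
   and the paths; per-trait failure codes (`not-applicable`, `no-scale`,
   `computation-failed`) contain any failure so a single image never
   aborts a batch.

## Trait definitions in brief

*Width profile.* For every row of the root bounding box, the horizontal
extent is rightmost − leftmost + 1 over root pixels of that row — an
extent, not a pixel count, so a C-shaped crown spans its own gap. The
median and maximum extents give `WIDTH_MED` and `WIDTH_MAX`; the
cumulative extent curve gives the depth landmarks `D10..D90` (depth
fraction at which 10%..90% of accumulated width is reached) and their
local slopes `DS10..DS90`.

*Angles.* `ANG_TOP` and `ANG_BTM` fit a total-least-squares line to the
outermost root pixel per row on each side, within the top and bottom 30%
depth bands, and report the mean absolute angle from the horizontal of
the two sides. The monocot tissue angles `STA_*` sample each path's
tangent where it first reaches depth fractions 0.25/0.5/0.75/0.9;
`RTA_*` sample the tangent at 90% of each path's own arclength.
Dominant angles (`STA_DOM_I/II`, `RTA_DOM_I/II`) are the centres of the
two most populated 10°-wide histogram bins (ties resolved toward the
steeper bin), and `NR_RTP_SEG_I/II` count the paths whose *median*
angle sample falls in each dominant bin — the median per path is robust
to a single stray tangent where a path crosses a junction.

*Diameters.* All diameters derive from the EDT radius \(r\) at skeleton
pixels as \(2r - 0.5\) px. The half-pixel correction reflects the
distance convention (an isolated pixel has EDT value 1, i.e. the
centre-to-centre distance to the nearest background pixel): without it,
\(2r\) overestimates a drawn bar width by exactly one pixel at odd
widths and zero at even widths; with it the error is at most half a
pixel at any width. `DIA_STM` is \(2\max(r) - 0.5\) over all skeleton
pixels whose depth lies in the top `f_stem` (default 5%) of the root
depth. The maximum — not a band average — is used for two reasons
established on synthetic crowns: (i) radii near the crown's top edge are
truncated by the distance to the background *above* the collar, which
biases any average low by up to ~50% for stems wider than the band is
deep; (ii) on wide stems the topmost skeleton tip sits on a corner
bisector that merges with the stem's centre line only at a depth of half
a stem width, so the central path alone may never visit the
full-radius pixels inside the band. The band itself lies above all
branching, so every skeleton pixel in it belongs to the stem and the
maximum is safe. `DIA_STM_SIMPLE` is the median per-row extent over the
same rows and serves as a cross-check.

*Dicot branches.* The taproot is the longest collar-to-tip path.
Branches are graph edges leaving the taproot, classified by the depth
fraction \(z\) of their junction: adventitious (\(z \le 0.05\)), basal
(\(0.05 < z \le 0.15\)), else lateral. The emergence angle is the angle
between the taproot tangent at the junction and the branch's secant
*after skipping the first taproot-radius of branch arclength* — the
initial stretch of a branch's skeleton lies inside the parent root's
body and reflects exit geometry, not growth direction. Lateral lengths
and diameters are measured over the whole subtree hanging off the
taproot.

*Excised samples.* Every component of at least `a_root` (default 200)
px that is not marker or tag is a segment; smaller components are
debris. Segments are skeletonized together and measured per graph
component; `EXC_BRA_FRQ` counts tips in excess of the 2 endpoints per
segment, per mm of total skeleton length.

## Numerical choices

**Thinning.** Zhang–Suen parallel thinning preserves topology but leaves
two kinds of artifacts: corner fillers on staircase diagonals (which can
turn a whole slanted branch into a chain of spurious "junctions") and
2×2 blocks at branch points. A sequential completion pass removes
non-tip pixels whose foreground neighbourhood remains 8-connected
without them and that touch a 4-adjacent background pixel, run to a
fixpoint. Sequential simple-point deletion preserves topology and tips
and leaves a minimal skeleton.

**Small-hole filling.** Before skeletonization the root mask has
interior holes up to `max_hole_area` (default 20 px) filled (4-connected
background regions not touching the border). Pixel-scale holes arise
from thresholding noise and from near-tangent root margins, and each one
seeds a spurious skeleton loop whose micro-edges confuse spur pruning
and branch enumeration. Genuine windows between crossing roots are
orders of magnitude larger and are preserved, as is the skeleton's
topology with respect to the cleaned mask.

**Spur pruning.** A tip-terminated edge is a spur when it is shorter
than \(\max(\texttt{min\_spur\_len}, 1.5 r_J)\), with \(r_J\) the medial
radius at its junction — terminal stubs shorter than the local root
radius are thinning artifacts of blunt ends. Three guards make this
safe: junction pixels linked by ≤ 2 px edges are treated as one cluster
and the cluster must keep at least two external connections (the branch
must continue somewhere); at most (external degree − 2) spurs are cut
per cluster, shortest first; and the prospective collar — the topmost
tip, ties broken toward the root centroid column — is never pruned, as
crowns with branches near the collar legitimately have a collar stub
shorter than the local radius. Pruning then iterates to a fixpoint and
is idempotent.

**Path semantics.** Collar-to-tip paths are minimum-arclength graph
paths (edge weights = polyline length with diagonal steps \(\sqrt 2\)).
On synthetic crowns with known stroke geometry these recover the drawn
angles within 2° at mid-path, which fixed this choice over
steepest-descent alternatives.

**Tie-breaks and degenerate inputs.** Equal-row collar candidates break
toward the root centroid column. An all-background mask is a valid
(empty) segmentation; a scene without foreground raises a structured
`no root found` error that the batch runner converts to a `no-root`
manifest status. Paths that never reach a sampling depth simply
contribute no sample. A trait family that errors yields
`computation-failed` codes for exactly its registry ids.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `threshold` | 0.5 | intensity | global segmentation threshold |
| `marker_diameter_mm` | 20 | mm | known physical marker diameter |
| `c_min` | 0.7 | – | minimum marker circularity |
| `a_min` | 200 | px | minimum marker area |
| `a_root` | 200 | px | minimum root/segment component area |
| `f_top`, `f_btm` | 0.3 | depth fraction | boundary-angle bands |
| `f_stem` | 0.05 | depth fraction | stem-diameter band |
| `min_spur_len` | 10 | px | spur-pruning floor |
| `max_hole_area` | 20 | px | largest interior hole filled |
| `bin_width` | 10 | degrees | dominant-angle histogram bin |
| `tangent_window` | 9 | points | tangent secant window |

The band defaults reflect the geometry of crown photographs (the stem
occupies the top few percent of the root depth; crown angles are
meaningful over the upper and lower thirds); the window of 9 polyline
points balances pixel-quantization noise against curvature smoothing.
All are exposed in `pipeline_config()` and echoed into every batch
manifest for reproducibility.

## The synthetic scene generator

`synthetic_root_spec()` + `render_scene()` draw protocol-compliant
scenes whose ground truth is known in closed form: a dark noisy
background (level 0.1, Gaussian sd 0.03 by default), a bright disc
marker of known pixel and physical diameter, a dense tag rectangle above
the root, and a root built from constant-width strokes — "stadiums",
the set of points within half a width of a centre segment. Three presets
cover the trait families: `monocot_fan` (a vertical stem, then a fan of
straight strokes from the stem foot), `dicot_taproot` (a vertical
taproot with laterals at chosen depth fractions and angles, cut flat at
the collar as the protocol cuts the stem), and `excised_segments`
(disconnected horizontal segments).

Ground truth is computed from the stroke geometry, never from pixels or
from the pipeline: widths from the closed-form per-row extent of the
stadium union evaluated at pixel-centre rows; the stem diameter as the
rasterized stem width; the top/bottom angles by applying the same
total-least-squares boundary-angle *definition* to the analytic,
continuous boundary of the drawn geometry (a fan's top band mixes the
stem edge with the outer stroke line, so no single stroke angle is the
right reference); path counts from the stroke count, emitted only when
adjacent stroke ends are guaranteed to separate by at least a stroke
width plus rasterization margin — heavily overlapping fans cannot have
their stroke count recovered by any skeleton method and are outside the
fixture contract.

Two generator defaults are themselves geometric prerequisites rather
than free dials: the fan's stem is drawn at 12% of the root depth so
that a stem as wide as 40 px both contains a medial disc of its own
width (a stem box must be at least as long as wide for any EDT-based
diameter to be well-posed) and fully contains the 5% measurement band;
and stroke widths below 3 px are rejected because a 1–2 px stroke has no
interior for a medial axis.

What the generator does *not* emulate: soil residue, specular
highlights, blur, perspective distortion, overlapping/occluding roots,
and texture within the root. Passing the synthetic validation therefore
demonstrates that the measurement chain is correct on clean geometry at
realistic scales and noise — it does not certify accuracy on weathered
field images, where threshold choice and debris dominate error.

## Verification at a glance

The test suite validates every operation against independent oracles:
brute-force flood fill for labeling, all-pairs nearest-background search
for the EDT, per-row mask scans for width profiles, closed-form
geometry for angles and diameters, and strict external parsers for CSV
and RSML. The headline check processes 50 seeded synthetic fans
(opening angles 20–80°, stem widths 8–40 px, 5–25 strokes, 640×640 px
at 4 px/mm) through the full pipeline and compares five traits — stem
diameter, median and maximum width, top and bottom angle — against
ground truth: each achieves a coefficient of determination ≥ 0.9 with
per-image tolerances of ±3° on angles, ±10% on stem diameter and ±2 px
on widths. Property suites cover threshold monotonicity, exact mm/px
homogeneity of all length and area traits, mirror invariance of angle
traits, and trait-ordering invariants on 200 reduced-size scenes; batch
runs of 100 scenes are byte-identical across worker counts.
`scripts/acceptance.R` recomputes all of these from scratch for any
seed.

## Worked example

```{r example, eval = FALSE}
library(rootcrown)

# a synthetic crown with known ground truth
scene <- render_scene(synthetic_root_spec("monocot_fan", seed = 7))
result <- process_image(scene$image, pipeline_config(root_class = "monocot"))
glance(result$record)
tidy(result$record)

# compare against what was drawn
merge(scene$truth,
      tidy(result$record)[, c("trait", "value")], by = "trait")

# a real photograph would go through the same call:
# result <- process_image("crown_0012.jpg",
#                         pipeline_config(threshold = 0.4,
#                                         marker_diameter_mm = 25.4,
#                                         root_class = "monocot"))
```

## Known limitations

- A single global threshold cannot rescue unevenly lit scenes; the
  calibration sweep is a visual aid, not an auto-thresholder.
- Heavily overlapping roots merge in the mask; path counts and per-path
  angles then describe the merged geometry, not the individual roots.
- The marker must be the most circular eligible component; a round soil
  clod of comparable size could in principle win the circularity
  contest.
- Depth fractions are measured on the bounding box of the segmented
  root, so debris attached to the crown shifts every depth-dependent
  band.
- The tag is located, not decoded; barcode/QR reading is left to
  external tools via `crop_tag()`.
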