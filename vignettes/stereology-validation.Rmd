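---
title: "Design-based stereology on synthetic phantoms: methods and validation"
author: "stereophantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology on synthetic phantoms: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereophantom)
```

## What this package computes

`stereophantom` implements the two classical design-based stereological
estimators used to quantify a layered organ from serial histological
sections, together with the group statistics that typically follow them
in a four-group toxicology design:

* **Cavalieri point-counting volumetry.** A systematic uniform random
  (SUR) sample of sections is taken: every $d$-th physical section of
  thickness $t$, after a random start uniform in $[0, d\,t)$. A square
  test-point grid with a uniform random offset is overlaid on each
  section, and the volume of a compartment is estimated as
  $$\hat V = \sum P \cdot t \cdot d \cdot a/p,$$
  where $\sum P$ is the total number of grid points hitting the
  compartment over all sections and $a/p$ is the area associated with
  each point. The two randomizations (section start, grid offset) are
  what make $\hat V$ unbiased for any object shape.

* **Physical-dissector cell counting.** Pairs of sections a known
  distance $h$ apart - a *reference* and a *look-up* section - are
  compared; cells seen in the reference but absent from the look-up
  ("disappearing tops") are counted inside an unbiased counting frame.
  The numerical density is
  $$\hat N = \frac{\sum Q}{a/f \cdot h \cdot \sum P_{\mathrm{frames}}},$$
  with $a/f$ the frame area and $\sum P_{\mathrm{frames}}$ the number of
  frame-associated points hitting the reference tissue. The total cell
  number is $\hat N_n = \hat N \cdot \hat V_{\mathrm{ref}}$ with
  $\hat V_{\mathrm{ref}}$ the reference-space volume.

* **Group comparison.** One-way ANOVA per outcome across the four groups
  (control, toxicant, antioxidant, combined) and Fisher LSD pairwise
  post hoc tests at $\alpha = 0.05$ - unadjusted pooled-variance t tests
  on the ANOVA error mean square, which is what "LSD" denotes; a
  Bonferroni column is attached for information only and is not part of
  the procedure.

Real studies of this kind report p-values and bar charts, not raw data,
so the estimators cannot be checked against published numbers. The
package therefore ships a synthetic **tissue phantom** with exactly known
ground truth, and the whole pipeline is validated as parameter recovery
on that phantom.

## The phantom

The organ is idealized as three concentric spherical compartments: a
white-matter core, a granular shell, and an outermost molecular shell
(defaults: outer radius 1000 um, molecular 150 um, granular 200 um).
Concentric spheres are chosen deliberately: shell volumes have closed
forms, so `whole = molecular + granular + white_matter` holds exactly and
every estimator has an exact oracle. The estimators under test are
shape-agnostic by design, so nothing about the validation depends on this
idealization - but see *Limitations*.

Cells (the counted particles, standing in for Purkinje neurons at the
cortical interface) are spheres of radius 10 um whose centers are placed
uniformly at random inside the molecular shell; 500 per specimen by
default.

```{r}
phantom <- generatePhantom(phantomSpec())
trueVolumes(phantom)
```

### The four-group effect model

Treatment effects are multiplicative on compartment volumes and on the
expected cell count, with independent mean-one lognormal animal-level
noise (CV 0.05) per compartment and a Poisson-realized cell count.
Because no group means are published for this kind of study, the
magnitudes are declared package defaults chosen to point in the reported
directions: the toxicant shrinks the molecular and granular layers
(x0.70) and the cell count (x0.60) while enlarging white matter (x1.30);
the antioxidant acts in reverse (x1.15 / x1.20 / x0.85); the combined
group lies between toxicant and control (x0.85 / x0.80 / x1.15); n = 6
animals per group.

Two consequences are worth stating plainly:

* The whole-organ volume is **not** independently scalable - it is the
  sum of the three compartments, so its effective multiplier is the
  volume-weighted consequence of the three per-compartment multipliers
  (about 0.87 for the toxicant, 1.07 for the antioxidant). Treating
  "whole" as a free fourth multiplier would contradict volume
  conservation, which the package keeps exact.
* Per-animal target volumes are hit *exactly*: the three shell radii are
  recovered from the noisy target volumes by successive cube roots, a
  closed form, so conservation survives the group effects and the noise.

## Sectioning and sampling designs

Two section samples are taken per specimen, mirroring how the two
estimators are used at the bench:

* **Cavalieri stack**: $t = 5$ um sections, period chosen per specimen as
  $d = \mathrm{round}(\mathrm{extent} / (10\,t))$ so that about 10
  sections span the organ (d = 40 for the default phantom, slab-to-slab
  distance 200 um). The point grid is auto-calibrated so the expected
  number of tissue hits per specimen - total profile area divided by
  $a/p$ - is the midpoint of the 180-200 range used at the bench.
* **Dissector stack**: the physical dissector is only valid if no cell
  can vanish entirely between the reference and look-up planes, i.e.
  $h \le t + 2r_{\mathrm{cell}}$. The dissector plan picks the largest
  period with $d\,t \le 2 r_{\mathrm{cell}}$ (d = 4, h = 20 um for 10 um
  cells), strictly inside the validity bound. Adjacent kept sections are
  paired disjointly - (1,2), (3,4), ... - by default; sliding pairs are
  available and are used by the exactness tests.

One subtlety cost us a measurable bias before it was caught by the
end-to-end recovery test: for a *fixed* phantom, disjoint pairs anchored
at section 1 sample a deterministic half of the z-axis, so which cells
are countable is not random and $E[\sum Q]$ is conditionally biased by a
few percent. The pairing parity (whether pairs start at section 1 or 2)
is therefore randomized alongside the sectioning start, which restores an
exact 1/2 inclusion probability for every cell top. This is the
disjoint-dissector analogue of the Cavalieri random start.

### Masks and coordinates

Sections are represented as integer label masks (background 0, molecular
1, granular 2, white matter 3) rasterized at the slab mid-plane with
pixel-center labeling and no partial-volume logic; pixels are half-open
`[x, x + pixel)`, slabs are half-open `[z, z + t)`, and points exactly on
a shell boundary belong to the outer compartment. The default pixel size
is 8 um; the pixelated molecular-shell volume differs from the analytic
value by under 0.01%, negligible against the ~2% sampling CV. Stacks
sliced with `renderMasks = FALSE` answer label queries from the exact
generating geometry instead (the pixel-size-to-zero limit), which the
dissector stage uses since it only needs labels at frame centers.
Grid randomization is translation-only; rotation adds nothing for
point-count unbiasedness here and is not modeled.

## The counting-frame rule

The unbiased counting frame accepts a particle profile if it intersects
the frame and does not touch the forbidden line: the left and bottom
edges *plus* the upward extension of the left edge above the top-left
corner and the downward extension below the bottom-right corner. The
right and top edges are acceptance lines. "Touch" means the profile
center lies within one profile radius of the line; point-like profiles
reduce to a half-open membership rule. The extensions are essential: with
them, a complete tiling of the plane by translated frames counts every
particle exactly once, which the test suite asserts exhaustively on
randomized instances, including particles placed exactly on shared frame
edges (adjacent frames are handed bit-identical boundary coordinates so
floating point cannot lose an edge case).

Cell identity between reference and look-up sections uses ground-truth
cell ids in synthetic mode; `profileIdentity()` provides the automated
alternative - greedy nearest-neighbour matching with a distance cap and
lexicographic tie-breaks - for the image-mode workflow, and the two agree
whenever cells are separated by more than twice the match radius.

## Estimator conventions

* All internal arithmetic is in micrometres; conversion to mm^3 happens
  once, at the reporting boundary (1 mm^3 = 1e9 um^3).
* Per-animal estimates pool counts before dividing (ratio of sums), the
  standard stereological aggregation that reduces small-sample ratio
  bias. Single-replicate $\hat N_n$ is still a product of two estimates
  and need not be unbiased; only means over replicates are asserted.
* The reference space for $\hat N_n$ is the molecular-layer volume by
  default (where the phantom's cells live), with
  `referenceSpace = "cortex"` (molecular + granular) available - the
  field's "cortex volume" phrasing is ambiguous, so both are implemented
  and the frame-point tissue test always matches the chosen reference
  space, keeping density and volume consistent.
* `calibrateGrid()` documents its expectation as area-based: expected
  hits = total profile area / $a/p$; it errors when the stack has no
  tissue or when the implied spacing falls below the mask pixel size.
* Degenerate inputs fail loudly: zero frame points is an undefined
  density (no tissue sampled), zero within-group variance everywhere is a
  degenerate ANOVA, mixed dissector heights or missing record columns are
  aggregation errors.

## Statistics

The ANOVA is fitted with base R's `lm`/`anova`; the LSD layer computes
$t = (\bar y_a - \bar y_b) / \sqrt{MSE\,(1/n_a + 1/n_b)}$ on the
within-group degrees of freedom, two-sided. The test suite pins the
closed-form identities (SS decomposition to 1e-10, $F = t^2$ for two
groups, LSD = pooled t test) and the nominal 5% type-I error of the LSD
pair tests under a simulated null. Pups are treated as independent
animals (a flat design); litter effects are not modeled, mirroring the
study design this emulates.

## What validation shows - problem sizes

The acceptance-style checks run at these sizes, chosen to keep the whole
suite comfortably inside a few minutes while leaving Monte-Carlo error
well below each tolerance: 30 specimens for grid calibration; 100 random
starts for the section count; 500 replicates for Cavalieri unbiasedness
(1% tolerance on the mean, ~2% single-estimate CV); 50 phantoms of up to
500 cells for exact dissector-vs-enumeration equality; 200 randomized
tiling instances; 100 replicate pipelines for total-number recovery (5%
tolerance); 10^4 null replicates for the type-I error; 200 simulated
cohorts for the direction pattern.

On the direction pattern: with the default effect sizes and n = 6, the
estimated group means order as reported in essentially every cohort, and
the five toxicant-vs-control LSD comparisons are significant in ~100% of
cohorts. The five antioxidant-vs-control effects are smaller (15-20%)
against a ~6-8% per-animal noise floor (5% biological CV plus the
point-count noise inherent in a 180-200-hit design), so each has roughly
85-90% power and *all ten* comparisons clear significance in only about
half the cohorts. The acceptance test asserts the sign pattern and the
toxicant-side significance; the joint-significance rate is printed
alongside so the power limitation is visible rather than hidden.

## Limitations

* The phantom is a concentric-sphere idealization: no foliation, no
  dendritic morphology, no staining texture, no section deformation,
  loss, or folding. Passing tests demonstrate correctness of the
  *estimators and their randomization*, not robustness to histological
  artifacts.
* Cells are represented as spheres and matched by center; real profile
  shapes and occlusion are out of scope, as is segmenting real
  micrographs into label masks.
* Coefficient-of-error diagnostics (Gundersen-Jensen) and optical
  disector/fractionator variants are intentionally not implemented.
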