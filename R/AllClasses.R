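#' @import methods
NULL

#' PhantomSpec: geometry of a synthetic layered organ
#'
#' Parametric description of the concentric-sphere tissue phantom: an
#' outermost molecular shell, a granular shell beneath it, and a
#' white-matter core. Point-like cells (the counted particles) are placed
#' uniformly at random inside the molecular shell. All lengths are in
#' micrometres.
#'
#' @slot outerRadius Outer radius of the organ (um).
#' @slot granularThickness Thickness of the granular shell (um).
#' @slot molecularThickness Thickness of the outermost molecular shell (um).
#' @slot nCells Number of cells to place in the molecular shell.
#' @slot cellRadius Radius of each spherical cell (um); must be smaller
#'   than the molecular-shell thickness.
#' @slot center Organ center in the phantom coordinate frame (um); the
#'   frame origin is the corner of the organ's bounding box.
#' @slot seed Integer seed controlling cell placement.
#'
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec", representation(
  outerRadius = "numeric",
  granularThickness = "numeric",
  molecularThickness = "numeric",
  nCells = "integer",
  cellRadius = "numeric",
  center = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@granularThickness <= 0 || object@molecularThickness <= 0)
    msg <- c(msg, "layer thicknesses must be positive")
  if (object@outerRadius <= object@granularThickness + object@molecularThickness)
    msg <- c(msg, "outerRadius must exceed granularThickness + molecularThickness")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (object@cellRadius <= 0 || object@cellRadius >= object@molecularThickness)
    msg <- c(msg, "cellRadius must satisfy 0 < cellRadius < molecularThickness")
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite 3-vector")
  if (length(msg)) msg else TRUE
})

#' Phantom: a realized synthetic specimen with known ground truth
#'
#' A generated specimen: the spec it was built from, the 3D cell centers,
#' the closed-form compartment volumes (mm^3) and the true cell count.
#' This object is the oracle against which the stereological estimators
#' are validated.
#'
#' @slot spec The generating [PhantomSpec-class].
#' @slot cells Numeric matrix (nCells x 3) of cell centers (um), columns
#'   x, y, z.
#' @slot trueVolumes Named numeric: molecular, granular, white_matter,
#'   whole (mm^3); whole is exactly the sum of the three compartments.
#' @slot trueCellCount Integer, equals \code{nrow(cells)}.
#' @export
setClass("Phantom", representation(
  spec = "PhantomSpec",
  cells = "matrix",
  trueVolumes = "numeric",
  trueCellCount = "integer"
))

setValidity("Phantom", function(object) {
  msg <- character(0)
  v <- object@trueVolumes
  need <- c("molecular", "granular", "white_matter", "whole")
  if (!all(need %in% names(v))) {
    msg <- c(msg, "trueVolumes must name molecular, granular, white_matter, whole")
  } else if (abs(v[["whole"]] - sum(v[c("molecular", "granular", "white_matter")])) >
             1e-9 * v[["whole"]]) {
    msg <- c(msg, "whole volume must equal the sum of the compartment volumes")
  }
  if (object@trueCellCount != nrow(object@cells))
    msg <- c(msg, "trueCellCount must equal nrow(cells)")
  if (nrow(object@cells) > 0L) {
    s <- object@spec
    rho <- sqrt(colSums((t(object@cells) - s@center)^2))
    inner <- s@outerRadius - s@molecularThickness
    if (any(rho < inner - 1e-9) || any(rho > s@outerRadius + 1e-9))
      msg <- c(msg, "all cell centers must lie inside the molecular shell")
  }
  if (length(msg)) msg else TRUE
})

#' GroupEffectModel: treatment-group effects on phantom geometry
#'
#' Encodes the four-group design (control, ACR, vitC, ACR_vitC) as
#' multiplicative effects on compartment volumes and on expected cell
#' count, plus animal-level lognormal noise. The whole-organ volume is not
#' independently scalable: it is the sum of the three compartments, so its
#' effective multiplier is the volume-weighted consequence of the three
#' per-compartment multipliers.
#'
#' @slot groups Ordered group labels.
#' @slot volumeMultipliers Numeric matrix, rows = groups, columns =
#'   molecular, granular, white_matter; all entries positive, control row
#'   all 1.
#' @slot cellCountMultipliers Named positive numeric, one per group;
#'   control = 1.
#' @slot animalCv Coefficient of variation of the lognormal animal-level
#'   noise applied to each compartment's target volume (mean-1 lognormal).
#' @slot nPerGroup Animals per group.
#' @slot seed Integer seed for cohort generation.
#' @seealso [defaultEffectModel()], [generateCohort()]
#' @export
setClass("GroupEffectModel", representation(
  groups = "character",
  volumeMultipliers = "matrix",
  cellCountMultipliers = "numeric",
  animalCv = "numeric",
  nPerGroup = "integer",
  seed = "integer"
))

setValidity("GroupEffectModel", function(object) {
  msg <- character(0)
  g <- object@groups
  vm <- object@volumeMultipliers
  cm <- object@cellCountMultipliers
  if (!identical(rownames(vm), g))
    msg <- c(msg, "volumeMultipliers rows must match groups")
  if (!identical(colnames(vm), tissueCompartments()))
    msg <- c(msg, "volumeMultipliers columns must be molecular, granular, white_matter")
  if (any(vm <= 0) || any(cm <= 0))
    msg <- c(msg, "all multipliers must be positive")
  if (!identical(names(cm), g))
    msg <- c(msg, "cellCountMultipliers names must match groups")
  if ("control" %in% g) {
    if (any(vm["control", ] != 1) || cm[["control"]] != 1)
      msg <- c(msg, "control multipliers must all be 1")
  }
  if (object@animalCv < 0) msg <- c(msg, "animalCv must be >= 0")
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SectionPlan: systematic uniform random sectioning design
#'
#' Physical sections of thickness \code{t} are cut exhaustively; every
#' \code{d}-th section is kept, so consecutive kept sections are
#' \code{d * t} um apart. The position of the first kept section is a
#' uniform random start in \code{[0, d*t)}, which is what makes the
#' Cavalieri estimator design-unbiased.
#'
#' @slot t Section thickness (um).
#' @slot d Integer sampling period (keep every d-th section).
#' @slot randomStart Offset of the first kept slab (um) in
#'   \code{[0, d*t)}; \code{NA} means "draw it at slicing time".
#' @slot pixelSize Mask pixel size (um/pixel).
#' @seealso [sectionPlan()], [slicePhantom()]
#' @export
setClass("SectionPlan", representation(
  t = "numeric", d = "integer", randomStart = "numeric", pixelSize = "numeric"
))

setValidity("SectionPlan", function(object) {
  msg <- character(0)
  if (object@t <= 0) msg <- c(msg, "t must be > 0")
  if (object@d < 1L) msg <- c(msg, "d must be >= 1")
  if (!is.na(object@randomStart) &&
      (object@randomStart < 0 || object@randomStart >= object@d * object@t))
    msg <- c(msg, "randomStart must lie in [0, d*t)")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' SectionStack: an ordered stack of serial section samples
#'
#' The result of slicing a phantom under a [SectionPlan-class]: for each
#' kept slab, its lower z coordinate, an optional integer label mask
#' (pixel value = compartment of the pixel-center point at the slab
#' mid-plane), and the cell profiles intersected by the slab. The stack
#' also carries the generating geometry (center and shell radii), which
#' supports exact label queries when masks are not rasterized.
#'
#' @slot zStarts Lower z of each slab (um), strictly increasing, constant
#'   spacing \code{d * t}.
#' @slot masks List of integer label matrices (rows = y, cols = x), or
#'   \code{NULL} entries when masks were not rendered.
#' @slot profiles List of data frames with columns \code{x}, \code{y},
#'   \code{cellId}, \code{r} (profile radius at the slab mid-plane, um).
#' @slot plan The realized [SectionPlan-class] (randomStart filled in).
#' @slot geometry List: \code{center}, \code{radii} (rWhite, rGran,
#'   rOuter), \code{maskOrigin} (x, y of mask corner), \code{extent}
#'   (mask width/height, um).
#' @slot legend Named integer label legend.
#' @export
setClass("SectionStack", representation(
  zStarts = "numeric",
  masks = "list",
  profiles = "list",
  plan = "SectionPlan",
  geometry = "list",
  legend = "integer"
))

setValidity("SectionStack", function(object) {
  msg <- character(0)
  n <- length(object@zStarts)
  if (length(object@masks) != n || length(object@profiles) != n)
    msg <- c(msg, "masks and profiles must have one entry per section")
  if (n > 1L) {
    dz <- diff(object@zStarts)
    if (any(dz <= 0)) msg <- c(msg, "section z positions must be strictly increasing")
    step <- object@plan@d * object@plan@t
    if (any(abs(dz - step) > 1e-6))
      msg <- c(msg, "section z spacing must equal d * t")
  }
  if (length(msg)) msg else TRUE
})

#' PointGrid: a randomly translated square test-point lattice
#'
#' Test points sit at \code{offset + (i * spacingU, j * spacingV)} for all
#' integers i, j. Each point carries an associated area
#' a/p = spacingU * spacingV, so (hits x a/p) estimates profile area. The
#' offset is uniform in one grid cell; translation randomness is what
#' makes point counts unbiased for area.
#'
#' @slot spacingU,spacingV Grid spacings (um).
#' @slot offset Numeric length-2 offset (um), each component in
#'   \code{[0, spacing)}.
#' @seealso [placeGrid()], [aP()]
#' @export
setClass("PointGrid", representation(
  spacingU = "numeric", spacingV = "numeric", offset = "numeric"
))

setValidity("PointGrid", function(object) {
  msg <- character(0)
  if (object@spacingU <= 0 || object@spacingV <= 0)
    msg <- c(msg, "spacings must be > 0")
  if (length(object@offset) != 2L ||
      object@offset[1] < 0 || object@offset[1] >= object@spacingU ||
      object@offset[2] < 0 || object@offset[2] >= object@spacingV)
    msg <- c(msg, "offset must lie inside one grid cell")
  if (length(msg)) msg else TRUE
})

#' CountingFrame: the unbiased counting frame
#'
#' A rectangle whose right vertical and top edges are acceptance lines and
#' whose left vertical and bottom edges - together with the upward
#' extension of the left edge from the top-left corner and the downward
#' extension from the bottom-right corner - form the forbidden line.
#' A particle is counted if it intersects the frame and does not touch the
#' forbidden line; under a complete tiling of the plane by translated
#' frames every particle is counted by exactly one frame.
#'
#' @slot width,height Frame side lengths (um).
#' @slot origin Numeric length-2, bottom-left corner (um).
#' @seealso [countingFrame()], [frameAdmits()], [aF()]
#' @export
setClass("CountingFrame", representation(
  width = "numeric", height = "numeric", origin = "numeric"
))

setValidity("CountingFrame", function(object) {
  msg <- character(0)
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "frame sides must be > 0")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must be length 2")
  if (length(msg)) msg else TRUE
})

#' FrameLattice: a complete tiling of the plane by counting frames
#'
#' Frames of one size tiling the plane edge-to-edge, translated by a
#' random offset. Used for exhaustive dissector counting and for the
#' tiling-completeness property of the counting-frame rule.
#'
#' @slot width,height Frame side lengths (um).
#' @slot offset Numeric length-2 lattice translation (um).
#' @seealso [placeFrameLattice()], [frameAt()]
#' @export
setClass("FrameLattice", representation(
  width = "numeric", height = "numeric", offset = "numeric"
))

setValidity("FrameLattice", function(object) {
  if (object@width <= 0 || object@height <= 0) "frame sides must be > 0" else TRUE
})

#' AnovaResult: one-way ANOVA of one outcome across groups
#'
#' @slot outcome Outcome name.
#' @slot F F statistic.
#' @slot dfBetween,dfWithin Degrees of freedom (groups - 1, N - groups).
#' @slot p Two-sided p-value from the F distribution.
#' @slot MSE Pooled within-group mean square (the LSD error term).
#' @slot SS Named numeric: between, within, total sums of squares.
#' @slot groupMeans Named numeric group means.
#' @slot groupN Named integer group sizes.
#' @seealso [oneWayAnova()]
#' @export
setClass("AnovaResult", representation(
  outcome = "character", F = "numeric", dfBetween = "integer",
  dfWithin = "integer", p = "numeric", MSE = "numeric", SS = "numeric",
  groupMeans = "numeric", groupN = "integer"
))

setValidity("AnovaResult", function(object) {
  msg <- character(0)
  if (object@F < 0) msg <- c(msg, "F must be >= 0")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' LSDResult: Fisher LSD pairwise comparisons for one outcome
#'
#' Unadjusted pairwise t tests on the ANOVA's pooled error mean square
#' with its within-group degrees of freedom (Fisher's Least Significant
#' Difference). A Bonferroni-adjusted column is reported for information
#' only; it is not part of the LSD procedure.
#'
#' @slot outcome Outcome name.
#' @slot pairs Data frame: groupA, groupB, meanDiff, se, t, p,
#'   pBonferroni, significant.
#' @slot alpha Significance level used for the \code{significant} flag.
#' @slot dfWithin Error degrees of freedom.
#' @seealso [lsdPosthoc()]
#' @export
setClass("LSDResult", representation(
  outcome = "character", pairs = "data.frame", alpha = "numeric",
  dfWithin = "integer"
))
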