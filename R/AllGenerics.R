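# Generics, accessors and show methods. Accessor functions are the
# supported way to get at slots; slot access with @ is internal.

#' Area associated with each test point (a/p)
#'
#' @param x A [PointGrid-class].
#' @return Area per grid point in um^2.
#' @export
setGeneric("aP", function(x) standardGeneric("aP"))

#' @rdname aP
#' @export
setMethod("aP", "PointGrid", function(x) x@spacingU * x@spacingV)

#' Area associated with each counting frame (a/f)
#'
#' @param x A [CountingFrame-class] or [FrameLattice-class].
#' @return Frame area in um^2.
#' @export
setGeneric("aF", function(x) standardGeneric("aF"))

#' @rdname aF
#' @export
setMethod("aF", "CountingFrame", function(x) x@width * x@height)

#' @rdname aF
#' @export
setMethod("aF", "FrameLattice", function(x) x@width * x@height)

#' Ground-truth compartment volumes of a phantom
#'
#' @param x A [Phantom-class].
#' @return Named numeric (molecular, granular, white_matter, whole), mm^3.
#' @export
setGeneric("trueVolumes", function(x) standardGeneric("trueVolumes"))

#' @rdname trueVolumes
#' @export
setMethod("trueVolumes", "Phantom", function(x) x@trueVolumes)

#' Ground-truth cell count of a phantom
#'
#' @param x A [Phantom-class].
#' @return Integer number of cells.
#' @export
setGeneric("trueCellCount", function(x) standardGeneric("trueCellCount"))

#' @rdname trueCellCount
#' @export
setMethod("trueCellCount", "Phantom", function(x) x@trueCellCount)

#' Cell centers of a phantom
#'
#' @param x A [Phantom-class].
#' @return Numeric matrix (n x 3) of cell centers (um).
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname cellCenters
#' @export
setMethod("cellCenters", "Phantom", function(x) x@cells)

#' Generating spec of a phantom
#'
#' @param x A [Phantom-class].
#' @return The [PhantomSpec-class].
#' @export
setGeneric("phantomSpecOf", function(x) standardGeneric("phantomSpecOf"))

#' @rdname phantomSpecOf
#' @export
setMethod("phantomSpecOf", "Phantom", function(x) x@spec)

#' Number of sections in a stack
#'
#' @param x A [SectionStack-class].
#' @return Integer.
#' @export
setGeneric("nSections", function(x) standardGeneric("nSections"))

#' @rdname nSections
#' @export
setMethod("nSections", "SectionStack", function(x) length(x@zStarts))

#' Lower z coordinates of the slabs in a stack
#'
#' @param x A [SectionStack-class].
#' @return Numeric vector (um).
#' @export
setGeneric("sectionZ", function(x) standardGeneric("sectionZ"))

#' @rdname sectionZ
#' @export
setMethod("sectionZ", "SectionStack", function(x) x@zStarts)

#' Label mask of one section
#'
#' @param x A [SectionStack-class].
#' @param i Section index.
#' @return Integer matrix, or NULL if masks were not rendered.
#' @export
setGeneric("sectionMask", function(x, i) standardGeneric("sectionMask"))

#' @rdname sectionMask
#' @export
setMethod("sectionMask", "SectionStack", function(x, i) x@masks[[i]])

#' Cell profiles intersected by one section
#'
#' @param x A [SectionStack-class].
#' @param i Section index.
#' @return Data frame with columns x, y, cellId, r.
#' @export
setGeneric("sectionProfiles", function(x, i) standardGeneric("sectionProfiles"))

#' @rdname sectionProfiles
#' @export
setMethod("sectionProfiles", "SectionStack", function(x, i) x@profiles[[i]])

#' Sectioning plan of a stack
#'
#' @param x A [SectionStack-class].
#' @return The realized [SectionPlan-class].
#' @export
setGeneric("sectionPlanOf", function(x) standardGeneric("sectionPlanOf"))

#' @rdname sectionPlanOf
#' @export
setMethod("sectionPlanOf", "SectionStack", function(x) x@plan)

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec (concentric-sphere organ)\n",
      sprintf("  outer radius %.1f um; molecular %.1f um; granular %.1f um\n",
              object@outerRadius, object@molecularThickness,
              object@granularThickness),
      sprintf("  cells: %d (radius %.1f um); seed %d\n",
              object@nCells, object@cellRadius, object@seed), sep = "")
})

setMethod("show", "Phantom", function(object) {
  v <- object@trueVolumes
  cat("Phantom with known ground truth\n",
      sprintf("  volumes (mm^3): molecular %.4f, granular %.4f, white %.4f, whole %.4f\n",
              v[["molecular"]], v[["granular"]], v[["white_matter"]],
              v[["whole"]]),
      sprintf("  cells: %d\n", object@trueCellCount), sep = "")
})

setMethod("show", "GroupEffectModel", function(object) {
  cat("GroupEffectModel:", paste(object@groups, collapse = ", "), "\n")
  cat(sprintf("  n per group %d; animal CV %.3f\n",
              object@nPerGroup, object@animalCv))
  print(round(cbind(object@volumeMultipliers,
                    cells = object@cellCountMultipliers), 3))
})

setMethod("show", "SectionPlan", function(object) {
  cat(sprintf(
    "SectionPlan: t = %.2f um, d = %d (period %.2f um), pixel %.2f um, start %s\n",
    object@t, object@d, object@d * object@t, object@pixelSize,
    if (is.na(object@randomStart)) "random" else sprintf("%.2f um", object@randomStart)))
})

setMethod("show", "SectionStack", function(object) {
  cat(sprintf("SectionStack: %d sections, z in [%.1f, %.1f] um, %s masks\n",
              length(object@zStarts),
              if (length(object@zStarts)) min(object@zStarts) else NA,
              if (length(object@zStarts)) max(object@zStarts) else NA,
              if (any(vapply(object@masks, is.null, logical(1)))) "no" else "rendered"))
})

setMethod("show", "PointGrid", function(object) {
  cat(sprintf("PointGrid: spacing %.2f x %.2f um (a/p = %.1f um^2), offset (%.2f, %.2f)\n",
              object@spacingU, object@spacingV, aP(object),
              object@offset[1], object@offset[2]))
})

setMethod("show", "CountingFrame", function(object) {
  cat(sprintf("CountingFrame: %.1f x %.1f um at (%.1f, %.1f); a/f = %.1f um^2\n",
              object@width, object@height, object@origin[1], object@origin[2],
              aF(object)))
})

setMethod("show", "FrameLattice", function(object) {
  cat(sprintf("FrameLattice: %.1f x %.1f um frames, offset (%.2f, %.2f)\n",
              object@width, object@height, object@offset[1], object@offset[2]))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("One-way ANOVA for '%s': F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              object@outcome, object@dfBetween, object@dfWithin, object@F,
              object@p, object@MSE))
})

setMethod("show", "LSDResult", function(object) {
  cat(sprintf("Fisher LSD pairwise comparisons for '%s' (df = %d, alpha = %.2f)\n",
              object@outcome, object@dfWithin, object@alpha))
  print(object@pairs, digits = 4)
})
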