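# The three stereological estimators: Cavalieri volume, dissector
# numerical density, total cell number.

#' Cavalieri volume estimate from point counts
#'
#' Implements V = sum(P) * t * d * a/p: total point hits on the
#' compartment over all sections, times the section thickness, the
#' sampling period and the area per point. Internal arithmetic is in um;
#' the result is converted to mm^3 once at the reporting boundary.
#'
#' @param records Data frame from [countPointsStack()] (columns section,
#'   compartment, P), all from one animal counted with one grid.
#' @param plan The [SectionPlan-class] used to cut the stack.
#' @param grid The [PointGrid-class] used for counting.
#' @param compartment Compartment name, or \code{"organ"} for the union
#'   of all tissue labels.
#' @return List: \code{V} (mm^3), \code{sumP}, \code{t}, \code{d},
#'   \code{aP} (um^2).
#' @examples
#' ## sum(P) = 100, t = 5 um, d = 10, a/p = 10000 um^2  ->  0.05 mm^3
#' @export
cavalieriVolume <- function(records, plan, grid, compartment = "organ") {
  if (!all(c("section", "compartment", "P") %in% names(records)))
    stop("aggregation error: records must have columns section, compartment, P")
  comps <- if (identical(compartment, "organ")) tissueCompartments()
           else compartment
  if (!all(comps %in% records$compartment))
    stop("unknown compartment in volume estimate: ",
         paste(setdiff(comps, records$compartment), collapse = ", "))
  sumP <- sum(records$P[records$compartment %in% comps])
  V <- sumP * plan@t * plan@d * aP(grid) / .UM3_PER_MM3
  list(V = V, sumP = as.integer(sumP), t = plan@t, d = plan@d, aP = aP(grid))
}

#' Dissector numerical density estimate
#'
#' Implements N = sum(Q) / (a/f * h * sum(P)): disappearing cells counted
#' over all dissectors divided by the sampled reference volume, where
#' each frame-associated point hitting the reference tissue contributes
#' a/f * h of volume. Counts are pooled before dividing (ratio of sums),
#' the standard stereological aggregation.
#'
#' @param records Data frame from [countDissectors()] (columns Q, PFrames,
#'   h; attribute aF), all sharing one frame geometry and one h.
#' @return List: \code{N} (cells/mm^3), \code{sumQ}, \code{sumPFrames},
#'   \code{aF} (um^2), \code{h} (um).
#' @examples
#' ## sum(Q) = 10, a/f = 1e4 um^2, h = 10 um, sum(P) = 50 -> 2000 cells/mm^3
#' @export
numericalDensity <- function(records) {
  aF <- attr(records, "aF")
  h <- unique(records$h)
  if (length(h) != 1L)
    stop("aggregation error: all dissector records must share one height h")
  if (is.null(aF)) stop("records must carry the frame area attribute 'aF'")
  sumQ <- sum(records$Q)
  sumPF <- sum(records$PFrames)
  if (sumPF == 0L)
    stop("undefined density: no frame-associated point hit the tissue")
  N <- sumQ / (aF * h * sumPF) * .UM3_PER_MM3
  list(N = N, sumQ = as.integer(sumQ), sumPFrames = as.integer(sumPF),
       aF = aF, h = h)
}

#' Total cell number
#'
#' Implements Nn = N * V: numerical density times the reference-space
#' volume. The reference space must be the one the density was estimated
#' in (here the molecular layer by default, optionally the whole cortex).
#'
#' @param N Numerical density (cells/mm^3), or the list returned by
#'   [numericalDensity()].
#' @param V Reference volume (mm^3), or the list returned by
#'   [cavalieriVolume()].
#' @return Total number of cells (dimensionless).
#' @examples
#' totalNumber(2000, 0.05)   # 100
#' @export
totalNumber <- function(N, V) {
  if (is.list(N)) N <- N$N
  if (is.list(V)) V <- V$V
  if (N < 0 || V < 0) stop("unit error: N and V must be non-negative")
  N * V
}

#' Full stereological estimate panel for one animal
#'
#' Composes the whole per-animal workflow: auto-calibrates a point grid
#' against the Cavalieri stack, counts points per compartment and section,
#' estimates the four compartment volumes, runs the physical dissector
#' with a complete frame tiling on the dissector stack, and combines
#' density with the reference-space volume into the total cell number.
#'
#' @param cavStack Cavalieri [SectionStack-class] (rendered masks, coarse
#'   systematic sample, about 10 sections).
#' @param dissStack Dissector [SectionStack-class] (fine systematic
#'   sample; the dissector height d*t must not exceed cell diameter).
#' @param targetHits Grid calibration range (default \code{c(180, 200)}).
#' @param frameSize Counting-frame side (um), default 100.
#' @param pairMode Dissector pairing, "disjoint" (default) or "sliding".
#' @param referenceSpace "molecular" (default) or "cortex"
#'   (molecular + granular): the reference space used both for the
#'   frame-point tissue test and for the volume entering Nn = N * V.
#' @param seed Optional seed for grid and frame-lattice offsets.
#' @return One-row data frame: vMolecular, vGranular, vWhiteMatter, vWhole
#'   (mm^3), numericalDensity (cells/mm^3), totalNumber, plus the audit
#'   counts sumP, sumQ, sumPFrames, nSections, gridSpacing.
#' @export
estimateAnimal <- function(cavStack, dissStack, targetHits = c(180, 200),
                           frameSize = 100, pairMode = "disjoint",
                           referenceSpace = c("molecular", "cortex"),
                           seed = NULL) {
  referenceSpace <- match.arg(referenceSpace)
  tissue <- if (referenceSpace == "molecular") "molecular"
            else c("molecular", "granular")
  seeds <- if (is.null(seed)) c(NA, NA, NA) else deriveSeeds(seed, 3L)
  spacing <- calibrateGrid(cavStack, targetHits)
  grid <- placeGrid(spacing, seed = if (is.na(seeds[1])) NULL else seeds[1])
  pts <- countPointsStack(cavStack, grid)
  plan <- sectionPlanOf(cavStack)
  vols <- lapply(c(tissueCompartments(), organ = "organ"), function(cp)
    cavalieriVolume(pts, plan, grid, cp))
  names(vols) <- c(tissueCompartments(), "whole")
  # random pairing phase: which half of the z-axis the disjoint dissectors
  # sample must be random for per-specimen unbiasedness
  phase <- withSeed(if (is.na(seeds[3])) NULL else seeds[3],
                    sample(c(0L, 1L), 1L))
  pairs <- makeDissectorPairs(dissStack, mode = pairMode, phase = phase)
  lattice <- placeFrameLattice(frameSize,
                               seed = if (is.na(seeds[2])) NULL else seeds[2])
  recs <- countDissectors(dissStack, pairs, lattice, mode = "id",
                          tissue = tissue)
  dens <- numericalDensity(recs)
  vRef <- if (referenceSpace == "molecular") vols$molecular$V
          else vols$molecular$V + vols$granular$V
  nn <- totalNumber(dens$N, vRef)
  data.frame(
    vMolecular = vols$molecular$V, vGranular = vols$granular$V,
    vWhiteMatter = vols$white_matter$V, vWhole = vols$whole$V,
    numericalDensity = dens$N, totalNumber = nn,
    sumP = vols$whole$sumP, sumQ = dens$sumQ,
    sumPFrames = dens$sumPFrames, nSections = nonEmptySections(cavStack),
    gridSpacing = spacing, stringsAsFactors = FALSE
  )
}

#' Estimate the full cohort
#'
#' Slices and estimates every animal of a cohort: a coarse Cavalieri
#' stack (about \code{targetSections} sections) and a fine dissector
#' stack per animal, then the full estimator panel.
#'
#' @param cohort Result of [generateCohort()].
#' @param t Section thickness (um).
#' @param targetSections Cavalieri sections per animal (about 10).
#' @param pixelSize Mask pixel size (um).
#' @param targetHits,frameSize,pairMode,referenceSpace See
#'   [estimateAnimal()].
#' @param seed Master seed; per-animal substreams are derived from it.
#' @return Data frame: one row per animal (animalId, group, the estimate
#'   panel), the input contract of the group-statistics stage.
#' @export
estimateCohort <- function(cohort, t = 5, targetSections = 10, pixelSize = 8,
                           targetHits = c(180, 200), frameSize = 100,
                           pairMode = "disjoint",
                           referenceSpace = "molecular", seed = 1L) {
  seeds <- deriveSeeds(seed, 3L * length(cohort))
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    e <- cohort[[i]]
    cavPlan <- defaultSectionPlan(e$phantom, t = t,
                                  targetSections = targetSections,
                                  pixelSize = pixelSize)
    cavStack <- slicePhantom(e$phantom, cavPlan, seed = seeds[3L * i - 2L])
    dissPlan <- dissectorSectionPlan(e$phantom, t = t, pixelSize = pixelSize)
    dissStack <- slicePhantom(e$phantom, dissPlan, seed = seeds[3L * i - 1L],
                              renderMasks = FALSE)
    est <- estimateAnimal(cavStack, dissStack, targetHits = targetHits,
                          frameSize = frameSize, pairMode = pairMode,
                          referenceSpace = referenceSpace,
                          seed = seeds[3L * i])
    rows[[i]] <- cbind(data.frame(animalId = e$animalId, group = e$group,
                                  stringsAsFactors = FALSE), est)
  }
  do.call(rbind, rows)
}
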