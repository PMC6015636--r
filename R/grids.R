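# Test-point grids: random placement, point counting, and calibration of
# the grid spacing to a target hit count.

#' Place a test-point grid with uniform random offset
#'
#' @param spacing Grid spacing (um); points carry an associated area
#'   a/p = spacing^2 (or spacing * spacingV for rectangular grids).
#' @param seed Optional integer seed for the offset.
#' @param spacingV Optional second spacing for rectangular grids.
#' @return A [PointGrid-class] with offset uniform in one grid cell.
#' @examples
#' g <- placeGrid(100, seed = 1)
#' aP(g)   # 10000 um^2
#' @export
placeGrid <- function(spacing, seed = NULL, spacingV = spacing) {
  if (spacing <= 0 || spacingV <= 0) stop("spacing must be > 0")
  off <- withSeed(seed, c(stats::runif(1, 0, spacing),
                          stats::runif(1, 0, spacingV)))
  new("PointGrid", spacingU = as.numeric(spacing),
      spacingV = as.numeric(spacingV), offset = off)
}

# Grid node coordinates falling in [x0, x1) x [y0, y1).
gridNodes <- function(grid, x0, y0, x1, y1) {
  iLo <- ceiling((x0 - grid@offset[1]) / grid@spacingU)
  iHi <- ceiling((x1 - grid@offset[1]) / grid@spacingU) - 1
  jLo <- ceiling((y0 - grid@offset[2]) / grid@spacingV)
  jHi <- ceiling((y1 - grid@offset[2]) / grid@spacingV) - 1
  if (iHi < iLo || jHi < jLo)
    return(cbind(x = numeric(0), y = numeric(0)))
  xs <- grid@offset[1] + (iLo:iHi) * grid@spacingU
  ys <- grid@offset[2] + (jLo:jHi) * grid@spacingV
  cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

#' Count grid points hitting a compartment on one section
#'
#' A grid node hits a compartment when the mask pixel containing it
#' (half-open pixel extents \code{[x, x + pixel)}) carries that label;
#' nodes outside the mask are background. Deterministic given the grid.
#'
#' @param stack A [SectionStack-class] with rendered masks.
#' @param i Section index.
#' @param grid A [PointGrid-class].
#' @param compartment One of \code{"molecular"}, \code{"granular"},
#'   \code{"white_matter"}, or \code{"organ"} (any tissue label).
#' @return Integer point count P.
#' @export
countPoints <- function(stack, i, grid, compartment = "organ") {
  codes <- compartmentCodes(stack@legend, compartment)
  g <- stack@geometry
  nodes <- gridNodes(grid, g$maskOrigin[1], g$maskOrigin[2],
                     g$maskOrigin[1] + g$extent, g$maskOrigin[2] + g$extent)
  if (nrow(nodes) == 0L) return(0L)
  lab <- labelAt(stack, i, nodes[, "x"], nodes[, "y"])
  sum(lab %in% codes)
}

compartmentCodes <- function(legend, compartment) {
  if (identical(compartment, "organ")) return(legend[tissueCompartments()])
  if (!compartment %in% names(legend))
    stop("unknown compartment label: ", compartment)
  if (identical(compartment, "background"))
    stop("point counts are defined for tissue compartments, not background")
  legend[compartment]
}

#' Point counts for all sections and compartments of a stack
#'
#' @param stack A [SectionStack-class] with rendered masks.
#' @param grid A [PointGrid-class].
#' @return Data frame: section, compartment, P - one row per section and
#'   tissue compartment. Because every node has exactly one label, the
#'   per-compartment counts decompose the organ count exactly.
#' @export
countPointsStack <- function(stack, grid) {
  comps <- tissueCompartments()
  g <- stack@geometry
  nodes <- gridNodes(grid, g$maskOrigin[1], g$maskOrigin[2],
                     g$maskOrigin[1] + g$extent, g$maskOrigin[2] + g$extent)
  out <- vector("list", nSections(stack))
  for (i in seq_len(nSections(stack))) {
    lab <- if (nrow(nodes)) labelAt(stack, i, nodes[, "x"], nodes[, "y"])
           else integer(0)
    P <- vapply(comps, function(cp) sum(lab == stack@legend[[cp]]), integer(1))
    out[[i]] <- data.frame(section = i, compartment = comps, P = P,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Expected grid hits on a stack for a given spacing
#'
#' Area-based expectation: total tissue profile area over all sections
#' divided by the area per point. Exact in expectation over uniform
#' random grid offsets.
#'
#' @param stack A [SectionStack-class].
#' @param spacing Grid spacing (um).
#' @return Expected total number of tissue hits.
#' @export
expectedHits <- function(stack, spacing) {
  A <- sum(vapply(seq_len(nSections(stack)),
                  function(i) sectionTissueArea(stack, i), numeric(1)))
  A / spacing^2
}

#' Calibrate the grid spacing to a target hit count
#'
#' Returns the spacing whose area-based expected number of tissue hits
#' (total profile area / a/p) equals the midpoint of the target range, so
#' realized counts land inside the range on average. This mirrors the
#' bench practice of choosing a grid so that 180-200 points hit the organ.
#'
#' @param stack A [SectionStack-class].
#' @param targetHits Numeric length-2 inclusive target range (default
#'   \code{c(180, 200)}).
#' @return Grid spacing (um).
#' @examples
#' ## total profile area 1.9 mm^2 and a 190-hit target give 100 um spacing
#' @export
calibrateGrid <- function(stack, targetHits = c(180, 200)) {
  if (length(targetHits) != 2L || any(targetHits <= 0) ||
      targetHits[1] > targetHits[2])
    stop("targetHits must be a positive non-empty range")
  A <- sum(vapply(seq_len(nSections(stack)),
                  function(i) sectionTissueArea(stack, i), numeric(1)))
  if (!is.finite(A) || A <= 0)
    stop("calibration error: stack contains no tissue area")
  spacing <- sqrt(A / mean(targetHits))
  if (spacing < stack@plan@pixelSize)
    stop(sprintf(
      "calibration error: required spacing %.3g um is below the mask pixel size %.3g um",
      spacing, stack@plan@pixelSize))
  spacing
}
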