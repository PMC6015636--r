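# Synthetic tissue phantom generation: a concentric-sphere organ with
# exactly known compartment volumes and a known list of cell centers.

#' Construct a phantom specification
#'
#' The default geometry emulates a small layered organ: 1000 um outer
#' radius with a 150 um molecular shell and a 200 um granular shell over a
#' white-matter core, and 500 cells of radius 10 um confined to the
#' molecular shell (the counted particle population).
#'
#' @param outerRadius Outer organ radius (um).
#' @param granularThickness Granular-shell thickness (um).
#' @param molecularThickness Molecular-shell thickness (um).
#' @param nCells Number of cells.
#' @param cellRadius Cell radius (um).
#' @param center Organ center (um); default puts the bounding box at the
#'   coordinate origin.
#' @param seed Integer seed for cell placement.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec()
#' trueVolumes(generatePhantom(spec))
#' @export
phantomSpec <- function(outerRadius = 1000, granularThickness = 200,
                        molecularThickness = 150, nCells = 500,
                        cellRadius = 10,
                        center = rep(outerRadius, 3), seed = 1L) {
  new("PhantomSpec", outerRadius = as.numeric(outerRadius),
      granularThickness = as.numeric(granularThickness),
      molecularThickness = as.numeric(molecularThickness),
      nCells = as.integer(nCells), cellRadius = as.numeric(cellRadius),
      center = as.numeric(center), seed = as.integer(seed))
}

#' Generate a phantom specimen from a spec
#'
#' Cell centers are drawn uniformly at random inside the molecular shell
#' (radial coordinate by inverse-CDF on r^2 dr, direction isotropic);
#' compartment volumes are computed in closed form as differences of
#' sphere volumes, so \code{whole = molecular + granular + white_matter}
#' holds exactly. Deterministic given the spec's seed.
#'
#' @param spec A [PhantomSpec-class].
#' @return A [Phantom-class].
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  rOuter <- spec@outerRadius
  rInner <- rOuter - spec@molecularThickness
  n <- spec@nCells
  cells <- withSeed(spec@seed, {
    if (n == 0L) {
      matrix(numeric(0), ncol = 3)
    } else {
      u <- stats::runif(n)
      r <- (rInner^3 + u * (rOuter^3 - rInner^3))^(1 / 3)
      dir <- matrix(stats::rnorm(3L * n), ncol = 3)
      len <- sqrt(rowSums(dir^2))
      len[len == 0] <- 1
      sweep(dir / len * r, 2L, spec@center, "+")
    }
  })
  colnames(cells) <- c("x", "y", "z")
  vols <- shellVolumes(rOuter, spec@granularThickness, spec@molecularThickness)
  new("Phantom", spec = spec, cells = cells, trueVolumes = vols,
      trueCellCount = n)
}

#' Construct a group-effect model
#'
#' @param groups Ordered group labels.
#' @param volumeMultipliers Numeric matrix (groups x compartments
#'   molecular/granular/white_matter) of positive multiplicative effects
#'   on compartment volumes.
#' @param cellCountMultipliers Named positive numeric, expected-cell-count
#'   multiplier per group.
#' @param animalCv Coefficient of variation of the mean-1 lognormal
#'   animal-level noise on each compartment's target volume.
#' @param nPerGroup Animals per group.
#' @param seed Integer seed.
#' @return A [GroupEffectModel-class].
#' @seealso [defaultEffectModel()]
#' @export
effectModel <- function(groups, volumeMultipliers, cellCountMultipliers,
                        animalCv = 0.05, nPerGroup = 6L, seed = 1L) {
  new("GroupEffectModel", groups = groups,
      volumeMultipliers = volumeMultipliers,
      cellCountMultipliers = cellCountMultipliers,
      animalCv = as.numeric(animalCv), nPerGroup = as.integer(nPerGroup),
      seed = as.integer(seed))
}

#' Default four-group effect model
#'
#' Encodes the reported effect directions of the neurotoxicant study
#' design: the toxicant (ACR) shrinks the molecular and granular layers
#' and the cell population while enlarging white matter; the antioxidant
#' (vitC) acts in the opposite direction; the combined group sits between
#' the toxicant and control. Group means are not published, so magnitudes
#' are declared package defaults: ACR 0.70 on molecular/granular volume,
#' 1.30 on white matter, 0.60 on cell count; vitC 1.15 / 0.85 / 1.20;
#' ACR_vitC 0.85 / 1.15 / 0.80; animal-level CV 0.05; n = 6 per group.
#'
#' @param animalCv,nPerGroup,seed Overrides of the defaults above.
#' @return A [GroupEffectModel-class].
#' @export
defaultEffectModel <- function(animalCv = 0.05, nPerGroup = 6L, seed = 1L) {
  groups <- c("control", "ACR", "vitC", "ACR_vitC")
  vm <- rbind(
    control  = c(1.00, 1.00, 1.00),
    ACR      = c(0.70, 0.70, 1.30),
    vitC     = c(1.15, 1.15, 0.85),
    ACR_vitC = c(0.85, 0.85, 1.15)
  )
  colnames(vm) <- tissueCompartments()
  cm <- c(control = 1.00, ACR = 0.60, vitC = 1.20, ACR_vitC = 0.80)
  effectModel(groups, vm, cm, animalCv = animalCv, nPerGroup = nPerGroup,
              seed = seed)
}

# Spec whose closed-form volumes equal the target volumes exactly:
# radii recovered by successive cube roots.
specForVolumes <- function(baseSpec, vMolecular, vGranular, vWhiteMatter,
                           nCells, seed) {
  r <- radiiForVolumes(vMolecular, vGranular, vWhiteMatter)
  phantomSpec(outerRadius = r[["rOuter"]],
              granularThickness = r[["rGran"]] - r[["rWhite"]],
              molecularThickness = r[["rOuter"]] - r[["rGran"]],
              nCells = nCells, cellRadius = baseSpec@cellRadius,
              center = rep(r[["rOuter"]], 3), seed = seed)
}

#' Generate a four-group cohort of phantoms
#'
#' For every animal, each compartment's target volume is the base spec's
#' closed-form volume times the group multiplier times an independent
#' mean-1 lognormal animal factor; shell radii are then solved in closed
#' form so the targets are hit exactly (conservation of
#' whole = sum of compartments is preserved by construction). The realized
#' cell count is a Poisson draw around base count x group multiplier.
#' Reproducible given the model seed.
#'
#' @param model A [GroupEffectModel-class].
#' @param baseSpec The control-geometry [PhantomSpec-class].
#' @return A data-frame-like list: one element per animal, each a list
#'   with \code{group}, \code{animalId} and \code{phantom}.
#' @examples
#' cohort <- generateCohort(defaultEffectModel(nPerGroup = 2L), phantomSpec())
#' length(cohort)   # 8 animals
#' @export
generateCohort <- function(model, baseSpec) {
  validObject(model); validObject(baseSpec)
  baseVols <- shellVolumes(baseSpec@outerRadius, baseSpec@granularThickness,
                           baseSpec@molecularThickness)
  sdlog <- sqrt(log1p(model@animalCv^2))
  comps <- tissueCompartments()
  out <- withSeed(model@seed, {
    res <- vector("list", length(model@groups) * model@nPerGroup)
    i <- 0L
    for (g in model@groups) {
      for (a in seq_len(model@nPerGroup)) {
        i <- i + 1L
        noise <- if (model@animalCv > 0)
          stats::rlnorm(3L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        else rep(1, 3L)
        tv <- baseVols[comps] * model@volumeMultipliers[g, comps] * noise
        lambda <- baseSpec@nCells * model@cellCountMultipliers[[g]]
        nCells <- stats::rpois(1L, lambda)
        placeSeed <- sample.int(.Machine$integer.max, 1L)
        sp <- specForVolumes(baseSpec, tv[["molecular"]], tv[["granular"]],
                             tv[["white_matter"]], nCells, placeSeed)
        res[[i]] <- list(group = g,
                         animalId = sprintf("%s_%02d", g, a),
                         phantom = generatePhantom(sp))
      }
    }
    res
  })
  out
}

#' Summarize a cohort's ground truth as a data frame
#'
#' @param cohort Result of [generateCohort()].
#' @return Data frame: animalId, group, true volumes (mm^3) and true cell
#'   count per animal.
#' @export
cohortTruth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(e) {
    v <- trueVolumes(e$phantom)
    data.frame(animalId = e$animalId, group = e$group,
               vMolecular = v[["molecular"]], vGranular = v[["granular"]],
               vWhiteMatter = v[["white_matter"]], vWhole = v[["whole"]],
               cells = trueCellCount(e$phantom),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
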