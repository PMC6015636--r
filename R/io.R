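# On-disk interchange: section stacks as multi-page TIFF label masks with
# a JSON sidecar, phantoms/cohorts as JSON manifests.

#' Write a section stack to TIFF + JSON sidecar
#'
#' Masks go into a multi-page 8-bit TIFF (one page per section, pixel
#' value = label code); section metadata (z positions, realized plan,
#' legend, geometry and per-section cell profiles) goes into a JSON
#' sidecar next to it. Masks are rendered on write if the stack was built
#' without them.
#'
#' @param stack A [SectionStack-class].
#' @param tiffPath Output TIFF path.
#' @param jsonPath Sidecar path; default \code{paste0(tiffPath, ".json")}.
#' @return Invisibly, the two paths.
#' @export
writeSectionStack <- function(stack, tiffPath,
                              jsonPath = paste0(tiffPath, ".json")) {
  plan <- stack@plan
  masks <- stack@masks
  for (i in seq_along(masks)) {
    if (is.null(masks[[i]]))
      masks[[i]] <- renderMask(stack@geometry, stack@zStarts[i] + plan@t / 2,
                               plan@pixelSize)
  }
  tiff::writeTIFF(lapply(masks, function(m) m / 255), tiffPath,
                  bits.per.sample = 8L)
  meta <- list(
    zStarts = stack@zStarts,
    plan = list(t = plan@t, d = plan@d, randomStart = plan@randomStart,
                pixelSize = plan@pixelSize),
    legend = as.list(stack@legend),
    geometry = list(center = stack@geometry$center,
                    radii = as.list(stack@geometry$radii),
                    maskOrigin = stack@geometry$maskOrigin,
                    extent = stack@geometry$extent),
    profiles = lapply(stack@profiles, function(p)
      list(x = p$x, y = p$y, cellId = p$cellId, r = p$r))
  )
  jsonlite::write_json(meta, jsonPath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(tiff = tiffPath, json = jsonPath))
}

#' Read a section stack written by [writeSectionStack()]
#'
#' Validates the file pair: a missing sidecar, a mask value absent from
#' the legend, or non-monotone z positions are format errors naming the
#' offending file or label.
#'
#' @param tiffPath TIFF path.
#' @param jsonPath Sidecar path; default \code{paste0(tiffPath, ".json")}.
#' @return A [SectionStack-class]; the round trip reproduces labels and
#'   metadata exactly and profile coordinates to full double precision.
#' @export
readSectionStack <- function(tiffPath, jsonPath = paste0(tiffPath, ".json")) {
  if (!file.exists(tiffPath)) stop("mask TIFF not found: ", tiffPath)
  if (!file.exists(jsonPath))
    stop("missing sidecar: expected JSON metadata at ", jsonPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  pages <- tiff::readTIFF(tiffPath, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  legend <- unlist(meta$legend)
  storage.mode(legend) <- "integer"
  masks <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    storage.mode(m) <- "integer"
    bad <- setdiff(unique(as.vector(m)), legend)
    if (length(bad))
      stop(sprintf("legend mismatch in %s page %d: unknown label %s",
                   tiffPath, i, paste(bad, collapse = ", ")))
    m
  })
  z <- as.numeric(meta$zStarts)
  if (length(z) != length(masks))
    stop("sidecar z list length does not match TIFF page count in ", jsonPath)
  if (length(z) > 1L && any(diff(z) <= 0))
    stop("non-monotone z positions in sidecar ", jsonPath)
  plan <- sectionPlan(t = meta$plan$t, d = meta$plan$d,
                      randomStart = meta$plan$randomStart,
                      pixelSize = meta$plan$pixelSize)
  profs <- lapply(meta$profiles, function(p)
    data.frame(x = as.numeric(unlist(p$x)), y = as.numeric(unlist(p$y)),
               cellId = as.integer(unlist(p$cellId)),
               r = as.numeric(unlist(p$r))))
  geometry <- list(center = as.numeric(meta$geometry$center),
                   radii = unlist(meta$geometry$radii),
                   maskOrigin = as.numeric(meta$geometry$maskOrigin),
                   extent = as.numeric(meta$geometry$extent))
  new("SectionStack", zStarts = z, masks = masks, profiles = profs,
      plan = plan, geometry = geometry, legend = legend)
}

# Phantom <-> plain list (for JSON cohort manifests).
phantomToList <- function(phantom) {
  s <- phantom@spec
  list(spec = list(outerRadius = s@outerRadius,
                   granularThickness = s@granularThickness,
                   molecularThickness = s@molecularThickness,
                   nCells = s@nCells, cellRadius = s@cellRadius,
                   center = s@center, seed = s@seed),
       trueVolumes = as.list(phantom@trueVolumes),
       trueCellCount = phantom@trueCellCount,
       cells = unname(phantom@cells))
}

phantomFromList <- function(x) {
  sp <- phantomSpec(outerRadius = x$spec$outerRadius,
                    granularThickness = x$spec$granularThickness,
                    molecularThickness = x$spec$molecularThickness,
                    nCells = x$spec$nCells, cellRadius = x$spec$cellRadius,
                    center = unlist(x$spec$center), seed = x$spec$seed)
  cells <- x$cells
  if (is.null(cells) || length(cells) == 0) {
    cells <- matrix(numeric(0), ncol = 3)
  } else if (!is.matrix(cells)) {
    cells <- do.call(rbind, lapply(cells, unlist))
  }
  colnames(cells) <- c("x", "y", "z")
  new("Phantom", spec = sp, cells = cells,
      trueVolumes = unlist(x$trueVolumes),
      trueCellCount = as.integer(x$trueCellCount))
}

#' Write a cohort manifest (specs, seeds, ground truth) to JSON
#'
#' The manifest is the fixture format consumed by tests and by the CLI
#' simulate stage: it records, for every animal, the generating spec and
#' seed, the exact ground-truth volumes and the cell list.
#'
#' @param cohort Result of [generateCohort()].
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeCohortManifest <- function(cohort, path) {
  jsonlite::write_json(
    lapply(cohort, function(e)
      list(animalId = e$animalId, group = e$group,
           phantom = phantomToList(e$phantom))),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest written by [writeCohortManifest()]
#'
#' @param path JSON path.
#' @return A cohort list like [generateCohort()] returns.
#' @export
readCohortManifest <- function(path) {
  if (!file.exists(path)) stop("cohort manifest not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  lapply(raw, function(e)
    list(group = e$group, animalId = e$animalId,
         phantom = phantomFromList(e$phantom)))
}
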