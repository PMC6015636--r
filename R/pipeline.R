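# Configuration and the end-to-end pipeline:
# simulate -> slice -> count -> estimate -> compare.

#' Default pipeline configuration
#'
#' A nested list holding every tunable of the pipeline, each overridable:
#' phantom geometry, group-effect model, sectioning design, grid
#' calibration target, dissector design and statistics settings, plus a
#' single master seed from which all per-stage substreams are derived.
#'
#' @return Named nested list.
#' @export
defaultPipelineConfig <- function() {
  list(
    phantom = list(outerRadius = 1000, granularThickness = 200,
                   molecularThickness = 150, nCells = 500, cellRadius = 10),
    effects = list(
      groups = c("control", "ACR", "vitC", "ACR_vitC"),
      volumeMultipliers = rbind(
        control = c(1.00, 1.00, 1.00), ACR = c(0.70, 0.70, 1.30),
        vitC = c(1.15, 1.15, 0.85), ACR_vitC = c(0.85, 0.85, 1.15)),
      cellCountMultipliers = c(control = 1.00, ACR = 0.60,
                               vitC = 1.20, ACR_vitC = 0.80),
      animalCv = 0.05, nPerGroup = 6L),
    sectioning = list(t = 5, targetSections = 10, pixelSize = 8),
    grid = list(targetHits = c(180, 200)),
    dissector = list(frameSize = 100, pairMode = "disjoint",
                     referenceSpace = "molecular"),
    stats = list(alpha = 0.05),
    seed = 1L
  )
}

# Deep-merge user overrides into the defaults.
mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Build a pipeline configuration from overrides
#'
#' @param ... Named overrides of [defaultPipelineConfig()] entries
#'   (nested lists are merged field-wise).
#' @return The merged configuration list.
#' @export
pipelineConfig <- function(...) {
  mergeConfig(defaultPipelineConfig(), list(...))
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly: unspecified fields fall back to
#' defaults on read.
#'
#' @param path YAML file path.
#' @param config Configuration list (for writing).
#' @return The configuration list ([readPipelineConfig()]) or,
#'   invisibly, the path ([writePipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effects$volumeMultipliers)) {
    vm <- raw$effects$volumeMultipliers
    if (!is.matrix(vm)) vm <- do.call(rbind, vm)
    raw$effects$volumeMultipliers <- vm
  }
  if (!is.null(raw$effects$cellCountMultipliers))
    raw$effects$cellCountMultipliers <- unlist(raw$effects$cellCountMultipliers)
  if (!is.null(raw$effects$groups))
    raw$effects$groups <- unlist(raw$effects$groups)
  if (!is.null(raw$grid$targetHits))
    raw$grid$targetHits <- as.numeric(unlist(raw$grid$targetHits))
  mergeConfig(defaultPipelineConfig(), raw)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- config
  vm <- cfg$effects$volumeMultipliers
  cfg$effects$volumeMultipliers <-
    stats::setNames(lapply(seq_len(nrow(vm)), function(i) unname(vm[i, ])),
                    rownames(vm))
  cfg$effects$cellCountMultipliers <- as.list(cfg$effects$cellCountMultipliers)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Config blocks -> domain objects.
configBaseSpec <- function(config, seed) {
  p <- config$phantom
  phantomSpec(outerRadius = p$outerRadius,
              granularThickness = p$granularThickness,
              molecularThickness = p$molecularThickness,
              nCells = p$nCells, cellRadius = p$cellRadius, seed = seed)
}

configEffectModel <- function(config, seed) {
  e <- config$effects
  vm <- e$volumeMultipliers
  colnames(vm) <- tissueCompartments()
  effectModel(e$groups, vm, e$cellCountMultipliers, animalCv = e$animalCv,
              nPerGroup = e$nPerGroup, seed = seed)
}

# Stable CSV writer: fixed "%.12g" numeric formatting so byte-identical
# reruns are a testable contract.
writeStableCsv <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- formatNum(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate -> slice -> count -> estimate -> compare for one
#' configuration and writes the estimates table, the statistics report
#' (ANOVA + LSD), the significance pattern and a run manifest into
#' \code{outDir}. Idempotent: rerunning with the same configuration and
#' seed reproduces byte-identical CSV outputs.
#'
#' @param config Configuration list (see [pipelineConfig()]).
#' @param outDir Output directory (created if missing); \code{NULL} runs
#'   in memory only.
#' @param verbose Log stage-level audit counts (sections kept, total
#'   point and cell counts).
#' @return List: \code{estimates}, \code{stats} (from [compareGroups()]),
#'   \code{truth}, \code{manifest}, and the output file paths.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL,
                        verbose = FALSE) {
  seeds <- deriveSeeds(config$seed, c("cohort", "placement", "estimate"))
  model <- configEffectModel(config, seeds[["cohort"]])
  baseSpec <- configBaseSpec(config, seeds[["placement"]])
  cohort <- generateCohort(model, baseSpec)
  if (verbose)
    message(sprintf("simulate: %d animals in %d groups",
                    length(cohort), length(model@groups)))
  estimates <- estimateCohort(
    cohort, t = config$sectioning$t,
    targetSections = config$sectioning$targetSections,
    pixelSize = config$sectioning$pixelSize,
    targetHits = config$grid$targetHits,
    frameSize = config$dissector$frameSize,
    pairMode = config$dissector$pairMode,
    referenceSpace = config$dissector$referenceSpace,
    seed = seeds[["estimate"]])
  if (verbose)
    message(sprintf(
      "estimate: mean sections %.1f, mean sum(P) %.1f, mean sum(Q) %.1f",
      mean(estimates$nSections), mean(estimates$sumP), mean(estimates$sumQ)))
  stats <- compareGroups(estimates, alpha = config$stats$alpha)
  truth <- cohortTruth(cohort)
  paths <- NULL
  manifest <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    estPath <- file.path(outDir, "estimates.csv")
    writeStableCsv(estimates, estPath)
    anovaDf <- do.call(rbind, lapply(stats$anova, function(a)
      data.frame(outcome = a@outcome, F = a@F, dfBetween = a@dfBetween,
                 dfWithin = a@dfWithin, p = a@p, MSE = a@MSE)))
    anovaPath <- file.path(outDir, "anova.csv")
    writeStableCsv(anovaDf, anovaPath)
    lsdDf <- do.call(rbind, lapply(stats$lsd, function(r)
      cbind(outcome = r@outcome, r@pairs)))
    lsdPath <- file.path(outDir, "lsd.csv")
    writeStableCsv(lsdDf, lsdPath)
    patPath <- file.path(outDir, "pattern.csv")
    writeStableCsv(stats$pattern, patPath)
    truthPath <- file.path(outDir, "truth.csv")
    writeStableCsv(truth, truthPath)
    paths <- c(estimates = estPath, anova = anovaPath, lsd = lsdPath,
               pattern = patPath, truth = truthPath)
    manifest <- list(
      package = "stereophantom",
      version = as.character(utils::packageVersion("stereophantom")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = config$seed,
      config = config,
      outputs = as.list(tools::md5sum(unname(paths)))
    )
    cfg <- manifest$config
    vm <- cfg$effects$volumeMultipliers
    cfg$effects$volumeMultipliers <-
      stats::setNames(lapply(seq_len(nrow(vm)), function(i) unname(vm[i, ])),
                      rownames(vm))
    manifest$config <- cfg
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  list(estimates = estimates, stats = stats, truth = truth,
       manifest = manifest, paths = paths)
}
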