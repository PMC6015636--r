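# Shared fixtures: small phantoms and stacks built in code at test time.

tinySpec <- function(nCells = 50L, seed = 11L) {
  phantomSpec(outerRadius = 300, granularThickness = 60,
              molecularThickness = 50, nCells = nCells, cellRadius = 8,
              seed = seed)
}

tinyPhantom <- function(nCells = 50L, seed = 11L) {
  generatePhantom(tinySpec(nCells = nCells, seed = seed))
}

# A dissector-ready stack (fine sectioning, no masks) for a tiny phantom.
tinyDissectorStack <- function(phantom = tinyPhantom(), seed = 3L) {
  slicePhantom(phantom, dissectorSectionPlan(phantom), seed = seed,
               renderMasks = FALSE)
}

# Brute-force oracle: number of cells whose top (z + cellRadius) lies in
# the half-open interval (zLo, zHi].
cellTopsIn <- function(phantom, zLo, zHi) {
  tops <- cellCenters(phantom)[, "z"] + phantom@spec@cellRadius
  sum(tops > zLo & tops <= zHi)
}

# Balanced long outcome table from a list of per-group value vectors.
makeOutcomeTable <- function(values, outcome = "y") {
  do.call(rbind, lapply(names(values), function(g)
    data.frame(animalId = paste0(g, "_", seq_along(values[[g]])),
               group = g, outcome = outcome, value = values[[g]],
               stringsAsFactors = FALSE)))
}
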