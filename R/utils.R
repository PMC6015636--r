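# Internal constants and small helpers shared across modules.

# Label legend for section masks. Integer codes are what gets rasterized
# into masks and written to TIFF; names are the user-facing compartments.
.LEGEND <- c(background = 0L, molecular = 1L, granular = 2L, white_matter = 3L)

# All internal arithmetic is in micrometres; volumes are converted to mm^3
# once, at the reporting boundary.
.UM3_PER_MM3 <- 1e9

#' Compartment label legend
#'
#' Returns the named integer legend used in section label masks:
#' \code{background = 0}, \code{molecular = 1}, \code{granular = 2},
#' \code{white_matter = 3}.
#'
#' @return Named integer vector.
#' @export
compartmentLegend <- function() .LEGEND

#' Names of the tissue compartments
#'
#' @return Character vector \code{c("molecular", "granular", "white_matter")}.
#' @export
tissueCompartments <- function() names(.LEGEND)[-1L]

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible sub-stream seeds from a master seed
#'
#' Draws \code{n} integer seeds from a stream initialised with the master
#' seed, so that each pipeline stage (or each animal) gets its own named
#' substream and one stage can be re-randomized without perturbing others.
#'
#' @param master Integer master seed.
#' @param n Number of seeds, or a character vector of substream names.
#' @return Integer vector of seeds (named if \code{n} was names).
#' @export
deriveSeeds <- function(master, n) {
  nms <- NULL
  if (is.character(n)) { nms <- n; n <- length(n) }
  s <- withSeed(master, sample.int(.Machine$integer.max, n))
  if (!is.null(nms)) names(s) <- nms
  s
}

# Volume of a sphere of radius r (same cubed units as r).
sphereVolume <- function(r) 4 / 3 * pi * r^3

# Closed-form spherical-shell volumes (mm^3) for the concentric-sphere
# organ: white-matter core, granular shell, outermost molecular shell.
shellVolumes <- function(outerRadius, granularThickness, molecularThickness) {
  rGran <- outerRadius - molecularThickness
  rWhite <- rGran - granularThickness
  v <- c(
    molecular    = sphereVolume(outerRadius) - sphereVolume(rGran),
    granular     = sphereVolume(rGran) - sphereVolume(rWhite),
    white_matter = sphereVolume(rWhite)
  ) / .UM3_PER_MM3
  c(v, whole = unname(sum(v)))
}

# Inverse of shellVolumes: radii (um) hitting target compartment volumes
# (mm^3) exactly. Successive cube roots; exact, no iteration needed.
radiiForVolumes <- function(vMolecular, vGranular, vWhiteMatter) {
  k <- 3 / (4 * pi) * .UM3_PER_MM3
  rWhite <- (k * vWhiteMatter)^(1 / 3)
  rGran <- (k * (vWhiteMatter + vGranular))^(1 / 3)
  rOuter <- (k * (vWhiteMatter + vGranular + vMolecular))^(1 / 3)
  c(rWhite = rWhite, rGran = rGran, rOuter = rOuter)
}

# Compartment code for squared radial distances rho2 given squared radii.
# Points exactly on a boundary go to the outer compartment (half-open
# shells [r_inner, r_outer)).
labelFromRho2 <- function(rho2, radii) {
  br <- c(radii[["rWhite"]], radii[["rGran"]], radii[["rOuter"]])^2
  idx <- findInterval(rho2, br)
  c(3L, 2L, 1L, 0L)[idx + 1L]
}

# Minimal-overhead data.frame constructor for equal-length columns
# (hot path: per-section profile tables).
quickDF <- function(...) {
  d <- list(...)
  class(d) <- "data.frame"
  attr(d, "row.names") <- .set_row_names(length(d[[1]]))
  d
}

# Format numbers for CSV output with stable, platform-independent text.
formatNum <- function(x) {
  out <- vapply(x, function(v) sprintf("%.12g", v), character(1))
  out
}
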