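# Systematic uniform random sectioning of a phantom into a stack of label
# masks plus per-section cell profiles.

#' Construct a sectioning plan
#'
#' @param t Section thickness (um); default 5.
#' @param d Integer sampling period: every d-th physical section is kept,
#'   so kept sections are \code{d * t} um apart.
#' @param randomStart Offset of the first kept slab in \code{[0, d*t)}
#'   (um); \code{NA} (default) draws it uniformly at slicing time.
#' @param pixelSize Mask pixel size (um).
#' @return A [SectionPlan-class].
#' @export
sectionPlan <- function(t = 5, d = 1L, randomStart = NA_real_, pixelSize = 8) {
  new("SectionPlan", t = as.numeric(t), d = as.integer(d),
      randomStart = as.numeric(randomStart), pixelSize = as.numeric(pixelSize))
}

#' Default Cavalieri sectioning plan for a phantom
#'
#' Chooses the sampling period so that about \code{targetSections}
#' sections span the organ: \code{d = round(extent / (targetSections * t))},
#' with the organ extent equal to its diameter. With the default geometry
#' (2000 um diameter, t = 5, 10 target sections) this gives d = 40 and a
#' 200 um slab-to-slab distance.
#'
#' @param phantom A [Phantom-class].
#' @param t Section thickness (um).
#' @param targetSections Desired number of sections through the organ.
#' @param pixelSize Mask pixel size (um).
#' @return A [SectionPlan-class].
#' @export
defaultSectionPlan <- function(phantom, t = 5, targetSections = 10,
                               pixelSize = 8) {
  extent <- 2 * phantom@spec@outerRadius
  d <- max(1L, as.integer(round(extent / (targetSections * t))))
  sectionPlan(t = t, d = d, pixelSize = pixelSize)
}

#' Sectioning plan for physical-dissector counting
#'
#' The physical dissector is only valid when no cell can vanish entirely
#' between the reference and look-up sections, i.e. the dissector height
#' h = d * t must not exceed the cell diameter plus section thickness.
#' This plan picks the largest period satisfying
#' \code{d * t <= 2 * cellRadius} (strictly below the validity bound), so
#' adjacent kept sections form valid dissector pairs.
#'
#' @param phantom A [Phantom-class].
#' @param t Section thickness (um).
#' @param pixelSize Mask pixel size (um).
#' @return A [SectionPlan-class].
#' @export
dissectorSectionPlan <- function(phantom, t = 5, pixelSize = 8) {
  d <- max(1L, as.integer(floor(2 * phantom@spec@cellRadius / t)))
  sectionPlan(t = t, d = d, pixelSize = pixelSize)
}

# Rasterize the label mask of one slab mid-plane. mask[row, col] covers
# y in [(row-1)*p, row*p), x likewise; pixel label = compartment of the
# pixel-center point.
renderMask <- function(geometry, zMid, pixelSize) {
  n <- as.integer(ceiling(geometry$extent / pixelSize))
  ctr <- geometry$center
  x <- geometry$maskOrigin[1] + (seq_len(n) - 0.5) * pixelSize
  y <- geometry$maskOrigin[2] + (seq_len(n) - 0.5) * pixelSize
  rho2 <- outer((y - ctr[2])^2, (x - ctr[1])^2, "+") + (zMid - ctr[3])^2
  m <- labelFromRho2(rho2, geometry$radii)
  dim(m) <- c(n, n)
  m
}

#' Slice a phantom into a systematically sampled section stack
#'
#' Slabs \code{[z, z + t)} are taken every \code{d * t} um starting at a
#' uniform random offset in \code{[0, d*t)} from the lower edge of the
#' organ's bounding box. Each kept slab gets (optionally) a label mask
#' rasterized at the slab mid-plane and the list of cell profiles: every
#' cell whose sphere intersects the slab contributes a profile at its
#' (x, y) center with the profile radius evaluated at the mid-plane.
#'
#' @param phantom A [Phantom-class].
#' @param plan A [SectionPlan-class]; if \code{plan@randomStart} is NA the
#'   start is drawn using \code{seed}.
#' @param seed Optional integer seed for the random start.
#' @param renderMasks If FALSE, masks are left unrendered (label queries
#'   then use the exact generating geometry, the pixel-size-to-zero limit
#'   of the mask). Point counting requires rendered masks.
#' @return A [SectionStack-class].
#' @export
slicePhantom <- function(phantom, plan, seed = NULL, renderMasks = TRUE) {
  validObject(phantom); validObject(plan)
  sp <- phantom@spec
  step <- plan@d * plan@t
  start <- plan@randomStart
  if (is.na(start)) start <- withSeed(seed, stats::runif(1, 0, step))
  zMin <- sp@center[3] - sp@outerRadius
  zMax <- sp@center[3] + sp@outerRadius
  z0 <- zMin + start
  if (z0 >= zMax) stop("phantom entirely outside the sampled range")
  zStarts <- seq(z0, zMax, by = step)
  # drop trailing slabs that cannot intersect the organ
  zStarts <- zStarts[zStarts < zMax]
  nSec <- length(zStarts)
  geometry <- list(
    center = sp@center,
    radii = c(rWhite = sp@outerRadius - sp@molecularThickness - sp@granularThickness,
              rGran = sp@outerRadius - sp@molecularThickness,
              rOuter = sp@outerRadius),
    maskOrigin = sp@center[1:2] - sp@outerRadius,
    extent = 2 * sp@outerRadius
  )
  masks <- vector("list", nSec)
  if (renderMasks) {
    # shared in-plane distance grid; per-section only the z term changes
    np <- as.integer(ceiling(geometry$extent / plan@pixelSize))
    xs <- geometry$maskOrigin[1] + (seq_len(np) - 0.5) * plan@pixelSize
    ys <- geometry$maskOrigin[2] + (seq_len(np) - 0.5) * plan@pixelSize
    rho2xy <- outer((ys - sp@center[2])^2, (xs - sp@center[1])^2, "+")
    for (i in seq_len(nSec)) {
      dz2 <- (zStarts[i] + plan@t / 2 - sp@center[3])^2
      m <- labelFromRho2(rho2xy + dz2, geometry$radii)
      dim(m) <- c(np, np)
      masks[[i]] <- m
    }
  }
  profiles <- rep(list(data.frame(x = numeric(0), y = numeric(0),
                                  cellId = integer(0), r = numeric(0))), nSec)
  cells <- phantom@cells
  if (nrow(cells) > 0L) {
    r <- sp@cellRadius
    zc <- cells[, 3]
    # candidate slabs k (1-based) with zStarts[k] in (zc - r - t, zc + r)
    kLo <- pmax(1L, as.integer(ceiling((zc - r - plan@t - z0) / step + 1e-12)) + 1L)
    kHi <- pmin(nSec, as.integer(floor((zc + r - z0) / step - 1e-12)) + 1L)
    keep <- which(kLo <= kHi)
    if (length(keep)) {
      idx <- unlist(lapply(keep, function(i) seq.int(kLo[i], kHi[i])))
      cid <- rep.int(keep, kHi[keep] - kLo[keep] + 1L)
      zs <- zStarts[idx]
      ok <- (zc[cid] + r > zs) & (zc[cid] - r < zs + plan@t)
      idx <- idx[ok]; cid <- cid[ok]
      if (length(idx)) {
        dz <- (zs[ok] + plan@t / 2) - zc[cid]
        pr <- sqrt(pmax(0, r^2 - dz^2))
        ord <- order(idx, cid)
        idx <- idx[ord]; cid <- cid[ord]; pr <- pr[ord]
        f <- factor(idx, levels = seq_len(nSec))
        xs <- split(cells[cid, 1], f); ys <- split(cells[cid, 2], f)
        ids <- split(cid, f); rs <- split(pr, f)
        for (k in seq_len(nSec)) {
          if (!length(ids[[k]])) next
          profiles[[k]] <- quickDF(x = unname(xs[[k]]), y = unname(ys[[k]]),
                                   cellId = ids[[k]], r = rs[[k]])
        }
      }
    }
  }
  realized <- sectionPlan(t = plan@t, d = plan@d, randomStart = start,
                          pixelSize = plan@pixelSize)
  stk <- new("SectionStack", zStarts = zStarts, masks = masks,
             profiles = profiles, plan = realized, geometry = geometry,
             legend = .LEGEND)
  if (!any(vapply(seq_len(nSec), function(i) sectionHasTissue(stk, i),
                  logical(1))))
    stop("empty stack: no section intersects the organ")
  stk
}

#' Count sections that contain tissue
#'
#' A section is non-empty when its label mask contains any tissue label
#' (or, for unrendered masks, when its mid-plane intersects the organ).
#'
#' @param stack A [SectionStack-class].
#' @return Integer count of non-empty sections.
#' @export
nonEmptySections <- function(stack) {
  sum(vapply(seq_len(nSections(stack)),
             function(i) sectionHasTissue(stack, i), logical(1)))
}

# Does section i contain any tissue (by mask if rendered, else geometry)?
sectionHasTissue <- function(stack, i) {
  m <- stack@masks[[i]]
  if (!is.null(m)) return(any(m != 0L))
  zMid <- stack@zStarts[i] + stack@plan@t / 2
  abs(zMid - stack@geometry$center[3]) < stack@geometry$radii[["rOuter"]]
}

#' Query compartment labels at continuous coordinates on a section
#'
#' Uses the rendered mask (pixel containing the point, half-open pixel
#' extents) when available, and the exact generating geometry at the slab
#' mid-plane otherwise.
#'
#' @param stack A [SectionStack-class].
#' @param i Section index.
#' @param x,y Coordinates (um), vectorized.
#' @return Integer label codes (see [compartmentLegend()]); points outside
#'   the mask extent are background.
#' @export
labelAt <- function(stack, i, x, y) {
  g <- stack@geometry
  m <- stack@masks[[i]]
  if (!is.null(m)) {
    p <- stack@plan@pixelSize
    col <- floor((x - g$maskOrigin[1]) / p) + 1
    row <- floor((y - g$maskOrigin[2]) / p) + 1
    out <- rep(0L, length(x))
    ok <- col >= 1 & col <= ncol(m) & row >= 1 & row <= nrow(m)
    out[ok] <- m[cbind(row[ok], col[ok])]
    out
  } else {
    zMid <- stack@zStarts[i] + stack@plan@t / 2
    rho2 <- (x - g$center[1])^2 + (y - g$center[2])^2 + (zMid - g$center[3])^2
    labelFromRho2(rho2, g$radii)
  }
}

# Tissue area (um^2) of one section: mask pixel count x pixel area if
# rendered, else the analytic disc area at the slab mid-plane.
sectionTissueArea <- function(stack, i, compartments = tissueCompartments()) {
  codes <- stack@legend[compartments]
  m <- stack@masks[[i]]
  if (!is.null(m)) {
    hits <- if (length(compartments) == 3L) sum(m != 0L)
            else sum(m %in% codes)
    return(hits * stack@plan@pixelSize^2)
  }
  g <- stack@geometry
  zMid <- stack@zStarts[i] + stack@plan@t / 2
  dz2 <- (zMid - g$center[3])^2
  discArea <- function(r) pi * max(0, r^2 - dz2)
  areas <- c(
    molecular = discArea(g$radii[["rOuter"]]) - discArea(g$radii[["rGran"]]),
    granular = discArea(g$radii[["rGran"]]) - discArea(g$radii[["rWhite"]]),
    white_matter = discArea(g$radii[["rWhite"]])
  )
  sum(areas[compartments])
}

#' Pair consecutive sections into physical dissectors
#'
#' Consecutive kept sections are paired (reference = lower z, look-up =
#' the next section); the dissector height h is the slab-to-slab distance
#' \code{d * t}. In \code{"disjoint"} mode (the default) every other
#' consecutive pair is used - (1,2), (3,4), ... for \code{phase = 0} or
#' (2,3), (4,5), ... for \code{phase = 1}; in \code{"sliding"} mode every
#' consecutive pair is used, so the sampled z-intervals tile the stack
#' exhaustively.
#'
#' For a single specimen the disjoint z-intervals cover a fixed half of
#' the axis, so which half is sampled must itself be randomized: choosing
#' the phase at random (on top of the random sectioning start) makes every
#' cell's top fall in a sampled interval with probability exactly 1/2,
#' which is what keeps the disjoint dissector design-unbiased per
#' specimen.
#'
#' @param stack A [SectionStack-class] with at least two sections.
#' @param mode "disjoint" or "sliding".
#' @param phase 0 or 1: parity of the first reference section in
#'   disjoint mode (ignored for sliding pairs; forced to 0 when the stack
#'   has only two sections).
#' @return Data frame: referenceIndex, lookupIndex, h (um).
#' @export
makeDissectorPairs <- function(stack, mode = c("disjoint", "sliding"),
                               phase = 0L) {
  mode <- match.arg(mode)
  n <- nSections(stack)
  if (n < 2L) stop("need at least two sections to form dissector pairs")
  if (!phase %in% c(0L, 1L)) stop("phase must be 0 or 1")
  if (n < 3L) phase <- 0L
  h <- stack@plan@d * stack@plan@t
  ref <- if (mode == "disjoint") seq(1L + as.integer(phase), n - 1L, by = 2L)
         else seq_len(n - 1L)
  data.frame(referenceIndex = ref, lookupIndex = ref + 1L, h = h)
}
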