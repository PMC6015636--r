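# The unbiased counting frame and physical-dissector counting.

#' Construct a counting frame
#'
#' @param width,height Frame side lengths (um).
#' @param origin Bottom-left corner (um).
#' @return A [CountingFrame-class].
#' @export
countingFrame <- function(width, height = width, origin = c(0, 0)) {
  new("CountingFrame", width = as.numeric(width), height = as.numeric(height),
      origin = as.numeric(origin))
}

#' Place a randomly translated tiling of counting frames
#'
#' @param width,height Frame side lengths (um).
#' @param seed Optional integer seed for the lattice offset (uniform in
#'   one frame).
#' @return A [FrameLattice-class].
#' @export
placeFrameLattice <- function(width, height = width, seed = NULL) {
  off <- withSeed(seed, c(stats::runif(1, 0, width), stats::runif(1, 0, height)))
  new("FrameLattice", width = as.numeric(width), height = as.numeric(height),
      offset = off)
}

#' Extract one frame of a lattice
#'
#' @param lattice A [FrameLattice-class].
#' @param i,j Integer lattice indices (any integers).
#' @return The [CountingFrame-class] at origin
#'   \code{offset + (i * width, j * height)}.
#' @export
frameAt <- function(lattice, i, j) {
  countingFrame(lattice@width, lattice@height,
                origin = lattice@offset + c(i * lattice@width,
                                            j * lattice@height))
}

# Distance from points (x, y) to an axis-aligned segment or ray.
# Vertical: x = vx, y in [y1, y2]; horizontal: y = hy, x in [x1, x2].
distToVSeg <- function(x, y, vx, y1, y2) {
  dy <- pmax(pmax(y1 - y, y - y2), 0)
  sqrt((x - vx)^2 + dy^2)
}
distToHSeg <- function(x, y, hy, x1, x2) {
  dx <- pmax(pmax(x1 - x, x - x2), 0)
  sqrt((y - hy)^2 + dx^2)
}

#' Apply the unbiased counting-frame rule
#'
#' A (circular) particle profile with center (x, y) and radius r is
#' counted by a frame when it intersects the closed frame rectangle and
#' does not touch the forbidden line: the left and bottom edges plus the
#' upward extension of the left edge from the top-left corner and the
#' downward extension from the bottom-right corner. Touching the right
#' vertical or top edge (the acceptance line) is allowed. "Touching" means
#' the center's distance to the line is at most r; point-like profiles
#' (r = 0) therefore follow the half-open convention
#' \code{[left, right) x [bottom, top)} away from corners. The forbidden
#' extensions are what make a complete tiling of the plane count each
#' particle exactly once.
#'
#' @param x,y Profile centers (um), vectorized.
#' @param frame A [CountingFrame-class].
#' @param r Profile radii (um), scalar or vector; default 0.
#' @return Logical vector: admitted by this frame.
#' @export
frameAdmits <- function(x, y, frame, r = 0) {
  admitVec(x, y, rep_len(r, length(x)), frame@origin[1], frame@origin[2],
           frame@origin[1] + frame@width, frame@origin[2] + frame@height)
}

# Vectorized admission test on explicit edge coordinates (fx < x1,
# fy < y1); the edges are passed in rather than derived from a width so
# that a tiling can hand two adjacent frames the bit-identical shared
# edge. Same rule as frameAdmits without S4 construction (hot path).
admitVec <- function(x, y, r, fx, fy, x1, y1) {
  # intersects the closed rectangle: distance from center to rect <= r
  dx <- pmax(pmax(fx - x, x - x1), 0)
  dy <- pmax(pmax(fy - y, y - y1), 0)
  intersects <- sqrt(dx^2 + dy^2) <= r
  # forbidden line: left edge + its upward extension, bottom edge,
  # downward extension from the bottom-right corner
  forb <- distToVSeg(x, y, fx, fy, Inf) <= r |        # left edge + up ray
          distToHSeg(x, y, fy, fx, x1) <= r |         # bottom edge
          distToVSeg(x, y, x1, -Inf, fy) <= r         # down ray at right
  intersects & !forb
}

#' Count particles under a complete frame tiling
#'
#' Applies [frameAdmits()] for every profile against the frames of a
#' tiling lattice in its 3x3 neighbourhood and returns, per profile, the
#' number of frames that admit it. The defining property of the counting
#' frame is that this is exactly 1 for every particle.
#'
#' @param x,y Profile centers (um).
#' @param lattice A [FrameLattice-class].
#' @param r Profile radii (um), scalar or vector.
#' @return Integer vector: number of admitting frames per profile.
#' @export
frameTilingCounts <- function(x, y, lattice, r = 0) {
  n <- length(x)
  r <- rep_len(r, n)
  counts <- integer(n)
  w <- lattice@width; h <- lattice@height
  i0 <- floor((x - lattice@offset[1]) / w)
  j0 <- floor((y - lattice@offset[2]) / h)
  for (di in -1:1) for (dj in -1:1) {
    # edges computed as offset + k * side so adjacent frames share the
    # bit-identical boundary coordinate
    fx <- lattice@offset[1] + (i0 + di) * w
    fy <- lattice@offset[2] + (j0 + dj) * h
    x1 <- lattice@offset[1] + (i0 + di + 1) * w
    y1 <- lattice@offset[2] + (j0 + dj + 1) * h
    counts <- counts + admitVec(x, y, r, fx, fy, x1, y1)
  }
  counts
}

#' Match cell profiles between two sections by nearest neighbour
#'
#' Greedy nearest-neighbour matching of profile centers: repeatedly link
#' the closest unmatched reference/look-up pair while the distance is at
#' most \code{matchRadius}; ties are broken lexicographically (reference
#' index, then look-up index), so the result is deterministic. Reference
#' profiles left unmatched are treated as disappearances. This automates
#' what is done by eye on photographs of stained section pairs.
#'
#' @param referenceProfiles,lookupProfiles Data frames with columns
#'   \code{x}, \code{y}.
#' @param matchRadius Maximum matching distance (um).
#' @return Integer vector, one entry per reference profile: the matched
#'   look-up row index or \code{NA} for a disappearance.
#' @export
profileIdentity <- function(referenceProfiles, lookupProfiles, matchRadius) {
  if (matchRadius <= 0) stop("matchRadius must be > 0")
  nr <- nrow(referenceProfiles); nl <- nrow(lookupProfiles)
  map <- rep(NA_integer_, nr)
  if (nr == 0L || nl == 0L) return(map)
  d <- outer(referenceProfiles$x, lookupProfiles$x, "-")^2 +
       outer(referenceProfiles$y, lookupProfiles$y, "-")^2
  d <- sqrt(d)
  d[d > matchRadius] <- Inf
  repeat {
    m <- min(d)
    if (!is.finite(m)) break
    hit <- which(d == m, arr.ind = TRUE)
    # lexicographic tie-break: smallest reference row, then look-up row
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    map[hit[1]] <- hit[2]
    d[hit[1], ] <- Inf
    d[, hit[2]] <- Inf
  }
  map
}

#' Physical-dissector count in one counting frame
#'
#' Counts the cells that are present in the reference section and absent
#' from the look-up section (the "disappearing tops" the dissector
#' samples) whose reference profile is admitted by the counting-frame
#' rule. With \code{mode = "id"} disappearance uses the phantom's
#' ground-truth cell identities; with \code{mode = "match"} profiles are
#' linked with [profileIdentity()]. The frame's associated test point (one
#' per frame, at the frame center) contributes \code{PFrames = 1} when it
#' hits the chosen tissue compartments on the reference section.
#'
#' @param stack A [SectionStack-class].
#' @param pair One row of [makeDissectorPairs()] output (or a list with
#'   \code{referenceIndex}, \code{lookupIndex}, \code{h}).
#' @param frame A [CountingFrame-class].
#' @param mode "id" (ground-truth identities) or "match".
#' @param matchRadius Matching radius (um) for \code{mode = "match"}.
#' @param tissue Compartments whose hit by the frame point counts toward
#'   the reference-space area sample (default the molecular layer, where
#'   the cells live).
#' @return List: \code{Q}, \code{PFrames}, \code{h}, \code{aF}.
#' @export
dissectorCount <- function(stack, pair, frame, mode = c("id", "match"),
                           matchRadius = NULL, tissue = "molecular") {
  mode <- match.arg(mode)
  ref <- sectionProfiles(stack, pair$referenceIndex)
  look <- sectionProfiles(stack, pair$lookupIndex)
  gone <- disappearedProfiles(ref, look, mode, matchRadius)
  admitted <- if (nrow(gone)) frameAdmits(gone$x, gone$y, frame) else logical(0)
  ctr <- frame@origin + c(frame@width, frame@height) / 2
  pf <- as.integer(labelAt(stack, pair$referenceIndex, ctr[1], ctr[2]) %in%
                     stack@legend[tissue])
  list(Q = sum(admitted), PFrames = pf, h = pair$h, aF = aF(frame))
}

# Reference profiles with no counterpart in the look-up section.
disappearedProfiles <- function(ref, look, mode, matchRadius) {
  if (mode == "id") {
    ref[!(ref$cellId %in% look$cellId), , drop = FALSE]
  } else {
    if (is.null(matchRadius))
      stop("mode = 'match' requires a matchRadius")
    map <- profileIdentity(ref, look, matchRadius)
    ref[is.na(map), , drop = FALSE]
  }
}

#' Dissector counts over all pairs with a complete frame tiling
#'
#' Runs the physical dissector on every pair: disappearing reference
#' profiles are counted through the counting-frame rule applied to the
#' full tiling (each admitted exactly once), and every frame whose center
#' lies within the section extent contributes its associated point to
#' \code{PFrames} when it hits the chosen tissue.
#'
#' @param stack A [SectionStack-class].
#' @param pairs Data frame from [makeDissectorPairs()].
#' @param lattice A [FrameLattice-class].
#' @param mode,matchRadius,tissue See [dissectorCount()].
#' @return Data frame with one row per pair: referenceIndex, lookupIndex,
#'   h, Q, PFrames; attributes \code{aF} and \code{h}.
#' @export
countDissectors <- function(stack, pairs, lattice, mode = c("id", "match"),
                            matchRadius = NULL, tissue = "molecular") {
  mode <- match.arg(mode)
  g <- stack@geometry
  # frame centers of all lattice frames intersecting the section extent
  w <- lattice@width; h2 <- lattice@height
  iLo <- floor((g$maskOrigin[1] - lattice@offset[1]) / w)
  iHi <- ceiling((g$maskOrigin[1] + g$extent - lattice@offset[1]) / w)
  jLo <- floor((g$maskOrigin[2] - lattice@offset[2]) / h2)
  jHi <- ceiling((g$maskOrigin[2] + g$extent - lattice@offset[2]) / h2)
  cx <- lattice@offset[1] + (iLo:iHi) * w + w / 2
  cy <- lattice@offset[2] + (jLo:jHi) * h2 + h2 / 2
  centers <- cbind(x = rep(cx, times = length(cy)),
                   y = rep(cy, each = length(cx)))
  codes <- stack@legend[tissue]
  Q <- integer(nrow(pairs)); PF <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ref <- sectionProfiles(stack, pairs$referenceIndex[k])
    look <- sectionProfiles(stack, pairs$lookupIndex[k])
    gone <- disappearedProfiles(ref, look, mode, matchRadius)
    if (nrow(gone)) {
      cnt <- frameTilingCounts(gone$x, gone$y, lattice)
      Q[k] <- sum(cnt > 0L)
    }
    lab <- labelAt(stack, pairs$referenceIndex[k],
                   centers[, "x"], centers[, "y"])
    PF[k] <- sum(lab %in% codes)
  }
  out <- data.frame(referenceIndex = pairs$referenceIndex,
                    lookupIndex = pairs$lookupIndex, h = pairs$h,
                    Q = Q, PFrames = PF)
  attr(out, "aF") <- aF(lattice)
  attr(out, "h") <- unique(pairs$h)
  out
}
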