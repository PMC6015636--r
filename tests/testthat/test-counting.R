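# A hand-built one-section stack with a constant-label mask.
constantMaskStack <- function(L = 100, pixelSize = 1, label = "molecular") {
  legend <- compartmentLegend()
  n <- as.integer(L / pixelSize)
  mask <- matrix(legend[[label]], n, n)
  new("SectionStack", zStarts = 0,
      masks = list(mask),
      profiles = list(data.frame(x = numeric(0), y = numeric(0),
                                 cellId = integer(0), r = numeric(0))),
      plan = sectionPlan(t = 5, d = 1L, randomStart = 0,
                         pixelSize = pixelSize),
      geometry = list(center = c(L / 2, L / 2, 0),
                      radii = c(rWhite = 1, rGran = 2, rOuter = 3),
                      maskOrigin = c(0, 0), extent = L),
      legend = legend)
}

test_that("point counts on constant masks follow the lattice arithmetic", {
  st <- constantMaskStack(L = 100, label = "molecular")
  g <- placeGrid(10, seed = 1L)
  # full-cover mask, spacing dividing the side: exactly (L/s)^2 nodes hit
  expect_identical(countPoints(st, 1, g, "molecular"), 100L)
  expect_identical(countPoints(st, 1, g, "organ"), 100L)
  expect_identical(countPoints(st, 1, g, "granular"), 0L)
  bg <- constantMaskStack(L = 100, label = "background")
  for (cp in tissueCompartments())
    expect_identical(countPoints(bg, 1, g, cp), 0L)
  expect_error(countPoints(st, 1, g, "cortex_x"), "unknown compartment")
})

test_that("mean point count recovers annulus area over random offsets", {
  p <- generatePhantom(tinySpec(nCells = 0L))
  plan <- sectionPlan(t = 5, d = 10L, randomStart = 47.5, pixelSize = 1)
  st <- slicePhantom(p, plan)
  i <- which.min(abs(sectionZ(st) + 2.5 - 300))
  analytic <- pi * (300^2 - 250^2)   # molecular annulus at the equator
  spacing <- 45
  P <- vapply(1:1000, function(s)
    countPoints(st, i, placeGrid(spacing, seed = s), "molecular"),
    integer(1))
  expect_lt(abs(mean(P) * spacing^2 - analytic) / analytic, 0.02)
})

test_that("counting-frame rule handles edges and corners as drawn", {
  fr <- countingFrame(10, 10, origin = c(0, 0))
  expect_true(frameAdmits(5, 5, fr))          # interior
  expect_true(frameAdmits(10, 5, fr))         # right edge: acceptance
  expect_true(frameAdmits(5, 10, fr))         # top edge: acceptance
  expect_true(frameAdmits(10, 10, fr))        # top-right corner
  expect_false(frameAdmits(0, 5, fr))         # left edge: forbidden
  expect_false(frameAdmits(5, 0, fr))         # bottom edge: forbidden
  expect_false(frameAdmits(0, 0, fr))         # bottom-left corner
  expect_false(frameAdmits(0, 10, fr))        # top-left corner
  expect_false(frameAdmits(0, 15, fr))        # upward extension of left edge
  expect_false(frameAdmits(10, -3, fr))       # downward extension at right
  expect_false(frameAdmits(15, 5, fr))        # outside
  # a disc overlapping the frame but touching the left line is rejected
  expect_false(frameAdmits(2, 5, fr, r = 3))
  expect_true(frameAdmits(2, 5, fr, r = 1.5))
  # a disc outside the frame but overlapping it across the top is counted
  expect_true(frameAdmits(5, 11, fr, r = 2))
})

test_that("a complete frame tiling counts every particle exactly once", {
  set.seed(99)
  for (rep in 1:200) {
    w <- runif(1, 5, 20); h <- runif(1, 5, 20)
    lat <- placeFrameLattice(w, h, seed = rep)
    n <- sample(1:40, 1)
    x <- runif(n, -50, 50); y <- runif(n, -50, 50)
    # mix in points exactly on frame boundaries
    snap <- sample(n, ceiling(n / 4))
    x[snap] <- lat@offset[1] + round((x[snap] - lat@offset[1]) / w) * w
    r <- if (rep %% 2) 0 else runif(n, 0, min(w, h) / 2 * 0.95)
    counts <- frameTilingCounts(x, y, lat, r)
    expect_true(all(counts == 1L))
  }
})

test_that("profile matching is greedy, deterministic and radius-limited", {
  ref <- data.frame(x = c(0, 10, 20), y = c(0, 0, 0))
  none <- data.frame(x = numeric(0), y = numeric(0))
  expect_identical(profileIdentity(ref, none, 5), rep(NA_integer_, 3))
  # identical lists match perfectly
  expect_identical(profileIdentity(ref, ref, 1), 1:3)
  # beyond the radius means disappearance
  look <- data.frame(x = c(0.4, 30), y = c(0, 0))
  expect_identical(profileIdentity(ref, look, 2), c(1L, NA, NA))
  # lexicographic tie-break: two references equidistant to one profile
  refTie <- data.frame(x = c(-1, 1), y = c(0, 0))
  lookTie <- data.frame(x = 0, y = 0)
  expect_identical(profileIdentity(refTie, lookTie, 5), c(1L, NA))
})

test_that("matching recovers ground-truth identity for separated cells", {
  p <- tinyPhantom(nCells = 40L, seed = 21L)
  st <- tinyDissectorStack(p)
  pairs <- makeDissectorPairs(st, "sliding")
  for (k in seq_len(nrow(pairs))) {
    ref <- sectionProfiles(st, pairs$referenceIndex[k])
    look <- sectionProfiles(st, pairs$lookupIndex[k])
    d <- as.matrix(stats::dist(rbind(ref[c("x", "y")], look[c("x", "y")])))
    diag(d) <- Inf
    if (!nrow(ref) || min(d) <= 2 * 4) next  # only well-separated pairs
    map <- profileIdentity(ref, look, matchRadius = 4)
    expected <- match(ref$cellId, look$cellId)
    expect_identical(map, expected)
  }
})

test_that("dissector counting obeys the disappearance rule", {
  p <- tinyPhantom(nCells = 60L, seed = 5L)
  st <- tinyDissectorStack(p)
  pairs <- makeDissectorPairs(st, "sliding")
  fr <- countingFrame(1000, 1000, origin = c(-200, -200))  # covers all
  # identical reference and look-up content: nothing disappears
  samePair <- list(referenceIndex = pairs$referenceIndex[1],
                   lookupIndex = pairs$referenceIndex[1], h = pairs$h[1])
  expect_identical(dissectorCount(st, samePair, fr)$Q, 0L)
  for (k in seq_len(nrow(pairs))) {
    ref <- sectionProfiles(st, pairs$referenceIndex[k])
    look <- sectionProfiles(st, pairs$lookupIndex[k])
    res <- dissectorCount(st, pairs[k, ], fr)
    # cells present in both sections contribute nothing
    expect_identical(res$Q, sum(!(ref$cellId %in% look$cellId)))
  }
})

test_that("exhaustive sliding dissectors equal the brute-force top count", {
  for (s in 1:8) {
    p <- tinyPhantom(nCells = sample(20:120, 1), seed = s)
    st <- tinyDissectorStack(p, seed = s + 100L)
    pairs <- makeDissectorPairs(st, "sliding")
    lat <- placeFrameLattice(37, seed = s)
    recs <- countDissectors(st, pairs, lat)
    z <- sectionZ(st)
    oracle <- cellTopsIn(p, z[1], z[nSections(st)])
    expect_identical(sum(recs$Q), oracle)
  }
})

test_that("the frame-associated point samples the chosen tissue", {
  p <- generatePhantom(tinySpec(nCells = 0L))
  st <- slicePhantom(p, sectionPlan(t = 5, d = 3L, randomStart = 0),
                     renderMasks = FALSE)
  i <- which.min(abs(sectionZ(st) + 2.5 - 300))
  pair <- list(referenceIndex = i, lookupIndex = i + 1L, h = 15)
  # frame centred deep in the white-matter core
  core <- countingFrame(20, 20, origin = c(290, 290))
  expect_identical(dissectorCount(st, pair, core, tissue = "molecular")$PFrames, 0L)
  expect_identical(dissectorCount(st, pair, core,
                                  tissue = "white_matter")$PFrames, 1L)
  # frame centred in the molecular annulus (x = 300 + 270 = near outer rim)
  rim <- countingFrame(20, 20, origin = c(560, 290))
  expect_identical(dissectorCount(st, pair, rim, tissue = "molecular")$PFrames, 1L)
})
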