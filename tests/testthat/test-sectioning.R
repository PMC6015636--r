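test_that("systematic slicing has exact spacing and is seeded", {
  p <- tinyPhantom()
  plan <- sectionPlan(t = 5, d = 12L, pixelSize = 6)
  st <- slicePhantom(p, plan, seed = 4L)
  z <- sectionZ(st)
  expect_true(all(abs(diff(z) - 60) < 1e-9))
  st2 <- slicePhantom(p, plan, seed = 4L)
  expect_identical(sectionZ(st), sectionZ(st2))
  expect_identical(sectionMask(st, 3), sectionMask(st2, 3))
  expect_identical(sectionProfiles(st, 3), sectionProfiles(st2, 3))
  # fixed random start overrides the seed draw
  planFixed <- sectionPlan(t = 5, d = 12L, randomStart = 17, pixelSize = 6)
  st3 <- slicePhantom(p, planFixed)
  expect_equal(sectionZ(st3)[1], (p@spec@center[3] - 300) + 17)
})

test_that("default plan yields about ten tissue-bearing sections", {
  p <- generatePhantom(phantomSpec(nCells = 0))
  plan <- defaultSectionPlan(p)
  expect_identical(plan@d, 40L)          # 2000 um / (10 * 5 um)
  n <- vapply(1:100, function(s)
    nonEmptySections(slicePhantom(p, plan, seed = s, renderMasks = FALSE)),
    integer(1))
  expect_lt(abs(mean(n) - 10), 1)
})

test_that("phantoms with no cells yield empty profiles everywhere", {
  p <- generatePhantom(tinySpec(nCells = 0L))
  st <- slicePhantom(p, sectionPlan(t = 5, d = 4L), seed = 1L,
                     renderMasks = FALSE)
  expect_true(all(vapply(seq_len(nSections(st)),
                         function(i) nrow(sectionProfiles(st, i)) == 0L,
                         logical(1))))
})

test_that("mask compartment areas converge to the analytic annuli", {
  p <- generatePhantom(tinySpec(nCells = 0L))
  # fine rasterization: pixel = outer radius / 500
  # start chosen so one slab mid-plane passes through the equator (z = 300)
  plan <- sectionPlan(t = 5, d = 10L, randomStart = 47.5,
                      pixelSize = 300 / 500)
  st <- slicePhantom(p, plan)
  i <- which.min(abs(sectionZ(st) + 2.5 - p@spec@center[3]))
  m <- sectionMask(st, i)
  legend <- compartmentLegend()
  pixArea <- plan@pixelSize^2
  analytic <- c(molecular = pi * (300^2 - 250^2),
                granular = pi * (250^2 - 190^2),
                white_matter = pi * 190^2)
  for (cp in names(analytic)) {
    est <- sum(m == legend[[cp]]) * pixArea
    expect_lt(abs(est - analytic[[cp]]) / analytic[[cp]], 0.01)
  }
})

test_that("every cell surfaces as a profile when sampling is dense enough", {
  p <- tinyPhantom(nCells = 120L, seed = 2L)
  # d*t = 15 um <= 2 * cellRadius + t = 21 um
  st <- slicePhantom(p, sectionPlan(t = 5, d = 3L), seed = 6L,
                     renderMasks = FALSE)
  seen <- sort(unique(unlist(lapply(seq_len(nSections(st)), function(i)
    sectionProfiles(st, i)$cellId))))
  expect_identical(seen, seq_len(120L))
  # and each profile's generating cell is within reach of its slab
  for (i in seq_len(nSections(st))) {
    pr <- sectionProfiles(st, i)
    if (!nrow(pr)) next
    zc <- cellCenters(p)[pr$cellId, "z"]
    zMid <- sectionZ(st)[i] + 2.5
    expect_true(all(abs(zc - zMid) < p@spec@cellRadius + 2.5))
  }
})

test_that("grid placement has the right area, determinism and uniformity", {
  g <- placeGrid(100, seed = 1L)
  expect_identical(aP(g), 10000)
  expect_identical(g@offset, placeGrid(100, seed = 1L)@offset)
  offs <- t(vapply(1:2000, function(s) placeGrid(100, seed = s)@offset,
                   numeric(2)))
  expect_true(all(offs >= 0 & offs < 100))
  expect_gt(stats::ks.test(offs[, 1] / 100, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(offs[, 2] / 100, "punif")$p.value, 0.01)
  expect_error(placeGrid(-5), "spacing")
})

test_that("grid calibration follows the area law", {
  p <- generatePhantom(phantomSpec(nCells = 0))
  st <- slicePhantom(p, defaultSectionPlan(p), seed = 3L)
  spacing <- calibrateGrid(st, c(180, 200))
  A <- sum(vapply(seq_len(nSections(st)), function(i)
    stereophantom:::sectionTissueArea(st, i), numeric(1)))
  expect_equal(spacing, sqrt(A / 190), tolerance = 1e-12)
  # doubling the spacing quarters the expected hits
  expect_equal(expectedHits(st, 2 * spacing) * 4, expectedHits(st, spacing),
               tolerance = 1e-12)
  expect_equal(expectedHits(st, spacing), 190, tolerance = 1e-12)
})

test_that("dissector pairing modes and heights are correct", {
  p <- generatePhantom(phantomSpec(nCells = 0))
  plan <- sectionPlan(t = 5, d = 40L)
  st <- slicePhantom(p, plan, seed = 2L, renderMasks = FALSE)
  expect_identical(nSections(st), 10L)
  dj <- makeDissectorPairs(st, "disjoint")
  expect_identical(nrow(dj), 5L)
  expect_identical(dj$referenceIndex, c(1L, 3L, 5L, 7L, 9L))
  sl <- makeDissectorPairs(st, "sliding")
  expect_identical(nrow(sl), 9L)
  expect_true(all(dj$h == 200) && all(sl$h == 200))
  one <- slicePhantom(p, sectionPlan(t = 5, d = 500L), seed = 1L,
                      renderMasks = FALSE)
  expect_lt(nSections(one), 2L)
  expect_error(makeDissectorPairs(one), "two sections")
})
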