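test_that("closed-form volumes match analytic spherical shells exactly", {
  p <- generatePhantom(phantomSpec(outerRadius = 1000,
                                   granularThickness = 200,
                                   molecularThickness = 150))
  v <- trueVolumes(p)
  expect_equal(v[["whole"]], 4 / 3 * pi * 1000^3 / 1e9, tolerance = 1e-12)
  expect_equal(v[["whole"]], 4.18879, tolerance = 1e-5)
  rGran <- 850; rWhite <- 650
  expect_equal(v[["white_matter"]], 4 / 3 * pi * rWhite^3 / 1e9,
               tolerance = 1e-12)
  expect_equal(v[["granular"]], 4 / 3 * pi * (rGran^3 - rWhite^3) / 1e9,
               tolerance = 1e-12)
  # conservation: whole is exactly the sum of the three compartments
  expect_identical(v[["whole"]],
                   sum(v[c("molecular", "granular", "white_matter")]))
})

test_that("cell placement is uniform in the molecular shell and seeded", {
  p <- tinyPhantom(nCells = 400L, seed = 7L)
  expect_identical(trueCellCount(p), 400L)
  rho <- sqrt(rowSums(sweep(cellCenters(p), 2, p@spec@center)^2))
  expect_true(all(rho >= 250 & rho <= 300))
  # radial CDF of a uniform shell is (r^3 - a^3) / (R^3 - a^3)
  u <- (rho^3 - 250^3) / (300^3 - 250^3)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  p2 <- tinyPhantom(nCells = 400L, seed = 7L)
  expect_identical(cellCenters(p), cellCenters(p2))
  p3 <- tinyPhantom(nCells = 400L, seed = 8L)
  expect_false(identical(cellCenters(p), cellCenters(p3)))
})

test_that("empty phantom and invalid geometry are handled", {
  p <- generatePhantom(phantomSpec(nCells = 0))
  expect_identical(trueCellCount(p), 0L)
  expect_identical(nrow(cellCenters(p)), 0L)
  expect_error(phantomSpec(outerRadius = 100, granularThickness = 60,
                           molecularThickness = 50), "outerRadius")
  expect_error(phantomSpec(cellRadius = 200), "cellRadius")
})

test_that("noise-free control animals reproduce the base geometry exactly", {
  model <- defaultEffectModel(animalCv = 0, nPerGroup = 3L)
  base <- phantomSpec()
  cohort <- generateCohort(model, base)
  baseVols <- trueVolumes(generatePhantom(base))
  controls <- Filter(function(e) e$group == "control", cohort)
  expect_length(controls, 3L)
  for (e in controls)
    expect_equal(trueVolumes(e$phantom)[c("molecular", "granular",
                                          "white_matter")],
                 baseVols[c("molecular", "granular", "white_matter")],
                 tolerance = 1e-12)
})

test_that("all-unit multipliers with zero CV give identical geometry", {
  vm <- matrix(1, 4, 3, dimnames = list(c("control", "ACR", "vitC",
                                          "ACR_vitC"), tissueCompartments()))
  cm <- c(control = 1, ACR = 1, vitC = 1, ACR_vitC = 1)
  model <- effectModel(rownames(vm), vm, cm, animalCv = 0, nPerGroup = 6L)
  cohort <- generateCohort(model, phantomSpec())
  expect_length(cohort, 24L)
  vols <- t(vapply(cohort, function(e) trueVolumes(e$phantom), numeric(4)))
  expect_true(all(abs(sweep(vols, 2, vols[1, ])) < 1e-9))
})

test_that("cohort volumes hit target multipliers and counts are Poisson-mean", {
  model <- defaultEffectModel(animalCv = 0, nPerGroup = 1000L, seed = 42L)
  base <- phantomSpec(nCells = 500)
  cohort <- generateCohort(model, base)
  truth <- cohortTruth(cohort)
  baseVols <- trueVolumes(generatePhantom(base))
  acr <- truth[truth$group == "ACR", ]
  # with zero CV the target volumes are hit exactly
  expect_equal(unique(round(acr$vMolecular / baseVols[["molecular"]], 10)),
               0.70)
  expect_equal(unique(round(acr$vWhiteMatter / baseVols[["white_matter"]],
                            10)), 1.30)
  # Monte-Carlo: mean realized ACR cell count within 2% of 500 * 0.6 = 300
  expect_lt(abs(mean(acr$cells) - 300) / 300, 0.02)
})

test_that("default effects point the expected directions at cohort level", {
  model <- defaultEffectModel(animalCv = 0, nPerGroup = 2L)
  truth <- cohortTruth(generateCohort(model, phantomSpec()))
  m <- aggregate(cbind(vMolecular, vGranular, vWhiteMatter, vWhole, cells)
                 ~ group, truth, mean)
  rownames(m) <- m$group
  expect_lt(m["ACR", "vMolecular"], m["control", "vMolecular"])
  expect_lt(m["ACR", "vGranular"], m["control", "vGranular"])
  expect_lt(m["ACR", "vWhole"], m["control", "vWhole"])
  expect_gt(m["ACR", "vWhiteMatter"], m["control", "vWhiteMatter"])
  expect_gt(m["vitC", "vMolecular"], m["control", "vMolecular"])
  expect_gt(m["vitC", "vWhole"], m["control", "vWhole"])
  expect_lt(m["vitC", "vWhiteMatter"], m["control", "vWhiteMatter"])
  # combined group sits between toxicant and control on whole volume
  expect_true(m["ACR", "vWhole"] < m["ACR_vitC", "vWhole"] &&
                m["ACR_vitC", "vWhole"] < m["control", "vWhole"])
})

test_that("cohorts are reproducible from the model seed", {
  model <- defaultEffectModel(nPerGroup = 2L, seed = 9L)
  c1 <- generateCohort(model, phantomSpec())
  c2 <- generateCohort(model, phantomSpec())
  expect_identical(cohortTruth(c1), cohortTruth(c2))
  expect_identical(cellCenters(c1[[5]]$phantom), cellCenters(c2[[5]]$phantom))
})

test_that("invalid effect models are rejected", {
  vm <- defaultEffectModel()@volumeMultipliers
  cm <- defaultEffectModel()@cellCountMultipliers
  vm["control", 1] <- 2
  expect_error(effectModel(rownames(vm), vm, cm), "control")
  vm <- defaultEffectModel()@volumeMultipliers
  vm["ACR", 2] <- -1
  expect_error(effectModel(rownames(vm), vm, cm), "positive")
})
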