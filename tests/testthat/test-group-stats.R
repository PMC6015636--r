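test_that("two-group ANOVA matches the closed form and the pooled t-test", {
  tab <- makeOutcomeTable(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  an <- oneWayAnova(tab, "y")
  # hand check: SSB = 13.5, SSW = 4, MSW = 1 -> F = 13.5 on (1, 4) df
  expect_equal(an@F, 13.5, tolerance = 1e-12)
  expect_identical(c(an@dfBetween, an@dfWithin), c(1L, 4L))
  expect_equal(an@SS[["between"]], 13.5, tolerance = 1e-12)
  expect_equal(an@SS[["within"]], 4, tolerance = 1e-12)
  expect_equal(an@MSE, 1, tolerance = 1e-12)
  expect_equal(an@p, stats::pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # k = 2 reduction: F = t^2 and LSD p equals the pooled two-sample t-test
  tt <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(an@F, unname(tt$statistic)^2, tolerance = 1e-12)
  lsd <- lsdPosthoc(tab, an)
  expect_equal(lsd@pairs$p, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(lsd@pairs$t), abs(unname(tt$statistic)), tolerance = 1e-12)
})

test_that("ANOVA sum-of-squares decomposition holds on random data", {
  set.seed(202)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    vals <- lapply(seq_len(k), function(i) rnorm(sample(3:8, 1), mean = i))
    names(vals) <- paste0("g", seq_len(k))
    tab <- makeOutcomeTable(vals)
    an <- oneWayAnova(tab, "y")
    y <- tab$value
    sst <- sum((y - mean(y))^2)
    expect_lt(abs(an@SS[["total"]] - sst) / sst, 1e-10)
    expect_lt(abs(an@SS[["between"]] + an@SS[["within"]] - sst) / sst, 1e-10)
    expect_identical(an@dfBetween, k - 1L)
    expect_identical(an@dfWithin, length(y) - k)
  }
})

test_that("degenerate and malformed tables are rejected", {
  tab <- makeOutcomeTable(list(a = c(2, 2, 2), b = c(5, 5, 5)))
  expect_error(oneWayAnova(tab, "y"), "degenerate")
  expect_error(oneWayAnova(makeOutcomeTable(list(a = c(1, 2))), "y"),
               "two groups")
  expect_error(oneWayAnova(makeOutcomeTable(list(a = c(1, 2), b = 3)), "y"),
               "two animals|two groups")
  expect_error(oneWayAnova(tab, "nope"), "no rows")
})

test_that("LSD reports all pairs, symmetric significance and Bonferroni bound", {
  set.seed(7)
  vals <- list(control = rnorm(6, 10), ACR = rnorm(6, 7),
               vitC = rnorm(6, 12), ACR_vitC = rnorm(6, 9))
  tab <- makeOutcomeTable(vals)
  an <- oneWayAnova(tab, "y")
  lsd <- lsdPosthoc(tab, an)
  expect_identical(nrow(lsd@pairs), 6L)   # C(4, 2)
  expect_true(all(lsd@pairs$p <= lsd@pairs$pBonferroni + 1e-15))
  # se follows sqrt(MSE * (1/n_a + 1/n_b))
  expect_equal(lsd@pairs$se,
               rep(sqrt(an@MSE * (1 / 6 + 1 / 6)), 6), tolerance = 1e-12)
  # identical groups compare with p ~ 1
  tab2 <- makeOutcomeTable(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                c = c(9, 10, 11)))
  lsd2 <- lsdPosthoc(tab2, oneWayAnova(tab2, "y"))
  ab <- lsd2@pairs[lsd2@pairs$groupA == "a" & lsd2@pairs$groupB == "b", ]
  expect_equal(ab$meanDiff, 0)
  expect_equal(ab$p, 1)
})

test_that("significance pattern captures directions and matches references", {
  vals <- list(control = c(10, 10.1, 9.9), ACR = c(5, 5.1, 4.9),
               vitC = c(15, 15.1, 14.9))
  tab <- makeOutcomeTable(vals, outcome = "vMolecular")
  lsd <- lsdPosthoc(tab, oneWayAnova(tab, "vMolecular"))
  pat <- significancePattern(list(lsd))
  expect_identical(names(pat),
                   c("outcome", "groupA", "groupB", "direction", "significant"))
  ac <- pat[pat$groupA == "control" & pat$groupB == "ACR", ]
  expect_identical(ac$direction, 1)
  expect_true(ac$significant)
  ref <- data.frame(outcome = "vMolecular", groupA = "ACR",
                    groupB = "control", direction = -1)
  expect_true(patternMatches(pat, ref))   # matched in flipped pair order
  refWrong <- data.frame(outcome = "vMolecular", groupA = "vitC",
                         groupB = "control", direction = -1)
  expect_false(patternMatches(pat, refWrong))
})

test_that("LSD type-I error is nominal under the null (simulation)", {
  set.seed(404)
  n <- 2000L
  rej <- logical(n)
  for (i in seq_len(n)) {
    tab <- makeOutcomeTable(list(control = rnorm(6), ACR = rnorm(6),
                                 vitC = rnorm(6), ACR_vitC = rnorm(6)))
    lsd <- lsdPosthoc(tab, oneWayAnova(tab, "y"))
    rej[i] <- lsd@pairs$significant[lsd@pairs$groupA == "control" &
                                      lsd@pairs$groupB == "ACR"]
  }
  # binomial 95% band around 0.05 at 2000 replicates is about +/- 0.0096
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})
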