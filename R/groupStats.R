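# Group comparison: one-way ANOVA across the four groups per outcome,
# Fisher LSD pairwise post hoc tests at alpha = 0.05.

#' Reshape an estimates table into long outcome format
#'
#' @param estimates Data frame from [estimateCohort()] (or any data frame
#'   with animalId, group and outcome columns).
#' @param outcomes Outcome column names to keep; defaults to the five
#'   study outcomes (four compartment volumes and total cell number).
#' @return Long data frame: animalId, group, outcome, value.
#' @export
outcomeTable <- function(estimates,
                         outcomes = c("vMolecular", "vGranular",
                                      "vWhiteMatter", "vWhole",
                                      "totalNumber")) {
  missing <- setdiff(outcomes, names(estimates))
  if (length(missing))
    stop("outcomes absent from estimates: ", paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(outcomes, function(o)
    data.frame(animalId = estimates$animalId, group = estimates$group,
               outcome = o, value = estimates[[o]],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA for one outcome
#'
#' Standard between/within sum-of-squares decomposition, fitted with
#' \code{stats::lm}/\code{stats::anova}. Errors out when every group has
#' zero within-group variance (the F statistic is then undefined).
#'
#' @param table Long table from [outcomeTable()].
#' @param outcome Outcome name to analyze.
#' @return An [AnovaResult-class].
#' @export
oneWayAnova <- function(table, outcome) {
  sub <- table[table$outcome == outcome, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for outcome: ", outcome)
  if (any(!is.finite(sub$value))) stop("non-finite outcome values")
  if (anyDuplicated(paste(sub$animalId, sub$outcome)))
    stop("every animal must appear once per outcome")
  g <- factor(sub$group, levels = unique(sub$group))
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need at least two groups with at least two animals each")
  fit <- stats::lm(sub$value ~ g)
  # a perfect fit warns inside anova(); degeneracy is handled explicitly below
  an <- suppressWarnings(stats::anova(fit))
  ssb <- an[["Sum Sq"]][1]; ssw <- an[["Sum Sq"]][2]
  mse <- an[["Mean Sq"]][2]
  scale <- max(ssb + ssw, mean(sub$value)^2, .Machine$double.xmin)
  if (ssw <= 1e-12 * scale || !is.finite(an[["F value"]][1]))
    stop("degenerate-variance error: zero within-group variance everywhere")
  new("AnovaResult", outcome = outcome, F = an[["F value"]][1],
      dfBetween = as.integer(an[["Df"]][1]),
      dfWithin = as.integer(an[["Df"]][2]),
      p = an[["Pr(>F)"]][1], MSE = mse,
      SS = c(between = ssb, within = ssw, total = ssb + ssw),
      groupMeans = c(tapply(sub$value, g, mean)),
      groupN = c(table(g)))
}

#' Fisher LSD pairwise post hoc comparisons
#'
#' Unadjusted pairwise t tests of all group pairs on the ANOVA's pooled
#' within-group mean square with its error degrees of freedom (Fisher's
#' Least Significant Difference procedure): for groups a and b,
#' \code{t = (mean_a - mean_b) / sqrt(MSE * (1/n_a + 1/n_b))}, two-sided
#' p from the t distribution on the within-group df. No multiplicity
#' adjustment is applied - that is what LSD means; a Bonferroni-adjusted
#' column is included for information only.
#'
#' @param table Long table from [outcomeTable()] (same data the ANOVA was
#'   computed on).
#' @param anova The matching [AnovaResult-class].
#' @param alpha Significance level for the significance flag (default
#'   0.05).
#' @return An [LSDResult-class] with all \code{choose(k, 2)} pairs.
#' @export
lsdPosthoc <- function(table, anova, alpha = 0.05) {
  means <- anova@groupMeans
  ns <- anova@groupN
  grp <- names(means)
  cmb <- utils::combn(grp, 2L)
  meanDiff <- means[cmb[1, ]] - means[cmb[2, ]]
  se <- sqrt(anova@MSE * (1 / ns[cmb[1, ]] + 1 / ns[cmb[2, ]]))
  tval <- meanDiff / se
  p <- 2 * stats::pt(-abs(tval), df = anova@dfWithin)
  pairs <- data.frame(
    groupA = cmb[1, ], groupB = cmb[2, ],
    meanDiff = unname(meanDiff), se = unname(se), t = unname(tval),
    p = unname(p), pBonferroni = pmin(1, unname(p) * ncol(cmb)),
    significant = unname(p) <= alpha,
    stringsAsFactors = FALSE
  )
  new("LSDResult", outcome = anova@outcome, pairs = pairs,
      alpha = alpha, dfWithin = anova@dfWithin)
}

#' Direction-and-significance pattern across outcomes
#'
#' Condenses a list of LSD results into one row per outcome and group
#' pair: the sign of the mean difference (+1, -1, or 0) and whether the
#' comparison is significant at the LSD alpha. This is the summary that
#' can be compared against a study's reported direction table.
#'
#' @param lsdResults List of [LSDResult-class] objects (one per outcome).
#' @return Data frame: outcome, groupA, groupB, direction, significant.
#' @export
significancePattern <- function(lsdResults) {
  out <- do.call(rbind, lapply(lsdResults, function(r) {
    data.frame(outcome = r@outcome, groupA = r@pairs$groupA,
               groupB = r@pairs$groupB,
               direction = sign(r@pairs$meanDiff),
               significant = r@pairs$significant,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Reported direction pattern of the four-group toxicity design
#'
#' The treated-vs-control directions reported by the study design this
#' package emulates: the toxicant group lies below control on molecular,
#' granular and whole volume and on total cell number, and above control
#' on white matter; the antioxidant group is reversed on all five.
#'
#' @return Data frame: outcome, groupA, groupB, direction - with
#'   groupB = "control" throughout.
#' @export
referenceDirectionPattern <- function() {
  outs <- c("vMolecular", "vGranular", "vWhole", "totalNumber",
            "vWhiteMatter")
  rbind(
    data.frame(outcome = outs, groupA = "ACR", groupB = "control",
               direction = c(-1, -1, -1, -1, +1), stringsAsFactors = FALSE),
    data.frame(outcome = outs, groupA = "vitC", groupB = "control",
               direction = c(+1, +1, +1, +1, -1), stringsAsFactors = FALSE)
  )
}

#' Does an observed pattern reproduce a reference direction table?
#'
#' Each reference row must appear in the observed pattern (in either pair
#' order, with the sign flipped accordingly) with the stated direction;
#' with \code{requireSignificance = TRUE} (the default) the LSD comparison
#' must also be significant. The sign-only check asks whether the
#' estimated group means order as reported; the strict check additionally
#' demands that every comparison clears the LSD threshold in one cohort.
#'
#' @param pattern Output of [significancePattern()].
#' @param reference Data frame like [referenceDirectionPattern()].
#' @param requireSignificance Demand significance as well as direction.
#' @return Logical scalar.
#' @export
patternMatches <- function(pattern, reference = referenceDirectionPattern(),
                           requireSignificance = TRUE) {
  for (i in seq_len(nrow(reference))) {
    r <- reference[i, ]
    hit <- pattern[pattern$outcome == r$outcome &
                     pattern$groupA == r$groupA &
                     pattern$groupB == r$groupB, , drop = FALSE]
    dirWanted <- r$direction
    if (!nrow(hit)) {
      hit <- pattern[pattern$outcome == r$outcome &
                       pattern$groupA == r$groupB &
                       pattern$groupB == r$groupA, , drop = FALSE]
      dirWanted <- -r$direction
    }
    if (!nrow(hit)) return(FALSE)
    if (hit$direction[1] != dirWanted) return(FALSE)
    if (requireSignificance && !hit$significant[1]) return(FALSE)
  }
  TRUE
}

#' ANOVA + LSD for every outcome of an estimates table
#'
#' @param estimates Data frame from [estimateCohort()].
#' @param outcomes Outcome columns to analyze.
#' @param alpha Significance level.
#' @return List with elements \code{anova} (list of [AnovaResult-class]),
#'   \code{lsd} (list of [LSDResult-class]) and \code{pattern}
#'   (the [significancePattern()] data frame).
#' @export
compareGroups <- function(estimates,
                          outcomes = c("vMolecular", "vGranular",
                                       "vWhiteMatter", "vWhole",
                                       "totalNumber"),
                          alpha = 0.05) {
  tab <- outcomeTable(estimates, outcomes)
  anovas <- lapply(outcomes, function(o) oneWayAnova(tab, o))
  names(anovas) <- outcomes
  lsds <- lapply(anovas, function(a) lsdPosthoc(tab, a, alpha = alpha))
  list(anova = anovas, lsd = lsds, pattern = significancePattern(lsds))
}
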