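makeTracks <- function(entry, event = "S_entry") {
  data.frame(cell_id = seq_along(entry), phase_at_damage = "G1_early",
             event = event, entry_time = entry,
             censored = is.na(entry), divided = FALSE,
             micronucleated = FALSE)
}

test_that("cumulative entry counts censored cells in the denominator", {
  # all entered before the grid -> constant 1
  cv <- cumulativeEntry(makeTracks(c(1, 2, 3)), "S_entry",
                        grid = c(0, 5, 10), t0 = 8)
  expect_equal(curveFractions(cv), c(1, 1, 1))

  # nobody enters -> constant 0
  cv0 <- cumulativeEntry(makeTracks(rep(NA_real_, 4)), "S_entry",
                         grid = c(0, 12, 24), t0 = 8)
  expect_equal(curveFractions(cv0), c(0, 0, 0))

  # entry times {1,2,3,4} evaluated at 2.5 -> 0.5
  cv5 <- cumulativeEntry(makeTracks(1:4), "S_entry", grid = c(2.5), t0 = 0)
  expect_equal(curveFractions(cv5), 0.5)

  # censored cells stay in the denominator
  cvc <- cumulativeEntry(makeTracks(c(1, 2, NA, NA)), "S_entry",
                         grid = c(10), t0 = 0)
  expect_equal(curveFractions(cvc), 0.5)

  expect_error(cumulativeEntry(makeTracks(1:3), "M_entry", c(0, 1), 0),
               "empty cohort")
})

test_that("entry curves are monotone and bounded on simulated cohorts", {
  for (s in 1:5) {
    trk <- simulateTracks(TrackCohortSpec(nCells = 120), seed = 60 + s)
    for (ev in c("S_entry", "M_entry")) {
      cv <- cumulativeEntry(trk, ev, grid = seq(0, 24, 0.5), t0 = 8)
      f <- curveFractions(cv)
      expect_true(all(diff(f) >= 0))
      expect_true(all(f >= 0 & f <= 1))
    }
  }
})

test_that("quantile-crossing delays interpolate and flag non-crossings", {
  mkCurve <- function(time, frac) {
    new("EntryCurve", time = time, fraction = frac,
        nCells = 100L, event = "M_entry", t0 = 8)
  }
  a <- mkCurve(0:10, seq(0, 1, 0.1))
  expect_equal(delayAtQuantile(a, a)$delay, 0)

  # control crosses 0.5 at t = 4, treated at t = 9 -> 5 h
  control <- mkCurve(c(0, 4, 8), c(0, 0.5, 1))
  treated <- mkCurve(c(0, 8, 9, 10), c(0, 0.4, 0.5, 1))
  d <- delayAtQuantile(treated, control)
  expect_equal(d$delay, 5)
  expect_true(d$estimable)

  flat <- mkCurve(c(0, 24), c(0, 0.3))
  nd <- delayAtQuantile(flat, control)
  expect_false(nd$estimable)
  expect_true(is.na(nd$delay))
})

test_that("the delay estimator recovers a configured fixed G2 delay", {
  g2 <- c(G1_early = 0, G1_late = 0, G2 = 1)
  treated <- simulateTracks(TrackCohortSpec(nCells = 150, g2Delay = c(5, 5),
                                            phaseAtDamage = g2), seed = 71)
  control <- simulateTracks(TrackCohortSpec(nCells = 150, damaged = FALSE,
                                            phaseAtDamage = g2), seed = 72)
  grid <- seq(0, 24, 0.25)
  d <- delayAtQuantile(cumulativeEntry(treated, "M_entry", grid),
                       cumulativeEntry(control, "M_entry", grid))
  expect_true(d$estimable)
  expect_lt(abs(d$delay - 5), 1)
})

test_that("entry reduction is the relative control-treated difference", {
  mkCurve <- function(frac24) {
    new("EntryCurve", time = c(0, 24), fraction = c(0, frac24),
        nCells = 100L, event = "S_entry", t0 = 8)
  }
  expect_equal(reductionAt(mkCurve(0.8), mkCurve(0.8), 24), 0)
  expect_equal(reductionAt(mkCurve(0.8), mkCurve(1), 24), 20)
  zero <- new("EntryCurve", time = c(0, 24), fraction = c(0, 0),
              nCells = 10L, event = "S_entry", t0 = 8)
  expect_error(reductionAt(mkCurve(0.5), zero, 24), "undefined|0")
})

test_that("micronucleation folds and exact test behave at the edges", {
  same <- micronucleationFold(c(5, 100), c(5, 100))
  expect_equal(same$fold, 1)
  expect_equal(same$p_value, 1)

  five <- micronucleationFold(c(10, 100), c(2, 100))
  expect_equal(five$fold, 5)
  expect_equal(five$p_value,
               fisher.test(matrix(c(10, 90, 2, 98), 2))$p.value)

  zc <- micronucleationFold(c(8, 100), c(0, 100))
  expect_false(zc$estimable)
  expect_true(is.na(zc$fold))
  expect_true(is.finite(zc$fold_lower_bound) && zc$fold_lower_bound > 0)

  expect_error(micronucleationFold(c(1, 0), c(1, 10)), "positive")
})

test_that("group comparisons match the textbook formulas", {
  # identical constant groups: degenerate-variance rule, p = 1
  same <- groupCompare(list(a = c(2, 2, 2), b = c(2, 2, 2)),
                       method = "anova_bonferroni")
  expect_true(same$comparisons$degenerate)
  expect_equal(same$comparisons$p_adjusted, 1)

  # identical non-constant groups: t statistic 0
  id <- groupCompare(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(id$comparisons$statistic, 0)
  expect_equal(id$comparisons$p_raw, 1)

  # hand-computed Welch t for {2,4,6} vs {5,7,9}
  w <- groupCompare(list(a = c(2, 4, 6), b = c(5, 7, 9)))
  expect_equal(w$comparisons$statistic, -3 / sqrt(4 / 3 + 4 / 3))

  # ANOVA + Bonferroni: F p-value matches aov, adjustment is raw * pairs
  set.seed(17)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  ab <- groupCompare(g, method = "anova_bonferroni")
  ref <- summary(aov(v ~ f, data.frame(
    v = unlist(g), f = factor(rep(names(g), each = 8)))))[[1]]
  expect_equal(ab$anova_p, ref[["Pr(>F)"]][1])
  expect_equal(ab$comparisons$p_adjusted,
               pmin(1, ab$comparisons$p_raw * 3))
  expect_equal(nrow(ab$comparisons), 3L)

  expect_error(groupCompare(list(a = 1:3)), "two")
  expect_error(groupCompare(list(a = 1:3, b = 2)), "at least two")
})

test_that("end-to-end recovery of arrest fraction and micronucleation", {
  g1 <- c(G1_early = 0.5, G1_late = 0.5, G2 = 0)
  g2 <- c(G1_early = 0, G1_late = 0, G2 = 1)
  grid <- seq(0, 24, 0.25)

  treated <- simulateTracks(TrackCohortSpec(nCells = 1000,
                                            phaseAtDamage = g1), seed = 81)
  control <- simulateTracks(TrackCohortSpec(nCells = 1000, damaged = FALSE,
                                            phaseAtDamage = g1), seed = 82)
  red <- reductionAt(cumulativeEntry(treated, "S_entry", grid),
                     cumulativeEntry(control, "S_entry", grid), 24)
  expect_lt(abs(red - 20), 100 * 3 * sqrt(0.2 * 0.8 / 1000))

  intact <- simulateTracks(TrackCohortSpec(nCells = 3000,
                                           phaseAtDamage = g2), seed = 83)
  abro <- simulateTracks(TrackCohortSpec(nCells = 3000, phaseAtDamage = g2,
                                         checkpointIntact = FALSE),
                         seed = 84)
  mf <- micronucleationFold(
    c(sum(abro$micronucleated), sum(abro$divided)),
    c(sum(intact$micronucleated), sum(intact$divided)))
  expect_true(mf$estimable)
  # 3 SE of the log ratio around the configured 5-fold
  seLog <- sqrt(1 / sum(intact$micronucleated) - 1 / sum(intact$divided) +
                  1 / sum(abro$micronucleated) - 1 / sum(abro$divided))
  expect_lt(abs(log(mf$fold) - log(5)), 3 * seLog)
})
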