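test_that("field generation is a pure function of (spec, seed)", {
  spec <- FieldSpec(nNuclei = 3, width = 128, height = 128,
                    fociPerNucleus = c(2, 0, 1))
  a <- generateField(spec, seed = 11)
  b <- generateField(spec, seed = 11)
  expect_identical(pixels(a$dapi), pixels(b$dapi))
  expect_identical(pixels(a$marker), pixels(b$marker))
  expect_identical(labelMatrix(nucleusMasks(a$truth)),
                   labelMatrix(nucleusMasks(b$truth)))
  expect_identical(focusRecords(a$truth), focusRecords(b$truth))
  c <- generateField(spec, seed = 12)
  expect_false(identical(pixels(a$dapi), pixels(c$dapi)))
})

test_that("an empty field is pure background plus noise", {
  spec <- FieldSpec(nNuclei = 0, width = 64, height = 64,
                    backgroundLevel = 100, noiseSd = 10)
  fld <- generateField(spec, seed = 1)
  expect_equal(nLabels(nucleusMasks(fld$truth)), 0L)
  expect_equal(nrow(focusRecords(fld$truth)), 0L)
  # intensities scatter around the background with no bright structure
  expect_lt(abs(mean(pixels(fld$dapi)) - 100), 3)
  expect_lt(max(pixels(fld$marker)), 100 + 8 * sqrt(100 + 100))
})

test_that("ground truth bookkeeping matches the requested focus counts", {
  spec <- FieldSpec(nNuclei = 3, width = 220, height = 220,
                    nucleusRadiusRange = c(26, 30),
                    fociPerNucleus = c(3, 0, 5))
  fld <- generateField(spec, seed = 5)
  fr <- focusRecords(fld$truth)
  expect_equal(nrow(fr), 8L)
  expect_equal(as.integer(table(factor(fr$nucleus_id, levels = 1:3))),
               c(3L, 0L, 5L))
  # centroids lie inside their nucleus mask (also enforced by validity)
  lab <- labelMatrix(nucleusMasks(fld$truth))
  at <- lab[cbind(round(fr$y) + 1L, round(fr$x) + 1L)]
  expect_equal(at, fr$nucleus_id)
  # planted foci respect the minimum separation
  if (nrow(fr) > 1) {
    d <- as.matrix(dist(fr[, c("x", "y")]))
    expect_true(all(d[upper.tri(d)] >= spec@focusMinSep))
  }
})

test_that("impossible nucleus placement raises an error naming the spec", {
  spec <- FieldSpec(nNuclei = 30, width = 96, height = 96,
                    nucleusRadiusRange = c(20, 24))
  expect_error(generateField(spec, seed = 1), "n_nuclei|width")
})

test_that("break-event simulation honours guide, kinetics and lag", {
  g0 <- simulateBreakEvents(GuideTarget(nSites = 0), CutKinetics(),
                            RepairModel(), nCells = 50, duration = 10,
                            step = 0.5, seed = 1)
  expect_equal(nrow(g0$events), 0L)
  expect_equal(nrow(g0$cells), 50L)

  p0 <- simulateBreakEvents(GuideTarget(nSites = 3),
                            CutKinetics(pMax = 0), RepairModel(),
                            nCells = 50, duration = 10, step = 0.5, seed = 1)
  expect_equal(nrow(p0$events), 0L)

  sim <- simulateBreakEvents(GuideTarget(nSites = 2), CutKinetics(),
                             RepairModel(), nCells = 400,
                             phaseMix = PhaseMix(1), duration = 24,
                             step = 0.25, seed = 7)
  ev <- sim$events
  expect_true(all(ev$cut_time > CutKinetics()@tLag))
  expect_true(all(ev$repair_time > ev$cut_time))
  # at most one cut per (cell, site, allele)
  expect_false(any(duplicated(ev[, c("cell", "site", "allele")])))
  expect_true(all(ev$allele <= 2))  # G1-only cohort

  expect_error(
    simulateBreakEvents(GuideTarget(1), CutKinetics(), RepairModel(),
                        nCells = 10, duration = 10, step = 0, seed = 1),
    "step")
})

test_that("mean total cuts matches the analytic expectation at saturation", {
  # 2 sites x 2 alleles x pMax 1, duration far past saturation -> 4 cuts
  sim <- simulateBreakEvents(GuideTarget(nSites = 2), CutKinetics(),
                             RepairModel(), nCells = 10000,
                             phaseMix = PhaseMix(1), duration = 150,
                             step = 0.5, seed = 21)
  perCell <- tabulate(sim$events$cell, nbins = 10000)
  se <- sd(perCell) / sqrt(10000)
  expect_lt(abs(mean(perCell) - 4), 3 * se + 1e-3)
})

test_that("track simulation reduces to the baseline without damage terms", {
  spec <- TrackCohortSpec(nCells = 2000, g2Delay = c(0, 0),
                          g1ArrestFraction = 0)
  trk <- simulateTracks(spec, seed = 3)
  entered <- trk$entry_time[!trk$censored]
  expect_true(all(entered >= 8 & entered <= 20))
  # uniform baseline over (8, 20)
  expect_gt(ks.test(entered, "punif", 8, 20)$p.value, 0.01)
})

test_that("full G1 arrest censors every G1 cell", {
  spec <- TrackCohortSpec(nCells = 300, g1ArrestFraction = 1,
                          phaseAtDamage = c(G1_early = 0.5, G1_late = 0.5,
                                            G2 = 0),
                          horizon = 24)
  trk <- simulateTracks(spec, seed = 4)
  expect_true(all(trk$censored))
  expect_true(all(is.na(trk$entry_time[trk$censored])))
})

test_that("a fixed G2 delay shifts mean entry by the configured amount", {
  g2only <- c(G1_early = 0, G1_late = 0, G2 = 1)
  damaged <- simulateTracks(TrackCohortSpec(nCells = 10000, g2Delay = c(5, 5),
                                            phaseAtDamage = g2only),
                            seed = 8)
  control <- simulateTracks(TrackCohortSpec(nCells = 10000, damaged = FALSE,
                                            phaseAtDamage = g2only),
                            seed = 9)
  shift <- mean(damaged$entry_time, na.rm = TRUE) -
    mean(control$entry_time, na.rm = TRUE)
  se <- sqrt(var(damaged$entry_time, na.rm = TRUE) / 10000 +
               var(control$entry_time, na.rm = TRUE) / 10000)
  expect_lt(abs(shift - 5), 3 * se)
})

test_that("micronucleation frequencies calibrate to the spec defaults", {
  g2only <- c(G1_early = 0, G1_late = 0, G2 = 1)
  intact <- simulateTracks(TrackCohortSpec(nCells = 8000,
                                           phaseAtDamage = g2only),
                           seed = 10)
  abro <- simulateTracks(TrackCohortSpec(nCells = 8000,
                                         phaseAtDamage = g2only,
                                         checkpointIntact = FALSE),
                         seed = 11)
  for (x in list(list(trk = intact, p = 0.02), list(trk = abro, p = 0.10))) {
    div <- x$trk$divided
    f <- mean(x$trk$micronucleated[div])
    se <- sqrt(x$p * (1 - x$p) / sum(div))
    expect_lt(abs(f - x$p), 3 * se)
  }
  expect_true(all(!intact$micronucleated | intact$divided))
})

test_that("indel spectra are exact multinomials over the class mixture", {
  one <- sampleIndelSpectrum(IndelMixSpec(classProbs = c(`+1` = 1),
                                          nReads = 500), seed = 1)
  expect_equal(unname(spectrumFrequencies(one)), 1)

  sp <- sampleIndelSpectrum(IndelMixSpec(nReads = 100000), seed = 2)
  f <- spectrumFrequencies(sp)
  expect_equal(sum(f), 1)
  expect_equal(nReads(sp), 100000)
  probs <- IndelMixSpec()@classProbs
  for (cls in names(probs)) {
    se <- sqrt(probs[cls] * (1 - probs[cls]) / 100000)
    expect_lt(abs(f[cls] - probs[cls]), 3 * se + 1e-6)
  }
  expect_error(IndelMixSpec(classProbs = numeric(), nReads = 10))
})
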