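#' Simulate per-cell break and repair events under cutting kinetics
#'
#' Discrete-time simulation of Cas9 cutting over a cohort of cells: each
#' allele of each target site is cut at most once, with the cut time drawn
#' on the simulation grid so that the probability of being cut by time `t`
#' equals [cutFraction()]`(t)`. Repair times are the cut time plus an
#' exponential lifetime from the repair model.
#'
#' @param guide A [GuideTarget-class]; G1 cells carry `allelesG1` copies per
#'   site, G2 cells `allelesG2`.
#' @param kinetics A [CutKinetics-class].
#' @param repair A [RepairModel-class].
#' @param nCells Cohort size.
#' @param phaseMix A [PhaseMix-class] giving the G1/G2 composition.
#' @param duration Simulated time span in hours (> 0).
#' @param step Simulation time step in hours (> 0); cut times land on
#'   multiples of `step`.
#' @param seed Integer seed.
#' @param breakType `"cas9"` or `"ir"`: which mean lifetime of the repair
#'   model applies.
#' @return A list with `events` (data.frame: `cell`, `phase`, `site`,
#'   `allele`, `cut_time`, `repair_time`; one row per realised cut) and
#'   `cells` (data.frame: `cell`, `phase`, `n_alleles` per site).
#' @examples
#' sim <- simulateBreakEvents(GuideTarget(nSites = 2), CutKinetics(),
#'                            RepairModel(), nCells = 10,
#'                            phaseMix = PhaseMix(1), duration = 24,
#'                            step = 0.1, seed = 1)
#' head(sim$events)
#' @export
simulateBreakEvents <- function(guide, kinetics, repair, nCells,
                                phaseMix = PhaseMix(), duration, step, seed,
                                breakType = c("cas9", "ir")) {
  stopifnot(is(guide, "GuideTarget"), is(kinetics, "CutKinetics"),
            is(repair, "RepairModel"), is(phaseMix, "PhaseMix"))
  breakType <- match.arg(breakType)
  .assertScalarNumber(duration, "duration", positive = TRUE)
  .assertScalarNumber(step, "step", positive = TRUE)
  if (nCells < 1L) stop("'nCells' must be >= 1")
  meanLife <- if (breakType == "cas9") repair@meanRetentionCas9 else
    repair@meanRetentionIR

  .withSeed(seed, {
    phases <- sample(c("G1", "G2"), nCells, replace = TRUE,
                     prob = c(phaseMix@fractionG1, phaseMix@fractionG2))
    alleles <- ifelse(phases == "G1", guide@allelesG1, guide@allelesG2)
    cells <- data.frame(cell = seq_len(nCells), phase = phases,
                        n_alleles = alleles)
    empty <- data.frame(cell = integer(), phase = character(),
                        site = integer(), allele = integer(),
                        cut_time = numeric(), repair_time = numeric())
    if (guide@nSites == 0L || kinetics@pMax == 0)
      return(list(events = empty, cells = cells))

    grid <- seq(step, duration, by = step)
    if (grid[length(grid)] < duration - 1e-9) grid <- c(grid, duration)
    Fgrid <- cutFraction(grid, kinetics)

    perCell <- alleles * guide@nSites
    cell <- rep.int(seq_len(nCells), perCell)
    site <- unlist(lapply(alleles,
                          function(a) rep(seq_len(guide@nSites), each = a)),
                   use.names = FALSE)
    allele <- unlist(lapply(alleles,
                            function(a) rep.int(seq_len(a), guide@nSites)),
                     use.names = FALSE)
    u <- runif(length(cell))
    cut <- u <= Fgrid[length(Fgrid)]
    if (!any(cut)) return(list(events = empty, cells = cells))
    idx <- pmin(findInterval(u[cut], Fgrid) + 1L, length(Fgrid))
    cutTime <- grid[idx]
    events <- data.frame(cell = cell[cut],
                         phase = phases[cell[cut]],
                         site = site[cut], allele = allele[cut],
                         cut_time = cutTime,
                         repair_time = cutTime +
                           rexp(sum(cut), rate = 1 / meanLife))
    list(events = events, cells = cells)
  })
}

#' Simulate FUCCI-style single-cell cell cycle tracks
#'
#' Draws one track per cell: phase at damage, the time of its next cell
#' cycle transition (S entry for G1 cells, M entry for G2 cells, hours
#' post-transfection), censoring at the horizon, and for dividing cells a
#' micronucleation outcome. Damaged G2 cells incur an additive checkpoint
#' delay (scaled down by `abrogatedDelayFactor` when the checkpoint is
#' abrogated); a fraction of damaged early-G1 cells arrest and never enter
#' S within the horizon.
#'
#' @param spec A [TrackCohortSpec-class].
#' @param seed Integer seed.
#' @return data.frame with columns `cell_id`, `phase_at_damage`
#'   (`"undamaged"` for control cohorts), `event` (`"S_entry"` or
#'   `"M_entry"`), `entry_time` (hours, `NA` when censored), `censored`,
#'   `divided`, `micronucleated`.
#' @examples
#' trk <- simulateTracks(TrackCohortSpec(nCells = 20), seed = 1)
#' table(trk$event, trk$censored)
#' @export
simulateTracks <- function(spec, seed) {
  stopifnot(is(spec, "TrackCohortSpec"))
  validObject(spec)
  .withSeed(seed, {
    n <- spec@nCells
    pm <- spec@phaseAtDamage[c("G1_early", "G1_late", "G2")]
    phase <- sample(names(pm), n, replace = TRUE, prob = pm)
    baseline <- runif(n, spec@baselineEntry[1], spec@baselineEntry[2])
    delayRaw <- runif(n, spec@g2Delay[1], spec@g2Delay[2])
    arrestU <- runif(n)
    micU <- runif(n)

    delay <- ifelse(phase == "G2" & spec@damaged,
                    delayRaw * if (spec@checkpointIntact) 1 else
                      spec@abrogatedDelayFactor,
                    0)
    entry <- baseline + delay

    # arrest preferentially hits early-G1 cells (before the restriction
    # point); only when the requested overall fraction exceeds the early
    # pool does it spill over to late-G1 cells
    pG1 <- pm[["G1_early"]] + pm[["G1_late"]]
    arrested <- rep(FALSE, n)
    if (spec@damaged && spec@g1ArrestFraction > 0 && pG1 > 0) {
      pEarly <- pm[["G1_early"]] / pG1
      pLate <- pm[["G1_late"]] / pG1
      pArrestEarly <- if (pEarly > 0)
        min(1, spec@g1ArrestFraction / pEarly) else 0
      remaining <- spec@g1ArrestFraction - pEarly * pArrestEarly
      pArrestLate <- if (pLate > 0) min(1, max(0, remaining) / pLate) else 0
      arrested <- (phase == "G1_early" & arrestU < pArrestEarly) |
        (phase == "G1_late" & arrestU < pArrestLate)
    }

    censored <- arrested | entry > spec@horizon
    divided <- phase == "G2" & !censored
    pMic <- if (spec@checkpointIntact) spec@micronucleationProbIntact else
      spec@micronucleationProbAbrogated
    micronucleated <- divided & micU < pMic

    data.frame(
      cell_id = seq_len(n),
      phase_at_damage = if (spec@damaged) phase else "undamaged",
      event = ifelse(phase == "G2", "M_entry", "S_entry"),
      entry_time = ifelse(censored, NA_real_, entry),
      censored = censored,
      divided = divided,
      micronucleated = micronucleated
    )
  })
}

#' Sample an indel spectrum from a class mixture
#'
#' Multinomial draw of `nReads` reads over the signed indel-size classes of
#' the mixture.
#'
#' @param mix An [IndelMixSpec-class].
#' @param seed Integer seed.
#' @return An [IndelSpectrum-class]; its frequencies sum to 1 exactly.
#' @examples
#' spectrumFrequencies(sampleIndelSpectrum(IndelMixSpec(), seed = 1))
#' @export
sampleIndelSpectrum <- function(mix, seed) {
  stopifnot(is(mix, "IndelMixSpec"))
  validObject(mix)
  .withSeed(seed, {
    counts <- as.vector(rmultinom(1, mix@nReads, mix@classProbs))
    names(counts) <- names(mix@classProbs)
    IndelSpectrum(counts)
  })
}

#' Simulate a time-lapse of focus detections
#'
#' Generates per-frame focus detection tables for a cohort of static,
#' well-separated foci whose lifetimes are exponential with the given
#' mean. Every focus appears at time 0 and remains detectable in frame `k`
#' (at time `k * frameInterval`) while its lifetime exceeds the frame time,
#' so a planted lifetime maps to a track length of `ceiling(lifetime /
#' frameInterval)` frames. Centroids jitter by a small Gaussian
#' displacement between frames.
#'
#' @param nFoci Number of foci.
#' @param lifetimeMean Mean focus lifetime in hours.
#' @param frameInterval Hours between frames (default 0.5).
#' @param duration Movie length in hours.
#' @param minSep Minimum focus separation in pixels.
#' @param jitterSd Per-frame centroid jitter SD in pixels.
#' @param seed Integer seed.
#' @return A list with `frames` (list of data.frames `x`, `y`, `area`,
#'   `intensity`, one per frame, frame 0 first), `lifetimes` (hours) and
#'   `frameInterval`.
#' @seealso [linkFoci()], [trackMetrics()]
#' @export
simulateFocusTimelapse <- function(nFoci, lifetimeMean, frameInterval = 0.5,
                                   duration = 24, minSep = 20,
                                   jitterSd = 0.5, seed = 1) {
  stopifnot(nFoci >= 1, lifetimeMean > 0, frameInterval > 0, duration > 0)
  .withSeed(seed, {
    side <- ceiling(sqrt(nFoci))
    spacing <- 2 * minSep
    gx <- ((seq_len(nFoci) - 1L) %% side) * spacing + minSep
    gy <- ((seq_len(nFoci) - 1L) %/% side) * spacing + minSep
    x0 <- gx + runif(nFoci, -minSep / 4, minSep / 4)
    y0 <- gy + runif(nFoci, -minSep / 4, minSep / 4)
    lifetimes <- rexp(nFoci, rate = 1 / lifetimeMean)
    frameTimes <- seq(0, duration - 1e-9, by = frameInterval)
    frames <- lapply(frameTimes, function(t) {
      alive <- lifetimes > t
      k <- sum(alive)
      data.frame(
        x = x0[alive] + rnorm(k, 0, jitterSd),
        y = y0[alive] + rnorm(k, 0, jitterSd),
        area = rep(20, k),
        intensity = rep(100, k)
      )
    })
    list(frames = frames, lifetimes = lifetimes,
         frameInterval = frameInterval)
  })
}
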