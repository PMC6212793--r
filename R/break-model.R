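#' Time-dependent per-allele cut fraction
#'
#' Lagged saturating-exponential model of Cas9 cutting: the cut fraction is
#' 0 up to the onset lag and then rises as
#' `pMax * (1 - exp(-(t - tLag) / tau))`. Non-decreasing in `t` and bounded
#' by `pMax`. With the default parameters (`tLag = 2` h, `tau = 6/log(2)`
#' h, `pMax = 1`) the fraction reaches exactly 1/2 at `t = 8` h.
#'
#' @param t Time(s) in hours (>= 0); vectorised.
#' @param k A [CutKinetics-class].
#' @return Numeric vector of cut probabilities.
#' @examples
#' cutFraction(c(2, 8, 100), CutKinetics())
#' @export
cutFraction <- function(t, k = CutKinetics()) {
  stopifnot(is(k, "CutKinetics"))
  if (any(t < 0)) stop("'t' must be non-negative")
  ifelse(t <= k@tLag, 0, k@pMax * (1 - exp(-(t - k@tLag) / k@tau)))
}

#' Expected number of foci per nucleus
#'
#' Closed-form expectation of the per-nucleus focus count at time `t`:
#' `background + nSites * (fG1 * allelesG1 + fG2 * allelesG2) *
#' cutFraction(t, k)`. Background foci are assumed additive with the
#' induced breaks. The result is exactly linear in both `nSites` and
#' `background`.
#'
#' @param guide A [GuideTarget-class].
#' @param mix A [PhaseMix-class].
#' @param t Time in hours.
#' @param k A [CutKinetics-class].
#' @param background Mean background focus count per nucleus (default 3,
#'   the level observed in undamaged control nuclei).
#' @return Expected foci per nucleus (numeric).
#' @examples
#' expectedFoci(GuideTarget(nSites = 1), PhaseMix(1), t = 8)
#' @export
expectedFoci <- function(guide, mix = PhaseMix(), t, k = CutKinetics(),
                         background = 3) {
  stopifnot(is(guide, "GuideTarget"), is(mix, "PhaseMix"))
  allelesPerSite <- mix@fractionG1 * guide@allelesG1 +
    mix@fractionG2 * guide@allelesG2
  background + guide@nSites * allelesPerSite * cutFraction(t, k)
}

#' Monte-Carlo mean of simultaneously present foci
#'
#' Simulates break events with [simulateBreakEvents()] and counts, per
#' cell, the breaks that are cut but not yet repaired at time `t`. With
#' repair disabled (`repairDisabled = TRUE`, infinite retention) the mean
#' agrees with [expectedFoci()] at zero background.
#'
#' @param guide A [GuideTarget-class].
#' @param mix A [PhaseMix-class].
#' @param k A [CutKinetics-class].
#' @param repair A [RepairModel-class].
#' @param t Evaluation time in hours.
#' @param nCells Number of simulated cells (>= 1).
#' @param seed Integer seed.
#' @param breakType `"cas9"` or `"ir"` lifetime mean.
#' @param repairDisabled When `TRUE`, breaks persist forever.
#' @param step Simulation step in hours.
#' @return A list with `mean` (foci per cell at `t`), `se` (Monte-Carlo
#'   standard error) and `n` (cells).
#' @export
mcConcurrentFoci <- function(guide, mix = PhaseMix(), k = CutKinetics(),
                             repair = RepairModel(), t, nCells, seed,
                             breakType = c("cas9", "ir"),
                             repairDisabled = FALSE, step = 0.05) {
  breakType <- match.arg(breakType)
  if (nCells < 1L) stop("'nCells' must be >= 1")
  .assertScalarNumber(t, "t")
  if (t < 0) stop("'t' must be non-negative")
  if (t == 0)
    return(list(mean = 0, se = 0, n = as.integer(nCells)))
  sim <- simulateBreakEvents(guide, k, repair, nCells, mix,
                             duration = t, step = step, seed = seed,
                             breakType = breakType)
  ev <- sim$events
  present <- if (nrow(ev)) {
    if (repairDisabled) ev$cut_time <= t else
      ev$cut_time <= t & ev$repair_time > t
  } else logical(0)
  perCell <- tabulate(ev$cell[present], nbins = nCells)
  list(mean = mean(perCell), se = sd(perCell) / sqrt(nCells),
       n = as.integer(nCells))
}

#' Classify an indel spectrum into repair pathways
#'
#' Partitions the spectrum's class frequencies into the small indels
#' characteristic of non-homologous end joining (+1, +2, -1, -2, -3, -4),
#' resection-dependent deletions (size <= -5), and a remainder. The
#' remainder includes unedited reads (size 0), which are also reported
#' separately; `*_repair_fraction` values exclude unedited reads from the
#' denominator, i.e. they are fractions of repair products.
#'
#' @param spectrum An [IndelSpectrum-class], or a named numeric vector of
#'   counts/frequencies keyed by signed indel size.
#' @return A list with `nhej_fraction`, `resection_fraction`,
#'   `other_fraction` (these three sum to 1 exactly), `unedited_fraction`,
#'   and `nhej_repair_fraction` / `resection_repair_fraction` (fractions of
#'   edited reads only).
#' @examples
#' classifyIndels(c(`+1` = 0.2, `-1` = 0.1, `-5` = 0.4, `-8` = 0.3))
#' @export
classifyIndels <- function(spectrum) {
  counts <- if (is(spectrum, "IndelSpectrum")) spectrum@counts else spectrum
  if (!length(counts) || is.null(names(counts)))
    stop("'spectrum' must be non-empty and named by signed indel size")
  if (sum(counts) <= 0)
    stop("all-zero spectrum: no reads to classify")
  sizes <- suppressWarnings(as.numeric(names(counts)))
  if (any(is.na(sizes)))
    stop("spectrum names must parse as signed indel sizes")
  freq <- counts / sum(counts)
  nhejClasses <- c(1, 2, -1, -2, -3, -4)
  nhej <- sum(freq[sizes %in% nhejClasses])
  resection <- sum(freq[sizes <= -5])
  other <- 1 - nhej - resection
  unedited <- sum(freq[sizes == 0])
  edited <- 1 - unedited
  list(
    nhej_fraction = nhej,
    resection_fraction = resection,
    other_fraction = other,
    unedited_fraction = unedited,
    nhej_repair_fraction = if (edited > 0) nhej / edited else NA_real_,
    resection_repair_fraction = if (edited > 0) resection / edited else
      NA_real_
  )
}
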