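#' @import methods
NULL

# ---------------------------------------------------------------------------
# Image containers
# ---------------------------------------------------------------------------

#' Two-dimensional intensity image
#'
#' A single-channel 2D grayscale image in arbitrary intensity units (a.u.).
#' Raw microscopy channels are non-negative; filtered images (e.g. the output
#' of [dogFilter()]) may carry signed values.
#'
#' @slot pixels Numeric matrix of intensities; rows are image rows (y),
#'   columns are image columns (x).
#' @slot pixelSize Optional physical pixel size in micrometres per pixel
#'   (`NA` when unknown). Purely descriptive; all geometry in this package is
#'   in pixel units.
#'
#' @seealso [ImageField()], [pixels()]
#' @export
setClass("ImageField",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@pixels))
      return("'pixels' must be a numeric matrix")
    if (any(!is.finite(object@pixels)))
      return("'pixels' must be finite")
    if (length(object@pixelSize) != 1L)
      return("'pixelSize' must be a single value")
    TRUE
  }
)

#' Construct an ImageField
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixelSize Optional physical scale (micrometres per pixel).
#' @return An [ImageField-class] object.
#' @examples
#' img <- ImageField(matrix(0, 8, 8))
#' dim(pixels(img))
#' @export
ImageField <- function(pixels, pixelSize = NA_real_) {
  storage.mode(pixels) <- "double"
  new("ImageField", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Integer nucleus label map
#'
#' Per-pixel nucleus labels: 0 is background, nuclei are labelled with the
#' contiguous integers `1..nLabels`. Each label's pixel set is 4-connected.
#'
#' @slot labels Integer matrix of labels, same shape as the source image.
#'
#' @seealso [LabelMap()], [segmentNuclei()], [nLabels()]
#' @export
setClass("LabelMap",
  representation(labels = "matrix"),
  validity = function(object) {
    l <- object@labels
    if (!is.integer(l))
      return("'labels' must be an integer matrix")
    if (any(l < 0L))
      return("labels must be non-negative")
    n <- max(l, 0L)
    present <- sort(unique(l[l > 0L]))
    if (n > 0L && !identical(present, seq_len(n)))
      return("labels must form the contiguous set 1..nLabels")
    TRUE
  }
)

#' Construct a LabelMap
#'
#' @param labels Integer matrix (0 = background, labels contiguous from 1).
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels)
}

# ---------------------------------------------------------------------------
# Synthetic-data specifications
# ---------------------------------------------------------------------------

#' Specification of a synthetic two-channel image field
#'
#' Describes one simulated field of view: ellipsoidal nuclei on a dark
#' background (DAPI channel) and bright damage-marker foci inside nuclei
#' (marker channel), both with Poisson--Gaussian noise.
#'
#' Focus counts per nucleus come either from `fociPerNucleus` (recycled over
#' nuclei) or, when `fociLambda` is not `NA`, from a Poisson draw per nucleus.
#'
#' @slot width,height Field size in pixels.
#' @slot nNuclei Number of nuclei to place.
#' @slot nucleusRadiusRange Min/max mean nucleus radius (pixels).
#' @slot overlapFraction Fraction of nuclei placed as touching pairs
#'   (centre distance 1.2--1.6 times the mean radius) to exercise watershed
#'   separation.
#' @slot nucleusIntensity DAPI plateau intensity above background (a.u.).
#' @slot backgroundLevel Mean background intensity of both channels (a.u.).
#' @slot markerNucleusLevel Diffuse nuclear marker signal above background
#'   (a.u.) on the marker channel.
#' @slot noiseSd Gaussian read-noise standard deviation (a.u.); Poisson shot
#'   noise is applied on top of the clean signal.
#' @slot fociPerNucleus Intended focus counts per nucleus (recycled).
#' @slot fociLambda When not `NA`, focus counts are Poisson with this mean.
#' @slot focusRadius Gaussian sigma of a rendered focus (pixels).
#' @slot focusAmplitude Peak focus intensity above the local nuclear
#'   signal (a.u.).
#' @slot focusMinSep Minimum centroid separation between planted foci
#'   (pixels); keeps adjacent-pixel focus regions from merging.
#' @slot eccentricityMax Maximum axis ratio of the elliptical nuclei.
#'
#' @seealso [FieldSpec()], [generateField()]
#' @export
setClass("FieldSpec",
  representation(
    width = "integer", height = "integer", nNuclei = "integer",
    nucleusRadiusRange = "numeric", overlapFraction = "numeric",
    nucleusIntensity = "numeric", backgroundLevel = "numeric",
    markerNucleusLevel = "numeric", noiseSd = "numeric",
    fociPerNucleus = "numeric", fociLambda = "numeric",
    focusRadius = "numeric", focusAmplitude = "numeric",
    focusMinSep = "numeric", eccentricityMax = "numeric"
  ),
  validity = function(object) {
    if (object@width <= 0L || object@height <= 0L)
      return("'width' and 'height' must be positive")
    if (object@nNuclei < 0L)
      return("'nNuclei' must be non-negative")
    rr <- object@nucleusRadiusRange
    if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2])
      return("'nucleusRadiusRange' must be an increasing positive pair")
    if (object@overlapFraction < 0 || object@overlapFraction > 1)
      return("'overlapFraction' must lie in [0, 1]")
    if (object@focusRadius <= 0)
      return("'focusRadius' must be positive")
    if (object@focusAmplitude < 0 || object@nucleusIntensity < 0 ||
        object@backgroundLevel < 0 || object@markerNucleusLevel < 0)
      return("intensities and amplitudes must be non-negative")
    if (object@noiseSd < 0)
      return("'noiseSd' must be non-negative")
    if (any(object@fociPerNucleus < 0))
      return("'fociPerNucleus' entries must be non-negative")
    if (!is.na(object@fociLambda) && object@fociLambda < 0)
      return("'fociLambda' must be non-negative")
    if (object@eccentricityMax < 1)
      return("'eccentricityMax' must be >= 1")
    TRUE
  }
)

#' Construct a FieldSpec
#'
#' Defaults emulate a 60x field of cultured epithelial nuclei: bright
#' elliptical DNA plateaus on a dark background, with compact diffraction-
#' limited foci well above the in-nucleus shot noise.
#'
#' @param width,height Field size in pixels.
#' @param nNuclei Number of nuclei.
#' @param nucleusRadiusRange Mean nucleus radius range (pixels).
#' @param overlapFraction Fraction of nuclei placed as touching pairs.
#' @param nucleusIntensity,backgroundLevel,markerNucleusLevel,noiseSd
#'   Intensity model (a.u.), see [FieldSpec-class].
#' @param fociPerNucleus Intended focus counts (recycled over nuclei).
#' @param fociLambda Optional Poisson mean for focus counts.
#' @param focusRadius Focus Gaussian sigma (pixels).
#' @param focusAmplitude Peak focus amplitude (a.u.).
#' @param focusMinSep Minimum focus centroid separation (pixels).
#' @param eccentricityMax Maximum nucleus axis ratio.
#' @return A [FieldSpec-class] object.
#' @examples
#' spec <- FieldSpec(nNuclei = 4, fociPerNucleus = c(2, 0, 5, 1))
#' spec
#' @export
FieldSpec <- function(width = 256, height = 256, nNuclei = 9,
                      nucleusRadiusRange = c(18, 24), overlapFraction = 0,
                      nucleusIntensity = 3000, backgroundLevel = 100,
                      markerNucleusLevel = 0, noiseSd = 20,
                      fociPerNucleus = 0, fociLambda = NA_real_,
                      focusRadius = 2.2, focusAmplitude = 1200,
                      focusMinSep = 16, eccentricityMax = 1.5) {
  new("FieldSpec",
    width = as.integer(width), height = as.integer(height),
    nNuclei = as.integer(nNuclei),
    nucleusRadiusRange = as.numeric(nucleusRadiusRange),
    overlapFraction = as.numeric(overlapFraction),
    nucleusIntensity = as.numeric(nucleusIntensity),
    backgroundLevel = as.numeric(backgroundLevel),
    markerNucleusLevel = as.numeric(markerNucleusLevel),
    noiseSd = as.numeric(noiseSd),
    fociPerNucleus = as.numeric(fociPerNucleus),
    fociLambda = as.numeric(fociLambda),
    focusRadius = as.numeric(focusRadius),
    focusAmplitude = as.numeric(focusAmplitude),
    focusMinSep = as.numeric(focusMinSep),
    eccentricityMax = as.numeric(eccentricityMax))
}

#' Ground truth of a generated field
#'
#' @slot nucleusMasks A [LabelMap-class] of the planted (noise-free) nucleus
#'   masks; pairwise disjoint by construction.
#' @slot focusRecords data.frame with one row per planted focus:
#'   `nucleus_id`, `x`, `y` (0-based pixel coordinates of the centroid),
#'   `radius` (Gaussian sigma, pixels) and `amplitude` (a.u.).
#' @seealso [generateField()]
#' @export
setClass("GroundTruth",
  representation(nucleusMasks = "LabelMap", focusRecords = "data.frame"),
  validity = function(object) {
    fr <- object@focusRecords
    need <- c("nucleus_id", "x", "y", "radius", "amplitude")
    if (!all(need %in% names(fr)))
      return(paste("focusRecords must have columns:",
                   paste(need, collapse = ", ")))
    if (nrow(fr)) {
      lab <- object@nucleusMasks@labels
      at <- lab[cbind(round(fr$y) + 1L, round(fr$x) + 1L)]
      if (any(at != fr$nucleus_id))
        return("every focus centroid must lie inside its nucleus mask")
    }
    TRUE
  }
)

#' Cohort specification for simulated cell cycle tracks
#'
#' Describes a FUCCI-style single-cell cohort followed after (mock) damage
#' induction. All times are hours post-transfection; damage is induced at
#' time 0 and entry events are typically quantified from `t0 = 8` h onwards
#' (see [cumulativeEntry()]).
#'
#' @slot nCells Cohort size.
#' @slot phaseAtDamage Named probabilities over `G1_early`, `G1_late`, `G2`.
#' @slot baselineEntry Uniform range (hours) of the undamaged time to the
#'   next transition (S entry for G1 cells, M entry for G2 cells).
#' @slot g2Delay Uniform range (hours) of the checkpoint delay added to
#'   damaged G2 cells.
#' @slot g1ArrestFraction Fraction of damaged G1 cells that arrest (never
#'   enter S within the horizon). Arrest preferentially hits early-G1
#'   cells (before the restriction point) and spills over to late-G1
#'   cells only when the requested fraction exceeds the early pool, so
#'   the overall G1 arrest fraction always matches.
#' @slot abrogatedDelayFactor Multiplier applied to the drawn G2 delay when
#'   the checkpoint is abrogated.
#' @slot horizon Observation horizon (hours); cells not entering by then are
#'   censored.
#' @slot checkpointIntact Whether the G2 checkpoint is functional.
#' @slot damaged Whether this cohort received breaks; undamaged control
#'   cohorts follow the baseline distribution exactly.
#' @slot micronucleationProbIntact,micronucleationProbAbrogated Probability
#'   that a dividing cell produces a micronucleated daughter, for intact vs
#'   abrogated checkpoints.
#'
#' @seealso [TrackCohortSpec()], [simulateTracks()]
#' @export
setClass("TrackCohortSpec",
  representation(
    nCells = "integer", phaseAtDamage = "numeric",
    baselineEntry = "numeric", g2Delay = "numeric",
    g1ArrestFraction = "numeric", abrogatedDelayFactor = "numeric",
    horizon = "numeric", checkpointIntact = "logical", damaged = "logical",
    micronucleationProbIntact = "numeric",
    micronucleationProbAbrogated = "numeric"
  ),
  validity = function(object) {
    pm <- object@phaseAtDamage
    if (!all(c("G1_early", "G1_late", "G2") %in% names(pm)))
      return("'phaseAtDamage' needs probabilities for G1_early, G1_late, G2")
    if (any(pm < 0) || abs(sum(pm) - 1) > 1e-8)
      return("'phaseAtDamage' must be non-negative and sum to 1")
    if (object@nCells < 1L) return("'nCells' must be >= 1")
    if (length(object@baselineEntry) != 2L ||
        any(object@baselineEntry < 0) ||
        object@baselineEntry[1] > object@baselineEntry[2])
      return("'baselineEntry' must be an increasing non-negative pair")
    if (length(object@g2Delay) != 2L || any(object@g2Delay < 0) ||
        object@g2Delay[1] > object@g2Delay[2])
      return("'g2Delay' must be an increasing non-negative pair")
    p <- c(object@g1ArrestFraction, object@micronucleationProbIntact,
           object@micronucleationProbAbrogated)
    if (any(p < 0 | p > 1))
      return("probabilities must lie in [0, 1]")
    if (object@abrogatedDelayFactor < 0 || object@abrogatedDelayFactor > 1)
      return("'abrogatedDelayFactor' must lie in [0, 1]")
    if (object@horizon <= 0) return("'horizon' must be positive")
    TRUE
  }
)

#' Construct a TrackCohortSpec
#'
#' Defaults encode the study conditions: an asynchronous population assumed
#' 80% G1 / 20% G2 at damage, a 4--6 h uniform G2 checkpoint delay, a 20%
#' G1 arrest fraction, baseline entry spread uniformly over 8--20 h
#' post-transfection, a 32 h horizon (24 h of observation from t0 = 8 h),
#' and micronucleation probabilities of 0.02 (intact checkpoint) versus
#' 0.10 (abrogated), embodying a 5-fold increase.
#'
#' @param nCells Cohort size.
#' @param phaseAtDamage Named phase probabilities.
#' @param baselineEntry Uniform range (h) of undamaged entry times.
#' @param g2Delay Uniform range (h) of the damage-induced G2 delay.
#' @param g1ArrestFraction Overall fraction of damaged G1 cells arresting.
#' @param abrogatedDelayFactor Delay multiplier under checkpoint abrogation.
#' @param horizon Observation horizon (h).
#' @param checkpointIntact,damaged Cohort condition flags.
#' @param micronucleationProbIntact,micronucleationProbAbrogated Per-division
#'   micronucleation probabilities.
#' @return A [TrackCohortSpec-class] object.
#' @export
TrackCohortSpec <- function(nCells = 150,
                            phaseAtDamage = c(G1_early = 0.4, G1_late = 0.4,
                                              G2 = 0.2),
                            baselineEntry = c(8, 20), g2Delay = c(4, 6),
                            g1ArrestFraction = 0.2,
                            abrogatedDelayFactor = 0.2, horizon = 32,
                            checkpointIntact = TRUE, damaged = TRUE,
                            micronucleationProbIntact = 0.02,
                            micronucleationProbAbrogated = 0.10) {
  new("TrackCohortSpec",
    nCells = as.integer(nCells), phaseAtDamage = phaseAtDamage,
    baselineEntry = as.numeric(baselineEntry), g2Delay = as.numeric(g2Delay),
    g1ArrestFraction = as.numeric(g1ArrestFraction),
    abrogatedDelayFactor = as.numeric(abrogatedDelayFactor),
    horizon = as.numeric(horizon),
    checkpointIntact = isTRUE(checkpointIntact), damaged = isTRUE(damaged),
    micronucleationProbIntact = as.numeric(micronucleationProbIntact),
    micronucleationProbAbrogated = as.numeric(micronucleationProbAbrogated))
}

#' Indel class mixture specification
#'
#' @slot classProbs Named probabilities per signed indel size (names such as
#'   `"+1"`, `"-5"`); must sum to 1.
#' @slot nReads Number of sequencing reads to draw.
#' @seealso [IndelMixSpec()], [sampleIndelSpectrum()]
#' @export
setClass("IndelMixSpec",
  representation(classProbs = "numeric", nReads = "integer"),
  validity = function(object) {
    p <- object@classProbs
    if (!length(p)) return("'classProbs' must be non-empty")
    if (is.null(names(p)) || any(!nzchar(names(p))))
      return("'classProbs' must be named by signed indel size")
    if (any(is.na(suppressWarnings(as.numeric(names(p))))))
      return("'classProbs' names must parse as signed integers")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      return("'classProbs' must be non-negative and sum to 1")
    if (object@nReads < 1L) return("'nReads' must be positive")
    TRUE
  }
)

#' Construct an IndelMixSpec
#'
#' The default mixture puts 30% of repair products into the small
#' NHEJ-characteristic classes (+1, +2, -1, -2, -3, -4) and 70% into the
#' resection-dependent deletions (-5, -8).
#'
#' @param classProbs Named class probabilities.
#' @param nReads Number of reads to sample.
#' @return An [IndelMixSpec-class] object.
#' @examples
#' IndelMixSpec()
#' @export
IndelMixSpec <- function(classProbs = c(`+1` = 0.10, `+2` = 0.02,
                                        `-1` = 0.08, `-2` = 0.04,
                                        `-3` = 0.03, `-4` = 0.03,
                                        `-5` = 0.40, `-8` = 0.30),
                         nReads = 10000) {
  new("IndelMixSpec", classProbs = classProbs, nReads = as.integer(nReads))
}

#' Observed indel spectrum
#'
#' @slot counts Named read counts per signed indel size.
#' @seealso [sampleIndelSpectrum()], [classifyIndels()]
#' @export
setClass("IndelSpectrum",
  representation(counts = "numeric"),
  validity = function(object) {
    cts <- object@counts
    if (!length(cts)) return("'counts' must be non-empty")
    if (is.null(names(cts)))
      return("'counts' must be named by signed indel size")
    if (any(cts < 0)) return("'counts' must be non-negative")
    if (sum(cts) <= 0) return("spectrum must contain at least one read")
    TRUE
  }
)

#' Construct an IndelSpectrum
#'
#' @param counts Named read counts per signed indel size (e.g. `c("+1" = 30,
#'   "-5" = 70)`).
#' @return An [IndelSpectrum-class] object.
#' @export
IndelSpectrum <- function(counts) {
  new("IndelSpectrum", counts = counts)
}

# ---------------------------------------------------------------------------
# Break-model parameter classes
# ---------------------------------------------------------------------------

#' Guide RNA target description
#'
#' Number of homologous genomic target sites of a guide and the allele copy
#' number per site by cell cycle phase: 2 copies in G1 and, after
#' replication, 4 in G2.
#'
#' @slot name Guide name (e.g. `"HS1"`).
#' @slot nSites Number of genomic target sites.
#' @slot allelesG1,allelesG2 Copies per site in G1 / G2 (G2 must equal twice
#'   G1).
#' @seealso [GuideTarget()], [expectedFoci()]
#' @export
setClass("GuideTarget",
  representation(name = "character", nSites = "integer",
                 allelesG1 = "integer", allelesG2 = "integer"),
  validity = function(object) {
    if (object@nSites < 0L) return("'nSites' must be non-negative")
    if (object@allelesG1 < 1L) return("'allelesG1' must be >= 1")
    if (object@allelesG2 != 2L * object@allelesG1)
      return("'allelesG2' must equal 2 * 'allelesG1'")
    TRUE
  }
)

#' Construct a GuideTarget
#'
#' @param name Guide name.
#' @param nSites Number of homologous target sites (the panel used for
#'   calibration spans 1, 4, 13, 15 and 17 sites).
#' @param allelesG1 Allele copies per site in G1 (diploid default 2).
#' @param allelesG2 Allele copies per site in G2 (default `2 * allelesG1`).
#' @return A [GuideTarget-class] object.
#' @examples
#' GuideTarget("HS1", nSites = 1)
#' @export
GuideTarget <- function(name = "guide", nSites = 1, allelesG1 = 2,
                        allelesG2 = 2 * allelesG1) {
  new("GuideTarget", name = as.character(name), nSites = as.integer(nSites),
      allelesG1 = as.integer(allelesG1), allelesG2 = as.integer(allelesG2))
}

#' Cas9 cutting kinetics
#'
#' Lagged saturating-exponential model of the per-allele cut probability
#' over time: zero up to the onset lag, then rising towards an asymptote
#' (see [cutFraction()]). Defaults are calibrated so that cutting becomes
#' detectable at 2 h and roughly half of all target alleles are cut around
#' 8 h post-transfection.
#'
#' @slot tLag Onset delay (hours).
#' @slot tau Saturation time constant (hours).
#' @slot pMax Asymptotic per-allele cut probability.
#' @seealso [CutKinetics()], [cutFraction()]
#' @export
setClass("CutKinetics",
  representation(tLag = "numeric", tau = "numeric", pMax = "numeric"),
  validity = function(object) {
    if (object@tLag < 0) return("'tLag' must be non-negative")
    if (object@tau <= 0) return("'tau' must be positive")
    if (object@pMax < 0 || object@pMax > 1)
      return("'pMax' must lie in [0, 1]")
    TRUE
  }
)

#' Construct a CutKinetics
#'
#' @param tLag Onset delay in hours (default 2).
#' @param tau Saturation time constant in hours; the default `6 / log(2)`
#'   makes the cut fraction reach exactly 1/2 at 8 h when `tLag = 2` and
#'   `pMax = 1`.
#' @param pMax Asymptotic per-allele cut probability (default 1).
#' @return A [CutKinetics-class] object.
#' @examples
#' cutFraction(8, CutKinetics())
#' @export
CutKinetics <- function(tLag = 2, tau = 6 / log(2), pMax = 1) {
  new("CutKinetics", tLag = as.numeric(tLag), tau = as.numeric(tau),
      pMax = as.numeric(pMax))
}

#' Focus repair-lifetime model
#'
#' Exponentially distributed focus lifetimes with separate means for
#' Cas9-induced and irradiation-induced breaks. The Cas9 mean is 2 h longer
#' than the IR mean by default, reflecting the slower repair of
#' nuclease-induced breaks.
#'
#' @slot meanRetentionCas9,meanRetentionIR Mean focus lifetimes (hours).
#' @slot family Lifetime distribution family (only `"exponential"`).
#' @seealso [RepairModel()], [simulateBreakEvents()]
#' @export
setClass("RepairModel",
  representation(meanRetentionCas9 = "numeric", meanRetentionIR = "numeric",
                 family = "character"),
  validity = function(object) {
    if (object@meanRetentionCas9 <= 0 || object@meanRetentionIR <= 0)
      return("mean retentions must be positive")
    if (!identical(object@family, "exponential"))
      return("only the 'exponential' lifetime family is supported")
    TRUE
  }
)

#' Construct a RepairModel
#'
#' @param meanRetentionIR Mean IR-break focus lifetime in hours (default 1).
#' @param meanRetentionCas9 Mean Cas9-break focus lifetime in hours
#'   (default `meanRetentionIR + 2`).
#' @param family Lifetime distribution family.
#' @return A [RepairModel-class] object.
#' @export
RepairModel <- function(meanRetentionIR = 1,
                        meanRetentionCas9 = meanRetentionIR + 2,
                        family = "exponential") {
  new("RepairModel", meanRetentionCas9 = as.numeric(meanRetentionCas9),
      meanRetentionIR = as.numeric(meanRetentionIR), family = family)
}

#' Cell cycle phase mixture
#'
#' @slot fractionG1,fractionG2 Non-negative fractions summing to 1.
#' @seealso [PhaseMix()], [expectedFoci()]
#' @export
setClass("PhaseMix",
  representation(fractionG1 = "numeric", fractionG2 = "numeric"),
  validity = function(object) {
    f <- c(object@fractionG1, object@fractionG2)
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
      return("phase fractions must be non-negative and sum to 1")
    TRUE
  }
)

#' Construct a PhaseMix
#'
#' The default 80% G1 / 20% G2 is a stated modelling assumption for an
#' asynchronous population at transfection.
#'
#' @param fractionG1,fractionG2 Phase fractions (must sum to 1).
#' @return A [PhaseMix-class] object.
#' @export
PhaseMix <- function(fractionG1 = 0.8, fractionG2 = 1 - fractionG1) {
  new("PhaseMix", fractionG1 = as.numeric(fractionG1),
      fractionG2 = as.numeric(fractionG2))
}

# ---------------------------------------------------------------------------
# Analysis parameter and result classes
# ---------------------------------------------------------------------------

#' Nucleus segmentation parameters
#'
#' @slot medianRadius Half-width of the square median filter window applied
#'   to the DAPI channel before thresholding (pixels).
#' @slot thresholdMethod `"otsu"` (default) or `"fixed"`.
#' @slot fixedThreshold Threshold intensity (a.u.) when `thresholdMethod`
#'   is `"fixed"`.
#' @slot minNucleusArea Components smaller than this (pixels) are discarded
#'   as debris.
#' @slot watershedSmoothingSigma Gaussian sigma (pixels) used to smooth the
#'   distance transform before watershed seeding.
#' @seealso [SegmentationParams()], [segmentNuclei()]
#' @export
setClass("SegmentationParams",
  representation(medianRadius = "integer", thresholdMethod = "character",
                 fixedThreshold = "numeric", minNucleusArea = "numeric",
                 watershedSmoothingSigma = "numeric"),
  validity = function(object) {
    if (object@medianRadius < 0L) return("'medianRadius' must be >= 0")
    if (!object@thresholdMethod %in% c("otsu", "fixed"))
      return("'thresholdMethod' must be 'otsu' or 'fixed'")
    if (object@thresholdMethod == "fixed" && is.na(object@fixedThreshold))
      return("'fixedThreshold' must be set when thresholdMethod = 'fixed'")
    if (object@minNucleusArea < 0) return("'minNucleusArea' must be >= 0")
    if (object@watershedSmoothingSigma < 0)
      return("'watershedSmoothingSigma' must be >= 0")
    TRUE
  }
)

#' Construct SegmentationParams
#'
#' @param medianRadius Median filter half-width (pixels).
#' @param thresholdMethod `"otsu"` or `"fixed"`.
#' @param fixedThreshold Threshold (a.u.) for the fixed method.
#' @param minNucleusArea Minimum nucleus area (pixels, default 200).
#' @param watershedSmoothingSigma Distance-map smoothing sigma (pixels).
#' @return A [SegmentationParams-class] object.
#' @export
SegmentationParams <- function(medianRadius = 2, thresholdMethod = "otsu",
                               fixedThreshold = NA_real_,
                               minNucleusArea = 200,
                               watershedSmoothingSigma = 1) {
  new("SegmentationParams", medianRadius = as.integer(medianRadius),
      thresholdMethod = thresholdMethod,
      fixedThreshold = as.numeric(fixedThreshold),
      minNucleusArea = as.numeric(minNucleusArea),
      watershedSmoothingSigma = as.numeric(watershedSmoothingSigma))
}

#' Focus detection parameters
#'
#' Encodes the focus-calling criteria applied to the background-subtracted
#' (DoG-filtered) marker channel: a candidate pixel must exceed the nuclear
#' background centre by `foldK` times the (median) background standard
#' deviation and exceed the absolute minimum `absMin`; candidate regions
#' must be strictly larger than `minFocusArea` pixels.
#'
#' @slot dogSigmaSmall,dogSigmaLarge Gaussian sigmas (pixels) of the
#'   Difference-of-Gaussians filter.
#' @slot foldK Multiplier of the background standard deviation (default 2).
#' @slot absMin Absolute minimum intensity (a.u.); `NA` means it is derived
#'   at detection time as the 95th percentile of the filtered signal outside
#'   all nuclei.
#' @slot minFocusArea Area threshold in pixels (strictly larger-than;
#'   default 16, so a 16-pixel region is rejected).
#' @slot connectivity 4 or 8; pixel adjacency used to group candidate
#'   pixels into foci.
#' @slot perNucleusSd When `TRUE`, the intensity criterion uses each
#'   nucleus's own background SD rather than the image-wide median SD.
#' @seealso [DetectionParams()], [detectFoci()]
#' @export
setClass("DetectionParams",
  representation(dogSigmaSmall = "numeric", dogSigmaLarge = "numeric",
                 foldK = "numeric", absMin = "numeric",
                 minFocusArea = "numeric", connectivity = "integer",
                 perNucleusSd = "logical"),
  validity = function(object) {
    if (object@dogSigmaSmall <= 0 ||
        object@dogSigmaSmall >= object@dogSigmaLarge)
      return("'dogSigmaSmall' must be positive and < 'dogSigmaLarge'")
    if (object@foldK <= 0) return("'foldK' must be positive")
    if (object@minFocusArea < 1) return("'minFocusArea' must be >= 1")
    if (!object@connectivity %in% c(4L, 8L))
      return("'connectivity' must be 4 or 8")
    TRUE
  }
)

#' Construct DetectionParams
#'
#' @param dogSigmaSmall,dogSigmaLarge DoG sigmas in pixels (defaults 2 and
#'   6, matched to the default simulated focus size).
#' @param foldK Background-SD multiplier (default 2).
#' @param absMin Absolute minimum (a.u.); `NA` derives it from the
#'   extranuclear background at detection time.
#' @param minFocusArea Strict area threshold in pixels (default 16).
#' @param connectivity 4 or 8 (default 8 for compact bright blobs).
#' @param perNucleusSd Use per-nucleus SD instead of the image-wide median.
#' @return A [DetectionParams-class] object.
#' @export
DetectionParams <- function(dogSigmaSmall = 2, dogSigmaLarge = 6, foldK = 2,
                            absMin = NA_real_, minFocusArea = 16,
                            connectivity = 8, perNucleusSd = FALSE) {
  new("DetectionParams", dogSigmaSmall = as.numeric(dogSigmaSmall),
      dogSigmaLarge = as.numeric(dogSigmaLarge), foldK = as.numeric(foldK),
      absMin = as.numeric(absMin), minFocusArea = as.numeric(minFocusArea),
      connectivity = as.integer(connectivity),
      perNucleusSd = isTRUE(perNucleusSd))
}

#' Per-field foci detection result
#'
#' @slot foci data.frame with one row per detected focus: `nucleus_id`,
#'   `x`, `y` (0-based centroid), `area` (pixels), `mean_intensity`,
#'   `max_intensity` (a.u., measured on the filtered image).
#' @slot counts Named integer vector of per-nucleus focus counts.
#' @slot stats data.frame of per-nucleus background statistics
#'   (`nucleus_id`, `bg_center`, `bg_sd`, `n_pixels`).
#' @slot globalSd Median of the per-nucleus background SDs (a.u.).
#' @slot focusLabels Integer matrix assigning each pixel of a kept focus the
#'   row index of that focus in `foci` (0 elsewhere).
#' @seealso [detectFoci()], [fociTable()], [fociCounts()]
#' @export
setClass("FociResult",
  representation(foci = "data.frame", counts = "integer",
                 stats = "data.frame", globalSd = "numeric",
                 focusLabels = "matrix"),
  validity = function(object) {
    if (length(object@counts) &&
        sum(object@counts) != nrow(object@foci))
      return("per-nucleus counts must equal focus list lengths")
    TRUE
  }
)

#' Cumulative cell cycle entry curve
#'
#' @slot time Time grid in hours relative to `t0`.
#' @slot fraction Cumulative fraction of the cohort having entered by each
#'   grid point; non-decreasing and bounded by 1.
#' @slot nCells Cohort size (censored cells stay in the denominator).
#' @slot event `"S_entry"` or `"M_entry"`.
#' @slot t0 Reference time (hours post-transfection) of grid point 0.
#' @seealso [cumulativeEntry()], [delayAtQuantile()], [reductionAt()]
#' @export
setClass("EntryCurve",
  representation(time = "numeric", fraction = "numeric", nCells = "integer",
                 event = "character", t0 = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@fraction))
      return("'time' and 'fraction' must have equal length")
    if (is.unsorted(object@time))
      return("'time' must be sorted")
    if (any(object@fraction < 0 | object@fraction > 1))
      return("'fraction' must lie in [0, 1]")
    if (is.unsorted(object@fraction))
      return("'fraction' must be non-decreasing")
    TRUE
  }
)
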