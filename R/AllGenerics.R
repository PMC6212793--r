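# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' Extract the pixel matrix of an image
#' @param x An [ImageField-class].
#' @return Numeric matrix of intensities.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Extract the label matrix of a LabelMap
#' @param x A [LabelMap-class].
#' @return Integer matrix of nucleus labels (0 = background).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Number of labels in a LabelMap
#' @param x A [LabelMap-class].
#' @return Integer count of nuclei.
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))

#' Table of detected foci
#' @param x A [FociResult-class].
#' @return data.frame with one row per focus.
#' @export
setGeneric("fociTable", function(x) standardGeneric("fociTable"))

#' Per-nucleus focus counts
#' @param x A [FociResult-class].
#' @return Named integer vector.
#' @export
setGeneric("fociCounts", function(x) standardGeneric("fociCounts"))

#' Per-nucleus background statistics
#' @param x A [FociResult-class].
#' @return data.frame with columns nucleus_id, bg_center, bg_sd, n_pixels.
#' @export
setGeneric("nucleusStats", function(x) standardGeneric("nucleusStats"))

#' Image-wide median background SD
#' @param x A [FociResult-class].
#' @return Numeric scalar (a.u.).
#' @export
setGeneric("globalSd", function(x) standardGeneric("globalSd"))

#' Planted nucleus masks of a ground truth
#' @param x A [GroundTruth-class].
#' @return A [LabelMap-class].
#' @export
setGeneric("nucleusMasks", function(x) standardGeneric("nucleusMasks"))

#' Planted focus records of a ground truth
#' @param x A [GroundTruth-class].
#' @return data.frame of planted foci.
#' @export
setGeneric("focusRecords", function(x) standardGeneric("focusRecords"))

#' Relative class frequencies of an indel spectrum
#' @param x An [IndelSpectrum-class].
#' @return Named numeric vector summing to 1.
#' @export
setGeneric("spectrumFrequencies",
           function(x) standardGeneric("spectrumFrequencies"))

#' Total reads in an indel spectrum
#' @param x An [IndelSpectrum-class].
#' @return Numeric scalar.
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' Time grid of an entry curve
#' @param x An [EntryCurve-class].
#' @return Numeric vector of hours relative to the curve's t0.
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))

#' Cumulative fractions of an entry curve
#' @param x An [EntryCurve-class].
#' @return Numeric vector in [0, 1].
#' @export
setGeneric("curveFractions", function(x) standardGeneric("curveFractions"))

#' Cohort size behind an entry curve
#' @param x An [EntryCurve-class].
#' @return Integer.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
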