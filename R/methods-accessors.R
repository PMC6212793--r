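#' @rdname pixels
#' @export
setMethod("pixels", "ImageField", function(x) x@pixels)

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "LabelMap", function(x) x@labels)

#' @rdname nLabels
#' @export
setMethod("nLabels", "LabelMap", function(x) max(x@labels, 0L))

#' @rdname fociTable
#' @export
setMethod("fociTable", "FociResult", function(x) x@foci)

#' @rdname fociCounts
#' @export
setMethod("fociCounts", "FociResult", function(x) x@counts)

#' @rdname nucleusStats
#' @export
setMethod("nucleusStats", "FociResult", function(x) x@stats)

#' @rdname globalSd
#' @export
setMethod("globalSd", "FociResult", function(x) x@globalSd)

#' @rdname nucleusMasks
#' @export
setMethod("nucleusMasks", "GroundTruth", function(x) x@nucleusMasks)

#' @rdname focusRecords
#' @export
setMethod("focusRecords", "GroundTruth", function(x) x@focusRecords)

#' @rdname spectrumFrequencies
#' @export
setMethod("spectrumFrequencies", "IndelSpectrum",
          function(x) x@counts / sum(x@counts))

#' @rdname nReads
#' @export
setMethod("nReads", "IndelSpectrum", function(x) sum(x@counts))

#' @rdname curveTimes
#' @export
setMethod("curveTimes", "EntryCurve", function(x) x@time)

#' @rdname curveFractions
#' @export
setMethod("curveFractions", "EntryCurve", function(x) x@fraction)

#' @rdname nCells
#' @export
setMethod("nCells", "EntryCurve", function(x) x@nCells)

setMethod("show", "ImageField", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageField: %d x %d px, range [%.4g, %.4g]",
              d[1], d[2], min(object@pixels), max(object@pixels)))
  if (!is.na(object@pixelSize))
    cat(sprintf(", %.3g um/px", object@pixelSize))
  cat("\n")
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMap: %d x %d px, %d nuclei\n", d[1], d[2],
              nLabels(object)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d nuclei, %d planted foci\n",
              nLabels(object@nucleusMasks), nrow(object@focusRecords)))
})

setMethod("show", "FociResult", function(object) {
  cat(sprintf(
    "FociResult: %d foci in %d nuclei (median background SD %.3g a.u.)\n",
    nrow(object@foci), length(object@counts), object@globalSd))
})

setMethod("show", "IndelSpectrum", function(object) {
  f <- spectrumFrequencies(object)
  cat(sprintf("IndelSpectrum: %g reads over %d classes\n",
              sum(object@counts), length(f)))
  print(round(f, 4))
})

setMethod("show", "EntryCurve", function(object) {
  cat(sprintf(
    "EntryCurve (%s): %d cells, t0 = %g h, final fraction %.3f at %g h\n",
    object@event, object@nCells, object@t0,
    object@fraction[length(object@fraction)],
    object@time[length(object@time)]))
})

setMethod("show", "CutKinetics", function(object) {
  cat(sprintf("CutKinetics: tLag = %g h, tau = %.4g h, pMax = %g\n",
              object@tLag, object@tau, object@pMax))
})

setMethod("show", "GuideTarget", function(object) {
  cat(sprintf("GuideTarget '%s': %d sites x %d (G1) / %d (G2) alleles\n",
              object@name, object@nSites, object@allelesG1,
              object@allelesG2))
})

setMethod("show", "FieldSpec", function(object) {
  cat(sprintf(
    "FieldSpec: %d x %d px, %d nuclei (r %g-%g px), noise sd %g a.u.\n",
    object@width, object@height, object@nNuclei,
    object@nucleusRadiusRange[1], object@nucleusRadiusRange[2],
    object@noiseSd))
})
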