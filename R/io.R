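#' Read a 16-bit grayscale TIFF as an ImageField
#'
#' @param path Path to a single-channel grayscale TIFF.
#' @return An [ImageField-class] carrying the raw integer sample values.
#' @export
readImageField <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (!is.matrix(x))
    stop("format error reading ", path, ": expected a single-channel ",
         "grayscale 2D image, got ", length(dim(x)), " dimensions (",
         paste(dim(x), collapse = " x "), ")")
  ImageField(x)
}

#' Write an ImageField as a 16-bit grayscale TIFF
#'
#' Pixel values must be integers in `[0, 65535]`; written files round-trip
#' bit-exactly through [readImageField()].
#'
#' @param image An [ImageField-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeImageField <- function(image, path) {
  stopifnot(is(image, "ImageField"))
  px <- image@pixels
  if (any(px < 0 | px > 65535 | px != round(px)))
    stop("pixels must be integers in [0, 65535] for 16-bit TIFF output")
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a nucleus label map from a 16-bit TIFF
#'
#' @param path Path to a label TIFF written by [writeLabelMap()].
#' @return A [LabelMap-class] with labels preserved.
#' @export
readLabelMap <- function(path) {
  img <- readImageField(path)
  LabelMap(matrix(as.integer(img@pixels), nrow(img@pixels),
                  ncol(img@pixels)))
}

#' Write a nucleus label map as a 16-bit TIFF
#'
#' @param labels A [LabelMap-class] (at most 65535 nuclei).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(labels, path) {
  stopifnot(is(labels, "LabelMap"))
  writeImageField(ImageField(labels@labels * 1.0), path)
}

#' Read a per-focus table written by the pipeline
#'
#' Validates the documented schema (`nucleus_id`, `x`, `y`, `area`,
#' `mean_intensity`, `max_intensity`).
#'
#' @param path Path to a foci CSV.
#' @return data.frame with one row per focus.
#' @export
readFociTable <- function(path) {
  if (!file.exists(path)) stop("no such foci table: ", path)
  df <- utils::read.csv(path)
  need <- c("nucleus_id", "x", "y", "area", "mean_intensity",
            "max_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("foci table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

.specFromList <- function(constructor, overrides) {
  if (is.null(overrides)) overrides <- list()
  stopifnot(is.list(overrides))
  known <- names(formals(constructor))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  do.call(constructor, overrides)
}

#' Run the simulate / segment / detect / summarize pipeline
#'
#' Executes the full fixed-cell analysis on synthetic fields: for every
#' condition, fields are generated ([generateField()]), written as 16-bit
#' TIFFs with their ground truth, segmented ([segmentNuclei()]) and
#' analysed for foci ([countFoci()]); per-condition focus count summaries
#' ([countSummary()]) are collected into a JSON summary. Re-running with
#' the same configuration reproduces every stochastic output
#' bit-identically.
#'
#' The configuration is a YAML file or an equivalent list with elements
#' `seed` (integer), `out_dir` (output directory), `conditions` (a list
#' of `list(name=, n_fields=, field=)` where `field` holds [FieldSpec()]
#' overrides), and optional `segmentation` / `detection` parameter
#' overrides ([SegmentationParams()] / [DetectionParams()] arguments).
#'
#' Outputs per field: `<cond>_<i>_dapi.tif`, `<cond>_<i>_marker.tif`,
#' `<cond>_<i>_truth.csv` (`nucleus_id,x,y,radius,amplitude`),
#' `<cond>_<i>_truthlabels.tif`, `<cond>_<i>_labels.tif`,
#' `<cond>_<i>_nuclei.csv` (`nucleus_id,area_px,centroid_x,centroid_y`),
#' `<cond>_<i>_foci.csv` and `<cond>_<i>_counts.csv`; plus `summary.json`
#' and `run_log.yaml` (all effective parameters including the seed).
#'
#' @param config Path to a YAML configuration or an equivalent list.
#' @return The summary list (also written as JSON), invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must provide 'seed'")
  if (is.null(config$out_dir)) stop("config must provide 'out_dir'")
  if (is.null(config$conditions) || !length(config$conditions))
    stop("config must provide at least one condition")
  seed <- as.integer(config$seed)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  segParams <- .specFromList(SegmentationParams, config$segmentation)
  detParams <- .specFromList(DetectionParams, config$detection)

  nFieldsTotal <- sum(vapply(config$conditions,
                             function(cc) as.integer(cc$n_fields %||% 1L),
                             integer(1)))
  subSeeds <- .withSeed(seed,
                        sample.int(.Machine$integer.max, nFieldsTotal))

  stage <- function(name, input, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed on ", input, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  results <- list()
  condLabels <- character(0)
  fieldIdx <- 0L
  for (cc in config$conditions) {
    if (is.null(cc$name)) stop("every condition needs a 'name'")
    spec <- .specFromList(FieldSpec, cc$field)
    for (i in seq_len(as.integer(cc$n_fields %||% 1L))) {
      fieldIdx <- fieldIdx + 1L
      tag <- file.path(outDir, paste0(cc$name, "_", i))
      fld <- stage("simulate", paste0(cc$name, " field ", i),
                   generateField(spec, subSeeds[fieldIdx]))
      writeImageField(fld$dapi, paste0(tag, "_dapi.tif"))
      writeImageField(fld$marker, paste0(tag, "_marker.tif"))
      utils::write.csv(focusRecords(fld$truth),
                       paste0(tag, "_truth.csv"), row.names = FALSE)
      writeLabelMap(nucleusMasks(fld$truth),
                    paste0(tag, "_truthlabels.tif"))

      labels <- stage("segment", paste0(tag, "_dapi.tif"),
                      suppressWarnings(segmentNuclei(fld$dapi, segParams)))
      writeLabelMap(labels, paste0(tag, "_labels.tif"))
      lm <- labelMatrix(labels)
      if (nLabels(labels) > 0L) {
        nuc <- .regionStats(lm, pixels(fld$dapi))
        utils::write.csv(
          data.frame(nucleus_id = nuc$region, area_px = nuc$area,
                     centroid_x = nuc$x, centroid_y = nuc$y),
          paste0(tag, "_nuclei.csv"), row.names = FALSE)
        res <- stage("detect", paste0(tag, "_marker.tif"),
                     countFoci(fld$marker, labels, detParams))
        utils::write.csv(fociTable(res), paste0(tag, "_foci.csv"),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(nucleus_id = seq_along(fociCounts(res)),
                     n_foci = as.integer(fociCounts(res))),
          paste0(tag, "_counts.csv"), row.names = FALSE)
        results <- c(results, list(res))
        condLabels <- c(condLabels, cc$name)
      }
    }
  }

  summaryDf <- stage("summarize", "per-nucleus counts",
                     countSummary(results, condLabels))
  summary <- list(
    seed = seed,
    n_fields = nFieldsTotal,
    conditions = summaryDf,
    global_sd = vapply(results, globalSd, numeric(1))
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  effective <- list(
    seed = seed, out_dir = outDir,
    segmentation = lapply(attributes(segParams)[slotNames(segParams)],
                          identity),
    detection = lapply(attributes(detParams)[slotNames(detParams)],
                       identity),
    conditions = config$conditions
  )
  yaml::write_yaml(effective, file.path(outDir, "run_log.yaml"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
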