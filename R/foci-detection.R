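#' Difference-of-Gaussians background subtraction
#'
#' Band-pass filters the marker channel by subtracting a wide Gaussian
#' blur from a narrow one: `G(sigmaSmall) * image - G(sigmaLarge) * image`,
#' with reflective boundary handling. The output is signed.
#'
#' @param marker An [ImageField-class] or numeric matrix.
#' @param params A [DetectionParams-class] supplying the two sigmas.
#' @return An [ImageField-class] with signed values.
#' @examples
#' img <- ImageField(matrix(100, 32, 32))
#' range(pixels(dogFilter(img, DetectionParams())))  # all zero
#' @export
dogFilter <- function(marker, params = DetectionParams()) {
  m <- if (is(marker, "ImageField")) marker@pixels else marker
  stopifnot(is.matrix(m), is(params, "DetectionParams"))
  validObject(params)
  ImageField(.gaussBlur(m, params@dogSigmaSmall) -
               .gaussBlur(m, params@dogSigmaLarge))
}

#' Per-nucleus background statistics of the filtered marker channel
#'
#' For every nucleus, the background centre is the median of the filtered
#' values inside the nucleus and the background SD is the MAD-based robust
#' standard deviation (1.4826 x median absolute deviation). The image-wide
#' summary is the median of the per-nucleus SDs.
#'
#' @param filtered The DoG-filtered marker channel ([ImageField-class]).
#' @param labels A [LabelMap-class] of nuclei.
#' @return A list with `stats` (data.frame: `nucleus_id`, `bg_center`,
#'   `bg_sd`, `n_pixels`) and `global_sd` (numeric).
#' @export
backgroundStats <- function(filtered, labels) {
  stopifnot(is(filtered, "ImageField"), is(labels, "LabelMap"))
  lab <- labels@labels
  if (nLabels(labels) == 0L)
    stop("empty LabelMap: no nuclei to analyze")
  if (!identical(dim(lab), dim(filtered@pixels)))
    stop("'filtered' and 'labels' must have the same shape")
  idx <- lab > 0L
  v <- split(filtered@pixels[idx], lab[idx])
  stats <- data.frame(
    nucleus_id = as.integer(names(v)),
    bg_center = vapply(v, median, numeric(1)),
    bg_sd = vapply(v, mad, numeric(1)),  # constant 1.4826
    n_pixels = vapply(v, length, integer(1)),
    row.names = NULL
  )
  list(stats = stats, global_sd = median(stats$bg_sd))
}

#' Detect nuclear foci on the background-subtracted marker channel
#'
#' Applies the focus-calling criteria per nucleus: a candidate pixel must
#' (i) exceed the nucleus background centre by `foldK` times the background
#' SD (the image-wide median SD by default, or the nucleus's own SD when
#' `perNucleusSd`) *and* exceed the absolute minimum, and (ii) belong to a
#' connected candidate region strictly larger than `minFocusArea` pixels.
#' Kept regions are emitted as foci with centroid, area and intensity
#' summaries measured on the filtered image.
#'
#' When `params@absMin` is `NA` it is derived as the maximum of the
#' filtered signal outside all nuclei -- the extranuclear noise ceiling --
#' (0 when the field has no background pixels). The filtered background is
#' spatially correlated, so a percentile-based minimum would admit noise
#' clusters large enough to pass the area criterion.
#'
#' @param filtered The DoG-filtered marker channel ([ImageField-class]).
#' @param labels A [LabelMap-class] of nuclei.
#' @param stats Per-nucleus statistics as returned by [backgroundStats()]
#'   (its `stats` element); must cover every label.
#' @param global_sd Image-wide median background SD (a.u.).
#' @param params A [DetectionParams-class].
#' @return A [FociResult-class].
#' @seealso [countFoci()] for the convenience wrapper running the filter,
#'   statistics and detection in one call.
#' @export
detectFoci <- function(filtered, labels, stats, global_sd,
                       params = DetectionParams()) {
  stopifnot(is(filtered, "ImageField"), is(labels, "LabelMap"),
            is.data.frame(stats), is(params, "DetectionParams"))
  validObject(params)
  lab <- labels@labels
  img <- filtered@pixels
  n <- nLabels(labels)
  missing <- setdiff(seq_len(n), stats$nucleus_id)
  if (length(missing))
    stop("missing background statistics for label(s): ",
         paste(missing, collapse = ", "))

  absMin <- params@absMin
  if (is.na(absMin)) {
    # the extranuclear noise ceiling: the DoG-filtered background is
    # spatially correlated, so tail pixels cluster into regions that can
    # pass the area criterion; no candidate may be dimmer than anything
    # the cell-free background produces
    outside <- img[lab == 0L]
    absMin <- if (length(outside)) max(outside) else 0
  }

  focusLabels <- matrix(0L, nrow(img), ncol(img))
  fociList <- vector("list", n)
  counts <- integer(n)
  names(counts) <- as.character(seq_len(n))
  nFoci <- 0L
  for (j in seq_len(n)) {
    s <- stats[stats$nucleus_id == j, , drop = FALSE][1L, ]
    sd_j <- if (params@perNucleusSd) s$bg_sd else global_sd
    thr <- s$bg_center + params@foldK * sd_j
    cand <- lab == j & img > thr & img > absMin
    if (!any(cand)) next
    comp <- .labelComponents(cand, params@connectivity)
    reg <- .regionStats(comp, img)
    keep <- reg[reg$area > params@minFocusArea, , drop = FALSE]
    if (!nrow(keep)) next
    counts[j] <- nrow(keep)
    for (r in seq_len(nrow(keep))) {
      nFoci <- nFoci + 1L
      focusLabels[comp == keep$region[r]] <- nFoci
    }
    fociList[[j]] <- data.frame(nucleus_id = j, keep[, -1, drop = FALSE],
                                row.names = NULL)
  }
  fociList <- fociList[!vapply(fociList, is.null, logical(1))]
  foci <- if (length(fociList))
    do.call(rbind, c(fociList, list(make.row.names = FALSE))) else NULL
  if (is.null(foci))
    foci <- data.frame(nucleus_id = integer(), x = numeric(), y = numeric(),
                       area = numeric(), mean_intensity = numeric(),
                       max_intensity = numeric())
  new("FociResult", foci = foci, counts = counts,
      stats = stats[order(stats$nucleus_id), , drop = FALSE],
      globalSd = as.numeric(global_sd), focusLabels = focusLabels)
}

#' Filter, measure background and detect foci in one call
#'
#' Convenience wrapper chaining [dogFilter()], [backgroundStats()] and
#' [detectFoci()].
#'
#' @param marker The raw marker channel ([ImageField-class]).
#' @param labels A [LabelMap-class] of nuclei.
#' @param params A [DetectionParams-class].
#' @return A [FociResult-class].
#' @examples
#' fld <- generateField(FieldSpec(nNuclei = 2, fociPerNucleus = c(2, 1),
#'                                width = 128, height = 128), seed = 7)
#' res <- countFoci(fld$marker, nucleusMasks(fld$truth))
#' fociCounts(res)
#' @export
countFoci <- function(marker, labels, params = DetectionParams()) {
  filtered <- dogFilter(marker, params)
  bg <- backgroundStats(filtered, labels)
  detectFoci(filtered, labels, bg$stats, bg$global_sd, params)
}

#' Per-condition focus count summary
#'
#' Pools per-nucleus focus counts across the fields of each condition and
#' reports the mean, SD and a t-interval 95% confidence interval of the
#' per-nucleus counts. A condition with a single nucleus is flagged: its CI
#' is undefined (`NA`), not silently zero-width.
#'
#' @param results A list of [FociResult-class] objects (one per field) or
#'   of numeric per-nucleus count vectors.
#' @param conditionLabels Character vector, one condition label per element
#'   of `results`.
#' @return data.frame with one row per condition: `condition`, `n_nuclei`,
#'   `mean_count`, `sd_count`, `ci_lower`, `ci_upper`, `ci_defined`.
#' @export
countSummary <- function(results, conditionLabels) {
  if (length(results) != length(conditionLabels))
    stop("'results' and 'conditionLabels' must have the same length")
  if (!length(results))
    stop("no results to summarize")
  counts <- lapply(results, function(r) {
    if (is(r, "FociResult")) as.numeric(fociCounts(r)) else as.numeric(r)
  })
  conds <- unique(conditionLabels)
  out <- lapply(conds, function(cnd) {
    x <- unlist(counts[conditionLabels == cnd], use.names = FALSE)
    if (!length(x)) stop("condition '", cnd, "' contains no nuclei")
    n <- length(x)
    mu <- mean(x)
    s <- if (n > 1L) sd(x) else NA_real_
    if (n > 1L) {
      half <- qt(0.975, n - 1L) * s / sqrt(n)
      ci <- mu + c(-1, 1) * half
      defined <- TRUE
    } else {
      ci <- c(NA_real_, NA_real_)
      defined <- FALSE
    }
    data.frame(condition = cnd, n_nuclei = n, mean_count = mu,
               sd_count = s, ci_lower = ci[1], ci_upper = ci[2],
               ci_defined = defined)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
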