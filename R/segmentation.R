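#' Median-filter an image
#'
#' Each output pixel is the median of the input pixels inside the square
#' window of half-width `radius` centred on it; at the image edge the
#' window is clipped to the image. `radius = 0` returns the input
#' unchanged.
#'
#' @param image An [ImageField-class] or numeric matrix.
#' @param radius Window half-width in pixels (>= 0).
#' @return An [ImageField-class].
#' @examples
#' img <- ImageField(matrix(rpois(64, 100), 8, 8))
#' sm <- medianSmooth(img, 1)
#' @export
medianSmooth <- function(image, radius) {
  m <- if (is(image, "ImageField")) image@pixels else image
  stopifnot(is.matrix(m))
  radius <- as.integer(radius)
  if (radius < 0L) stop("'radius' must be >= 0")
  if (radius == 0L) return(ImageField(m))
  nr <- nrow(m)
  nc <- ncol(m)
  padded <- matrix(NA_real_, nr + 2L * radius, nc + 2L * radius)
  padded[radius + seq_len(nr), radius + seq_len(nc)] <- m
  k <- (2L * radius + 1L)^2
  stack <- matrix(NA_real_, nr * nc, k)
  j <- 0L
  for (dx in -radius:radius) {
    for (dy in -radius:radius) {
      j <- j + 1L
      stack[, j] <- as.vector(
        padded[radius + dy + seq_len(nr), radius + dx + seq_len(nc)])
    }
  }
  out <- matrix(apply(stack, 1L, median, na.rm = TRUE), nr, nc)
  ImageField(out)
}

#' Segment nuclei from the DAPI channel
#'
#' Thresholds the median-filtered DAPI signal (Otsu by default, or a fixed
#' threshold), then separates touching nuclei by a watershed on the
#' Gaussian-smoothed distance transform of the foreground. Components
#' smaller than `minNucleusArea` are discarded and the surviving nuclei are
#' relabelled contiguously; every label is a 4-connected pixel set.
#'
#' A blank field (no foreground, or nothing surviving the area filter)
#' yields an empty [LabelMap-class] with a warning rather than an error.
#'
#' @param dapi An [ImageField-class] (DAPI channel).
#' @param params A [SegmentationParams-class].
#' @return A [LabelMap-class] of the same shape as `dapi`.
#' @examples
#' fld <- generateField(FieldSpec(nNuclei = 2, width = 128, height = 128),
#'                      seed = 1)
#' nLabels(segmentNuclei(fld$dapi, SegmentationParams()))
#' @export
segmentNuclei <- function(dapi, params = SegmentationParams()) {
  stopifnot(is(dapi, "ImageField"), is(params, "SegmentationParams"))
  validObject(params)
  m <- pixels(medianSmooth(dapi, params@medianRadius))

  thr <- if (params@thresholdMethod == "fixed") {
    params@fixedThreshold
  } else {
    rng <- range(m)
    if (diff(rng) <= 0) {
      warning("blank image: no intensity contrast for Otsu thresholding; ",
              "returning an empty LabelMap")
      return(LabelMap(matrix(0L, nrow(m), ncol(m))))
    }
    scaled <- (m - rng[1]) / diff(rng)
    as.numeric(EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))) *
      diff(rng) + rng[1]
  }

  fg <- m > thr
  if (!any(fg)) {
    warning("no foreground above the threshold; returning an empty LabelMap")
    return(LabelMap(matrix(0L, nrow(m), ncol(m))))
  }

  fgNum <- matrix(as.numeric(fg), nrow(m), ncol(m))
  dm <- EBImage::distmap(fgNum)
  if (params@watershedSmoothingSigma > 0)
    dm <- .gaussBlur(as.matrix(dm), params@watershedSmoothingSigma) * fgNum
  ws <- EBImage::watershed(EBImage::Image(as.matrix(dm)), tolerance = 0.5,
                           ext = 1)
  ws <- matrix(as.integer(ws), nrow(m), ncol(m))
  ws[!fg] <- 0L

  # enforce 4-connectivity within each watershed region, apply the area
  # filter, and relabel contiguously
  out <- matrix(0L, nrow(m), ncol(m))
  nextLab <- 0L
  for (k in sort(unique(ws[ws > 0L]))) {
    sub <- .labelComponents(ws == k, connectivity = 4L)
    for (p in seq_len(max(sub, 0L))) {
      sel <- sub == p
      if (sum(sel) >= params@minNucleusArea) {
        nextLab <- nextLab + 1L
        out[sel] <- nextLab
      }
    }
  }
  if (nextLab == 0L) {
    warning("no nuclei larger than 'minNucleusArea'; ",
            "returning an empty LabelMap")
    return(LabelMap(out))
  }
  LabelMap(.relabel(out))
}
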