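#' Generate a synthetic two-channel image field with ground truth
#'
#' Renders a field of elliptical nuclei (DAPI channel) and planted
#' damage-marker foci (marker channel) according to a [FieldSpec-class],
#' applies Poisson shot noise plus Gaussian read noise, and returns the
#' exact planted geometry as ground truth. Identical `(spec, seed)` pairs
#' produce bit-identical output.
#'
#' Nuclei are axis-aligned ellipses with smooth (Gaussian-blurred) edges;
#' a fraction of them can be placed as touching pairs (centre distance
#' 1.2--1.6 times the mean radius) to exercise watershed separation. Foci
#' are isotropic 2D Gaussian bumps whose centroids lie inside their
#' nucleus mask and respect the spec's minimum separation.
#'
#' @param spec A [FieldSpec-class].
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return A list with elements `dapi` ([ImageField-class]), `marker`
#'   ([ImageField-class]) and `truth` ([GroundTruth-class]).
#' @examples
#' fld <- generateField(FieldSpec(nNuclei = 2, fociPerNucleus = 3,
#'                                width = 128, height = 128), seed = 1)
#' nrow(focusRecords(fld$truth))
#' @export
generateField <- function(spec, seed) {
  stopifnot(is(spec, "FieldSpec"))
  validObject(spec)
  .withSeed(seed, .generateFieldImpl(spec))
}

.generateFieldImpl <- function(spec) {
  h <- spec@height
  w <- spec@width
  n <- spec@nNuclei
  labm <- matrix(0L, h, w)
  records <- data.frame(nucleus_id = integer(), x = numeric(),
                        y = numeric(), radius = numeric(),
                        amplitude = numeric())
  blurredInd <- matrix(0, h, w)
  markerClean <- matrix(spec@backgroundLevel, h, w)

  if (n > 0L) {
    r <- runif(n, spec@nucleusRadiusRange[1], spec@nucleusRadiusRange[2])
    ratio <- runif(n, 1, spec@eccentricityMax)
    swap <- runif(n) < 0.5
    ax <- ifelse(swap, r / sqrt(ratio), r * sqrt(ratio))
    ay <- ifelse(swap, r * sqrt(ratio), r / sqrt(ratio))
    maxAxis <- pmax(ax, ay)
    nPair <- floor(spec@overlapFraction * n / 2)
    pairPartner <- integer(n)
    if (nPair > 0)
      pairPartner[seq_len(nPair) * 2L] <- seq_len(nPair) * 2L - 1L

    cx <- numeric(n)
    cy <- numeric(n)
    for (i in seq_len(n)) {
      m <- maxAxis[i] + 2
      if (m >= (w - 1) / 2 || m >= (h - 1) / 2)
        stop("nucleus of radius ", round(maxAxis[i], 1),
             " px cannot fit the field; increase 'width'/'height' or ",
             "reduce 'nucleusRadiusRange' in the FieldSpec")
      placed <- FALSE
      for (att in seq_len(500L)) {
        if (pairPartner[i] > 0L) {
          p <- pairPartner[i]
          d <- runif(1, 1.2, 1.6) * mean(c(r[i], r[p]))
          th <- runif(1, 0, 2 * pi)
          xi <- cx[p] + d * cos(th)
          yi <- cy[p] + d * sin(th)
          if (xi < m || xi > w - 1 - m || yi < m || yi > h - 1 - m) next
          others <- setdiff(seq_len(i - 1L), p)
        } else {
          xi <- runif(1, m, w - 1 - m)
          yi <- runif(1, m, h - 1 - m)
          others <- seq_len(i - 1L)
        }
        if (length(others)) {
          dd <- sqrt((cx[others] - xi)^2 + (cy[others] - yi)^2)
          if (any(dd < maxAxis[others] + maxAxis[i] + 4)) next
        }
        cx[i] <- xi
        cy[i] <- yi
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place nucleus ", i, " within the field bounds; ",
             "reduce 'n_nuclei' or 'overlap_fraction', or enlarge ",
             "'width'/'height' in the FieldSpec")
    }

    # disjoint pixel masks: nearest centre in normalised ellipse distance
    best <- matrix(Inf, h, w)
    innerPixels <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- max(1L, floor(cy[i] - ay[i])):min(h, ceiling(cy[i] + ay[i] + 2))
      cols <- max(1L, floor(cx[i] - ax[i])):min(w, ceiling(cx[i] + ax[i] + 2))
      dx <- ((cols - 1) - cx[i]) / ax[i]
      dy <- ((rows - 1) - cy[i]) / ay[i]
      d <- outer(dy^2, dx^2, "+")
      sel <- d <= 1 & d < best[rows, cols, drop = FALSE]
      if (any(sel)) {
        sub <- labm[rows, cols, drop = FALSE]
        sub[sel] <- i
        labm[rows, cols] <- sub
        bsub <- best[rows, cols, drop = FALSE]
        bsub[sel] <- d[sel]
        best[rows, cols] <- bsub
      }
      innerPixels[[i]] <- d <= 0.8
    }
    # inner pixels must also have survived the disjointness assignment
    for (i in seq_len(n)) {
      rows <- max(1L, floor(cy[i] - ay[i])):min(h, ceiling(cy[i] + ay[i] + 2))
      cols <- max(1L, floor(cx[i] - ax[i])):min(w, ceiling(cx[i] + ax[i] + 2))
      keep <- innerPixels[[i]] & labm[rows, cols, drop = FALSE] == i
      rc <- which(keep, arr.ind = TRUE)
      innerPixels[[i]] <- cbind(row = rows[rc[, 1]], col = cols[rc[, 2]])
    }

    # touching nuclei keep a thin dark seam at the contact (the nuclear
    # envelopes of adjacent nuclei), as in real DAPI images
    ind <- matrix(as.numeric(labm > 0L), h, w)
    seam <- matrix(FALSE, h, w)
    a <- labm[-h, ]
    b <- labm[-1, ]
    d <- a > 0L & b > 0L & a != b
    seam[-h, ][d] <- TRUE
    seam[-1, ][d] <- TRUE
    a <- labm[, -w]
    b <- labm[, -1]
    d <- a > 0L & b > 0L & a != b
    seam[, -w][d] <- TRUE
    seam[, -1][d] <- TRUE
    if (any(seam)) {  # one dilation step: the seam spans ~2 px per side
      grow <- seam
      grow[-h, ] <- grow[-h, ] | seam[-1, ]
      grow[-1, ] <- grow[-1, ] | seam[-h, ]
      grow[, -w] <- grow[, -w] | seam[, -1]
      grow[, -1] <- grow[, -1] | seam[, -w]
      seam <- grow & labm > 0L
    }
    ind[seam] <- 0
    blurredInd <- .gaussBlur(ind, 1.5)
    markerClean <- markerClean + spec@markerNucleusLevel * blurredInd

    counts <- if (!is.na(spec@fociLambda)) {
      rpois(n, spec@fociLambda)
    } else {
      rep_len(spec@fociPerNucleus, n)
    }
    counts <- as.integer(round(counts))

    fx <- numeric(0)
    fy <- numeric(0)
    fn <- integer(0)
    for (i in seq_len(n)) {
      px <- innerPixels[[i]]
      for (k in seq_len(counts[i])) {
        ok <- FALSE
        for (att in seq_len(4000L)) {
          j <- px[sample.int(nrow(px), 1L), ]
          xi <- (j["col"] - 1) + runif(1, -0.45, 0.45)
          yi <- (j["row"] - 1) + runif(1, -0.45, 0.45)
          if (length(fx) &&
              any((fx - xi)^2 + (fy - yi)^2 < spec@focusMinSep^2)) next
          ok <- TRUE
          break
        }
        if (!ok)
          stop("could not place focus ", k, " in nucleus ", i,
               " at the requested separation; reduce 'foci_per_nucleus' ",
               "or 'focus_min_sep', or enlarge the nuclei in the FieldSpec")
        fx <- c(fx, xi)
        fy <- c(fy, yi)
        fn <- c(fn, i)
      }
    }
    if (length(fx)) {
      br <- ceiling(5 * spec@focusRadius)
      for (k in seq_along(fx)) {
        rows <- max(1L, floor(fy[k] - br + 1)):min(h, ceiling(fy[k] + br + 1))
        cols <- max(1L, floor(fx[k] - br + 1)):min(w, ceiling(fx[k] + br + 1))
        d2 <- outer(((rows - 1) - fy[k])^2, ((cols - 1) - fx[k])^2, "+")
        markerClean[rows, cols] <- markerClean[rows, cols] +
          spec@focusAmplitude * exp(-d2 / (2 * spec@focusRadius^2))
      }
      records <- data.frame(nucleus_id = fn, x = fx, y = fy,
                            radius = spec@focusRadius,
                            amplitude = spec@focusAmplitude)
    }
  }

  dapiClean <- spec@backgroundLevel + spec@nucleusIntensity * blurredInd
  noisy <- function(clean) {
    v <- rpois(length(clean), pmax(clean, 0)) +
      rnorm(length(clean), 0, spec@noiseSd)
    matrix(pmin(65535, pmax(0, round(v))), nrow(clean), ncol(clean))
  }
  list(dapi = ImageField(noisy(dapiClean)),
       marker = ImageField(noisy(markerClean)),
       truth = new("GroundTruth", nucleusMasks = LabelMap(labm),
                   focusRecords = records))
}
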