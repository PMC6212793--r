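#' Link per-frame focus detections into tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames: among
#' all (track, detection) pairs within `maxDisplacement`, the closest pair
#' is linked first (ties broken by the lower detection index, then the
#' lower track index), and so on until no admissible pair remains.
#' Unmatched detections start new tracks; a track ends at the first frame
#' without a match -- there is no gap closing, so a focus that blinks off
#' for one frame terminates its track.
#'
#' @param perFrameDetections List of data.frames, one per frame in temporal
#'   order, each with columns `x`, `y` and optionally `area`, `intensity`.
#' @param maxDisplacement Maximum linking distance in pixels (> 0).
#' @param frameInterval Hours between frames (stored on the output).
#' @return data.frame with one row per (track, frame): `track_id`, `frame`
#'   (0-based), `x`, `y`, `area`, `intensity`. The frame interval is
#'   attached as attribute `frame_interval`.
#' @examples
#' det <- replicate(5, data.frame(x = 10, y = 10), simplify = FALSE)
#' tr <- linkFoci(det, maxDisplacement = 5, frameInterval = 0.5)
#' max(tr$track_id)
#' @export
linkFoci <- function(perFrameDetections, maxDisplacement,
                     frameInterval = 0.5) {
  .assertScalarNumber(maxDisplacement, "maxDisplacement", positive = TRUE)
  .assertScalarNumber(frameInterval, "frameInterval", positive = TRUE)
  stopifnot(is.list(perFrameDetections))
  getCol <- function(df, nm) if (nm %in% names(df)) df[[nm]] else
    rep(NA_real_, nrow(df))

  rows <- list()
  nTracks <- 0L
  active <- data.frame(track = integer(), x = numeric(), y = numeric())
  for (f in seq_along(perFrameDetections)) {
    det <- perFrameDetections[[f]]
    nd <- if (is.null(det)) 0L else nrow(det)
    assigned <- integer(nd)  # track id per detection, 0 = unmatched
    if (nd > 0L && nrow(active) > 0L) {
      dx <- outer(active$x, det$x, "-")
      dy <- outer(active$y, det$y, "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= maxDisplacement, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], cand[, 2], cand[, 1])
        cand <- cand[ord, , drop = FALSE]
        usedTrack <- logical(nrow(active))
        usedDet <- logical(nd)
        for (i in seq_len(nrow(cand))) {
          a <- cand[i, 1]
          d <- cand[i, 2]
          if (usedTrack[a] || usedDet[d]) next
          usedTrack[a] <- TRUE
          usedDet[d] <- TRUE
          assigned[d] <- active$track[a]
        }
      }
    }
    if (nd > 0L) {
      newIdx <- which(assigned == 0L)
      if (length(newIdx)) {
        assigned[newIdx] <- nTracks + seq_along(newIdx)
        nTracks <- nTracks + length(newIdx)
      }
      rows[[f]] <- data.frame(track_id = assigned, frame = f - 1L,
                              x = det$x, y = det$y,
                              area = getCol(det, "area"),
                              intensity = getCol(det, "intensity"))
      active <- data.frame(track = assigned, x = det$x, y = det$y)
    } else {
      active <- data.frame(track = integer(), x = numeric(), y = numeric())
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(track_id = integer(), frame = integer(), x = numeric(),
               y = numeric(), area = numeric(), intensity = numeric())
  }
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- frameInterval
  out
}

#' Per-track retention, size and intensity metrics
#'
#' Retention is the number of frames in the track times the frame
#' interval -- frames are counted inclusively, so a single-frame
#' appearance has retention equal to one interval, not zero, and no
#' interpolation is applied. Maximum area and intensity are the maxima
#' over the track's member frames.
#'
#' @param tracks A tracks data.frame as returned by [linkFoci()].
#' @param frameInterval Hours per frame; defaults to the attribute stored
#'   by [linkFoci()].
#' @return data.frame with one row per track: `track_id`, `n_frames`,
#'   `retention` (hours), `max_area`, `max_intensity`.
#' @export
trackMetrics <- function(tracks, frameInterval = NULL) {
  if (is.null(frameInterval))
    frameInterval <- attr(tracks, "frame_interval")
  if (is.null(frameInterval))
    stop("'frameInterval' must be supplied when the tracks carry none")
  if (!is.data.frame(tracks) || nrow(tracks) == 0L)
    stop("empty track set")
  ids <- sort(unique(tracks$track_id))
  sp <- split(tracks, tracks$track_id)
  data.frame(
    track_id = ids,
    n_frames = vapply(sp, nrow, integer(1))[as.character(ids)],
    retention = vapply(sp, nrow, integer(1))[as.character(ids)] *
      frameInterval,
    max_area = vapply(sp, function(d) suppressWarnings(max(d$area)),
                      numeric(1))[as.character(ids)],
    max_intensity = vapply(sp, function(d) suppressWarnings(max(d$intensity)),
                           numeric(1))[as.character(ids)],
    row.names = NULL
  )
}

#' Difference in mean focus retention between two cohorts
#'
#' Mean retention of cohort `a` minus that of cohort `b`, with a seeded
#' percentile bootstrap 95% confidence interval.
#'
#' @param retentionsA,retentionsB Numeric vectors of per-track retentions
#'   (hours), e.g. the `retention` column of [trackMetrics()] output.
#' @param nBoot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return A list with `difference` (hours), `ci` (length-2 numeric 95%
#'   interval) and `n` (the two cohort sizes).
#' @export
cohortRetentionDifference <- function(retentionsA, retentionsB,
                                      nBoot = 2000, seed = 1) {
  if (!length(retentionsA) || !length(retentionsB))
    stop("both cohorts must be non-empty")
  diff <- mean(retentionsA) - mean(retentionsB)
  ci <- .withSeed(seed, {
    boots <- vapply(seq_len(nBoot), function(i) {
      mean(sample(retentionsA, replace = TRUE)) -
        mean(sample(retentionsB, replace = TRUE))
    }, numeric(1))
    quantile(boots, c(0.025, 0.975), names = FALSE)
  })
  list(difference = diff, ci = ci,
       n = c(length(retentionsA), length(retentionsB)))
}
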