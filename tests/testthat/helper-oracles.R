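# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package implementation.

# per-pixel sort-and-middle median with the window clipped at the edges
bruteMedian <- function(m, r) {
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      rows <- max(1, i - r):min(nrow(m), i + r)
      cols <- max(1, j - r):min(ncol(m), j + r)
      v <- sort(as.vector(m[rows, cols]))
      k <- length(v)
      out[i, j] <- if (k %% 2 == 1) v[(k + 1) / 2] else
        (v[k / 2] + v[k / 2 + 1]) / 2
    }
  }
  out
}

# symmetric (half-sample) boundary reflection of an index into 1..n
reflectIdx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# explicit 2D Gaussian convolution (4-sigma truncation, kernel sum 1)
bruteGaussConv <- function(m, sigma) {
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  out <- m * 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + k2[di + r + 1, dj + r + 1] *
            m[reflectIdx(i + di, nrow(m)), reflectIdx(j + dj, ncol(m))]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# literal pixel-by-pixel application of the focus-calling criteria:
# (i) filtered value > nucleus background centre + foldK * SD and > absMin,
# (ii) connected candidate region strictly larger than minArea pixels.
# Returns a list of sorted pixel-index vectors, one per kept focus.
oracleFociPixels <- function(filteredMat, labMat, foldK = 2, absMin,
                             minArea = 16, connectivity = 8,
                             perNucleusSd = FALSE) {
  n <- max(labMat)
  # background statistics by literal sorting
  centres <- numeric(n)
  sds <- numeric(n)
  for (j in seq_len(n)) {
    v <- sort(filteredMat[labMat == j])
    k <- length(v)
    med <- if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
    dev <- sort(abs(filteredMat[labMat == j] - med))
    madv <- if (k %% 2 == 1) dev[(k + 1) / 2] else
      (dev[k / 2] + dev[k / 2 + 1]) / 2
    centres[j] <- med
    sds[j] <- 1.4826 * madv
  }
  gsd <- median(sds)

  nr <- nrow(labMat)
  nc <- ncol(labMat)
  cand <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      l <- labMat[i, j]
      if (l > 0) {
        sdUse <- if (perNucleusSd) sds[l] else gsd
        thr <- centres[l] + foldK * sdUse
        if (filteredMat[i, j] > thr && filteredMat[i, j] > absMin)
          cand[i, j] <- TRUE
      }
    }
  }

  offs <- if (connectivity == 8) {
    expand.grid(di = -1:1, dj = -1:1)[-5, ]
  } else {
    data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  visited <- matrix(FALSE, nr, nc)
  groups <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (cand[i, j] && !visited[i, j]) {
        queue <- list(c(i, j))
        visited[i, j] <- TRUE
        members <- integer(0)
        while (length(queue)) {
          p <- queue[[1]]
          queue <- queue[-1]
          members <- c(members, (p[2] - 1) * nr + p[1])
          for (o in seq_len(nrow(offs))) {
            ii <- p[1] + offs$di[o]
            jj <- p[2] + offs$dj[o]
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                cand[ii, jj] && !visited[ii, jj] &&
                labMat[ii, jj] == labMat[i, j]) {
              visited[ii, jj] <- TRUE
              queue <- c(queue, list(c(ii, jj)))
            }
          }
        }
        if (length(members) > minArea)
          groups <- c(groups, list(sort(members)))
      }
    }
  }
  groups
}

# canonical string form of a set of pixel sets, for exact comparison
pixelSetKey <- function(groups) {
  sort(vapply(groups, function(g) paste(g, collapse = ","), character(1)))
}

fociPixelSets <- function(res) {
  fl <- res@focusLabels
  idx <- which(fl > 0L)
  if (!length(idx)) return(list())
  unname(lapply(split(idx, fl[idx]), sort))
}

# noisy two-disk DAPI fixture at a given centre-distance factor; rendered
# like the generator (blurred indicator, Poisson + Gaussian noise) but
# independently of it. Returns the image and the true disjoint masks.
makeDiskPair <- function(distanceFactor, radius = 20, size = 128,
                         intensity = 3000, background = 100, noiseSd = 20,
                         seed = 1) {
  set.seed(seed)
  th <- runif(1, 0, 2 * pi)
  cx <- size / 2 - 1 + c(-1, 1) * distanceFactor * radius / 2 * cos(th)
  cy <- size / 2 - 1 + c(-1, 1) * distanceFactor * radius / 2 * sin(th)
  xs <- 0:(size - 1)
  d1 <- outer((xs - cy[1])^2, (xs - cx[1])^2, "+")
  d2 <- outer((xs - cy[2])^2, (xs - cx[2])^2, "+")
  truth <- matrix(0L, size, size)
  truth[d1 <= radius^2 & d1 <= d2] <- 1L
  truth[d2 <= radius^2 & d2 < d1] <- 2L
  ind <- matrix(as.numeric(truth > 0L), size, size)
  g <- function(m) {
    kr <- 6
    k <- exp(-((-kr):kr)^2 / (2 * 1.5^2))
    k <- k / sum(k)
    p <- m[c(pmin(kr:1, size), 1:size, size + 1 - pmin(1:kr, size)),
           c(pmin(kr:1, size), 1:size, size + 1 - pmin(1:kr, size))]
    o1 <- matrix(0, size, size + 2 * kr)
    for (i in seq_along(k)) o1 <- o1 + k[i] * p[(i - 1) + 1:size, ]
    o <- matrix(0, size, size)
    for (i in seq_along(k)) o <- o + k[i] * o1[, (i - 1) + 1:size]
    o
  }
  clean <- background + intensity * g(ind)
  px <- matrix(pmax(0, round(rpois(size^2, clean) +
                               rnorm(size^2, 0, noiseSd))), size, size)
  list(image = ImageField(px), truth = LabelMap(truth))
}
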