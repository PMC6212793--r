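# Internal numerical helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Normalised 1D Gaussian kernel truncated at 4 sigma.
.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Half-sample symmetric reflection of arbitrary (possibly far out of
# range) indices into 1..n; folds repeatedly when the kernel is wider
# than the image.
.reflectIndex <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

# Pad a matrix by symmetric reflection on all sides.
.padReflect <- function(m, r) {
  nr <- nrow(m)
  nc <- ncol(m)
  m[.reflectIndex((1 - r):(nr + r), nr),
    .reflectIndex((1 - r):(nc + r), nc), drop = FALSE]
}

# Separable Gaussian convolution with reflective boundary handling.
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- .gaussKernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m)
  nc <- ncol(m)
  p <- .padReflect(m, r)
  # convolve along rows (dimension 1)
  out1 <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k)) {
    out1 <- out1 + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  # convolve along columns (dimension 2)
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * out1[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

# 4- or 8-connected components of a logical matrix. Returns an integer
# matrix labelled 1..n in raster order of each component's first pixel.
# 4-connectivity comes from EBImage::bwlabel; 8-connectivity additionally
# unions labels that touch diagonally.
.labelComponents <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L) {
    n <- max(lab)
    if (n > 1L) {
      parent <- seq_len(n)
      findRoot <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      nr <- nrow(lab)
      nc <- ncol(lab)
      pairs <- NULL
      for (d in list(c(1L, 1L), c(1L, -1L))) {
        a <- lab[seq_len(nr - 1L), , drop = FALSE]
        if (d[2] == 1L) {
          a <- a[, seq_len(nc - 1L), drop = FALSE]
          b <- lab[-1L, -1L, drop = FALSE]
        } else {
          a <- a[, -1L, drop = FALSE]
          b <- lab[-1L, seq_len(nc - 1L), drop = FALSE]
        }
        sel <- a > 0L & b > 0L & a != b
        if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
      }
      if (!is.null(pairs)) {
        for (i in seq_len(nrow(pairs))) {
          ra <- findRoot(pairs[i, 1])
          rb <- findRoot(pairs[i, 2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        root <- vapply(seq_len(n), findRoot, integer(1))
        lab[lab > 0L] <- root[lab[lab > 0L]]
      }
    }
  }
  .relabel(lab)
}

# Relabel a non-negative integer matrix to the contiguous set 1..n, in
# raster order of each label's first pixel (deterministic).
.relabel <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  first <- idx[!duplicated(lab[idx])]
  old <- lab[first][order(first)]
  map <- integer(max(lab))
  map[old] <- seq_along(old)
  lab[idx] <- map[lab[idx]]
  storage.mode(lab) <- "integer"
  lab
}

# 0-based centroids and summary stats of labelled pixels.
.regionStats <- function(lab, values) {
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  v <- values[idx]
  data.frame(
    region = sort(unique(l)),
    x = as.numeric(tapply(cols - 1L, l, mean)),
    y = as.numeric(tapply(rows - 1L, l, mean)),
    area = as.numeric(tapply(l, l, length)),
    mean_intensity = as.numeric(tapply(v, l, mean)),
    max_intensity = as.numeric(tapply(v, l, max))
  )
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be positive", call. = FALSE)
  invisible(x)
}
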