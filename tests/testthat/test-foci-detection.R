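test_that("DoG filtering is a difference of two Gaussian convolutions", {
  # constants map to zero
  expect_equal(pixels(dogFilter(ImageField(matrix(250, 20, 20)))),
               matrix(0, 20, 20), tolerance = 1e-10)

  # linearity in the input
  set.seed(5)
  x <- matrix(rpois(256, 80), 16, 16)
  p <- DetectionParams()
  expect_equal(pixels(dogFilter(ImageField(3.5 * x), p)),
               3.5 * pixels(dogFilter(ImageField(x), p)),
               tolerance = 1e-10)

  # equals the explicit difference of brute-force 2D convolutions
  brute <- bruteGaussConv(x, 2) - bruteGaussConv(x, 6)
  expect_equal(pixels(dogFilter(ImageField(x), p)), brute,
               tolerance = 1e-8)
})

test_that("background statistics are per-nucleus medians and MADs", {
  # constant nucleus -> zero spread
  lab <- LabelMap(matrix(rep(c(0L, 1L), each = 32), 8, 8))
  img <- ImageField(matrix(4, 8, 8))
  bg <- backgroundStats(img, lab)
  expect_equal(bg$stats$bg_sd, 0)
  expect_equal(bg$stats$bg_center, 4)

  # the image-wide summary is the median of per-nucleus SDs
  set.seed(8)
  lab3 <- matrix(0L, 10, 30)
  lab3[, 1:8] <- 1L
  lab3[, 11:18] <- 2L
  lab3[, 21:28] <- 3L
  vals <- matrix(0, 10, 30)
  vals[lab3 == 1L] <- rnorm(80, sd = 1)
  vals[lab3 == 2L] <- rnorm(80, sd = 5)
  vals[lab3 == 3L] <- rnorm(80, sd = 100)
  bg3 <- backgroundStats(ImageField(vals), LabelMap(lab3))
  expect_equal(bg3$global_sd, sort(bg3$stats$bg_sd)[2])

  # five nuclei with random values match brute-force sorts
  set.seed(9)
  lab5 <- matrix(rep(1:5, each = 40), 10, 20)
  v5 <- matrix(rnorm(200, 10, 7), 10, 20)
  bg5 <- backgroundStats(ImageField(v5), LabelMap(lab5))
  for (j in 1:5) {
    x <- sort(v5[lab5 == j])
    med <- (x[20] + x[21]) / 2
    dev <- sort(abs(v5[lab5 == j] - med))
    expect_equal(bg5$stats$bg_center[j], med)
    expect_equal(bg5$stats$bg_sd[j], 1.4826 * (dev[20] + dev[21]) / 2)
  }

  expect_error(backgroundStats(img, LabelMap(matrix(0L, 8, 8))),
               "no nuclei")
})

test_that("the area criterion is strictly larger-than", {
  # constructed filtered image: one nucleus, one rectangular candidate
  # region of known area on a flat zero background
  lab <- matrix(0L, 40, 40)
  lab[5:35, 5:35] <- 1L
  base <- matrix(0, 40, 40)
  stats <- data.frame(nucleus_id = 1L, bg_center = 0, bg_sd = 1,
                      n_pixels = sum(lab))
  p <- DetectionParams(absMin = 5, minFocusArea = 16)

  m15 <- base
  m15[10:12, 10:14] <- 100  # 3 x 5 = 15 px
  r15 <- detectFoci(ImageField(m15), LabelMap(lab), stats, global_sd = 1,
                    params = p)
  expect_equal(unname(fociCounts(r15)), 0L)

  m16 <- base
  m16[10:13, 10:13] <- 100  # 16 px: a tie is rejected
  r16 <- detectFoci(ImageField(m16), LabelMap(lab), stats, global_sd = 1,
                    params = p)
  expect_equal(unname(fociCounts(r16)), 0L)

  m17 <- base
  m17[10:13, 10:13] <- 100
  m17[14, 10] <- 100  # 17 px
  r17 <- detectFoci(ImageField(m17), LabelMap(lab), stats, global_sd = 1,
                    params = p)
  expect_equal(unname(fociCounts(r17)), 1L)
  expect_equal(fociTable(r17)$area, 17)
})

test_that("missing per-nucleus statistics are reported by label", {
  lab <- matrix(0L, 10, 20)
  lab[2:8, 2:8] <- 1L
  lab[2:8, 12:18] <- 2L
  stats <- data.frame(nucleus_id = 1L, bg_center = 0, bg_sd = 1,
                      n_pixels = 49)
  expect_error(
    detectFoci(ImageField(matrix(0, 10, 20)), LabelMap(lab), stats,
               global_sd = 1),
    "label.*2")
})

test_that("fields without planted foci yield zero counts everywhere", {
  fld <- generateField(FieldSpec(nNuclei = 3, width = 160, height = 160,
                                 fociPerNucleus = 0), seed = 13)
  res <- countFoci(fld$marker, nucleusMasks(fld$truth))
  expect_equal(sum(fociCounts(res)), 0L)
})

test_that("detection equals the literal pixel-by-pixel criteria oracle", {
  for (s in 1:6) {
    fld <- generateField(FieldSpec(nNuclei = 1, width = 64, height = 64,
                                   nucleusRadiusRange = c(20, 24),
                                   fociPerNucleus = s %% 3), seed = 30 + s)
    lab <- nucleusMasks(fld$truth)
    filt <- dogFilter(fld$marker)
    bg <- backgroundStats(filt, lab)
    absMin <- max(pixels(filt)[labelMatrix(lab) == 0L])
    res <- detectFoci(filt, lab, bg$stats, bg$global_sd,
                      DetectionParams(absMin = absMin))
    oracle <- oracleFociPixels(pixels(filt), labelMatrix(lab),
                               foldK = 2, absMin = absMin)
    expect_identical(pixelSetKey(fociPixelSets(res)), pixelSetKey(oracle))
  }
})

test_that("three well-separated bright foci are each recovered", {
  fld <- generateField(FieldSpec(nNuclei = 1, width = 150, height = 150,
                                 nucleusRadiusRange = c(50, 55),
                                 fociPerNucleus = 3), seed = 77)
  res <- countFoci(fld$marker, nucleusMasks(fld$truth))
  expect_equal(unname(fociCounts(res)), 3L)
  # detected centroids pair up with the planted ones
  tr <- focusRecords(fld$truth)
  det <- fociTable(res)
  for (k in seq_len(3)) {
    d <- sqrt((det$x - tr$x[k])^2 + (det$y - tr$y[k])^2)
    expect_lt(min(d), 2)
  }
})

test_that("tightening any detection parameter never raises a count", {
  fld <- generateField(FieldSpec(nNuclei = 2, width = 200, height = 200,
                                 nucleusRadiusRange = c(34, 40),
                                 fociPerNucleus = c(4, 2)), seed = 55)
  lab <- nucleusMasks(fld$truth)
  filt <- dogFilter(fld$marker)
  bg <- backgroundStats(filt, lab)
  count <- function(p) sum(fociCounts(
    detectFoci(filt, lab, bg$stats, bg$global_sd, p)))
  base <- DetectionParams(absMin = 10)
  for (foldK in c(2, 4, 8, 20)) {
    cs <- vapply(c(foldK, foldK * 2),
                 function(k) count(DetectionParams(foldK = k, absMin = 10)),
                 numeric(1))
    expect_gte(cs[1], cs[2])
  }
  for (am in list(c(10, 100), c(100, 400))) {
    expect_gte(count(DetectionParams(absMin = am[1])),
               count(DetectionParams(absMin = am[2])))
  }
  for (ar in list(c(16, 40), c(40, 120))) {
    expect_gte(count(DetectionParams(absMin = 10, minFocusArea = ar[1])),
               count(DetectionParams(absMin = 10, minFocusArea = ar[2])))
  }
})

test_that("count summaries report t-interval CIs and flag degenerate n", {
  s <- countSummary(list(c(3, 3, 3)), "a")
  expect_equal(s$mean_count, 3)
  expect_equal(s$sd_count, 0)

  s1 <- countSummary(list(5), "solo")
  expect_false(s1$ci_defined)
  expect_true(is.na(s1$ci_lower))

  s2 <- countSummary(list(c(0, 1, 2), c(3, 4)), c("a", "a"))
  expect_equal(s2$mean_count, 2)
  expect_equal(s2$sd_count, sqrt(2.5))
  half <- qt(0.975, 4) * sqrt(2.5) / sqrt(5)
  expect_equal(s2$ci_lower, 2 - half)
  expect_equal(s2$ci_upper, 2 + half)

  expect_error(countSummary(list(), character(0)))
  expect_error(countSummary(list(numeric(0)), "empty"), "no nuclei")
})
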