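#' Cumulative cell cycle entry curve of a cohort
#'
#' Fraction of the cohort having entered the requested phase by each grid
#' time. Censored cells (cells that never enter within the horizon) stay
#' in the denominator throughout. Grid times are hours relative to `t0`
#' (entry quantification conventionally starts 8 h post-transfection);
#' entry times in `tracks` are absolute hours post-transfection.
#'
#' @param tracks data.frame of cell tracks as returned by
#'   [simulateTracks()] (columns `event`, `entry_time`, `censored`).
#' @param event `"S_entry"` or `"M_entry"`; only cells whose transition is
#'   this event enter the cohort.
#' @param grid Sorted numeric vector of evaluation times (hours from `t0`).
#' @param t0 Reference time in hours post-transfection (default 8).
#' @return An [EntryCurve-class].
#' @examples
#' trk <- simulateTracks(TrackCohortSpec(nCells = 100), seed = 1)
#' cumulativeEntry(trk, "S_entry", grid = seq(0, 24, 0.5))
#' @export
cumulativeEntry <- function(tracks, event = c("S_entry", "M_entry"),
                            grid = seq(0, 24, by = 0.25), t0 = 8) {
  event <- match.arg(event)
  if (is.unsorted(grid)) stop("'grid' must be sorted")
  sel <- tracks[tracks$event == event, , drop = FALSE]
  n <- nrow(sel)
  if (n == 0L)
    stop("empty cohort: no cells with event '", event, "'")
  entered <- sel$entry_time[!sel$censored & !is.na(sel$entry_time)]
  frac <- vapply(grid, function(t) sum(entered <= t0 + t) / n, numeric(1))
  new("EntryCurve", time = as.numeric(grid), fraction = frac,
      nCells = as.integer(n), event = event, t0 = as.numeric(t0))
}

# first time a curve reaches fraction q, linearly interpolated between
# grid points; NA when the curve never reaches q
.crossingTime <- function(curve, q) {
  f <- curve@fraction
  t <- curve@time
  i <- which(f >= q)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  if (i == 1L || f[i] == f[i - 1L]) return(t[i])
  t[i - 1L] + (q - f[i - 1L]) / (f[i] - f[i - 1L]) * (t[i] - t[i - 1L])
}

#' Entry delay at a quantile crossing
#'
#' The time at which the treated curve first reaches cumulative fraction
#' `q` minus the time at which the control curve does, with linear
#' interpolation between grid points. When either curve never reaches `q`
#' the delay is explicitly not estimable (`NA`, with `estimable = FALSE`),
#' which is distinct from a delay of 0.
#'
#' @param treated,control [EntryCurve-class] objects.
#' @param q Quantile in (0, 1); default 0.5, i.e. the 50% crossing shift.
#' @return A list with `delay` (hours, `NA` when not estimable),
#'   `estimable`, `treated_crossing` and `control_crossing`.
#' @export
delayAtQuantile <- function(treated, control, q = 0.5) {
  stopifnot(is(treated, "EntryCurve"), is(control, "EntryCurve"))
  if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
  ct <- .crossingTime(treated, q)
  cc <- .crossingTime(control, q)
  estimable <- !is.na(ct) && !is.na(cc)
  list(delay = if (estimable) ct - cc else NA_real_,
       estimable = estimable,
       treated_crossing = ct, control_crossing = cc)
}

#' Relative reduction in cumulative entry at a time point
#'
#' `100 * (control(t) - treated(t)) / control(t)`, in percent. Curve
#' values at `t` are linearly interpolated on the grid.
#'
#' @param treated,control [EntryCurve-class] objects.
#' @param t Evaluation time (hours from the curves' t0); must lie within
#'   both grids.
#' @return Percent reduction (numeric scalar).
#' @export
reductionAt <- function(treated, control, t) {
  stopifnot(is(treated, "EntryCurve"), is(control, "EntryCurve"))
  .assertScalarNumber(t, "t")
  valueAt <- function(curve) {
    if (t < curve@time[1] || t > curve@time[length(curve@time)])
      stop("'t' lies outside the curve grid")
    approx(curve@time, curve@fraction, xout = t, ties = "ordered")$y
  }
  ft <- valueAt(treated)
  fc <- valueAt(control)
  if (fc == 0)
    stop("control fraction at t is 0: reduction undefined")
  100 * (fc - ft) / fc
}

#' Micronucleation fold change with an exact test
#'
#' Fold change of the micronucleated-per-division frequency between a
#' treated (e.g. checkpoint-abrogated) and a control (intact) cohort,
#' with a two-sided Fisher exact test on the 2x2 counts. With zero
#' control events the fold is reported as not estimable together with a
#' one-sided lower bound (using the exact upper 97.5% bound of the control
#' frequency), never as infinity.
#'
#' @param treated,control Length-2 numeric vectors
#'   `c(micronucleated, divided)`.
#' @return A list with `fold` (`NA` when not estimable), `estimable`,
#'   `fold_lower_bound` (only informative when not estimable), `p_value`,
#'   and the two frequencies.
#' @examples
#' micronucleationFold(c(10, 100), c(2, 100))$fold
#' @export
micronucleationFold <- function(treated, control) {
  stopifnot(length(treated) == 2L, length(control) == 2L)
  mt <- treated[1]; dt <- treated[2]
  mc <- control[1]; dc <- control[2]
  if (dt <= 0 || dc <= 0) stop("divided counts must be positive")
  if (mt > dt || mc > dc)
    stop("micronucleated counts cannot exceed divided counts")
  p <- fisher.test(matrix(c(mt, dt - mt, mc, dc - mc), nrow = 2))$p.value
  ft <- mt / dt
  fc <- mc / dc
  if (mc == 0) {
    # exact (Clopper-Pearson) upper bound of the control frequency
    upper <- 1 - 0.025^(1 / dc)
    return(list(fold = NA_real_, estimable = FALSE,
                fold_lower_bound = ft / upper, p_value = p,
                freq_treated = ft, freq_control = fc))
  }
  list(fold = ft / fc, estimable = TRUE, fold_lower_bound = NA_real_,
       p_value = p, freq_treated = ft, freq_control = fc)
}

#' Group comparisons for figure-legend statistics
#'
#' `method = "welch_t"` performs Welch two-sample t-tests on all group
#' pairs. `method = "anova_bonferroni"` performs a one-way ANOVA F-test
#' plus all-pairs comparisons using the pooled residual variance, with
#' Bonferroni adjustment (`adjusted p = min(1, raw * number of
#' comparisons)`). Pairs in which both groups have zero variance and
#' identical means are flagged as degenerate with p reported as 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param method `"welch_t"` or `"anova_bonferroni"`.
#' @return A list with `method`, `anova_p` (`NA` for Welch) and
#'   `comparisons`, a data.frame with one row per pair: `group1`,
#'   `group2`, `statistic`, `p_raw`, `p_adjusted`, `degenerate`.
#' @examples
#' groupCompare(list(a = c(2, 4, 6), b = c(5, 7, 9)))$comparisons
#' @export
groupCompare <- function(groups, method = c("welch_t", "anova_bonferroni")) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least two samples")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group must contain at least two observations")

  pairs <- combn(names(groups), 2)
  nComp <- ncol(pairs)
  anovaP <- NA_real_
  pooledVar <- NA_real_
  dfRes <- NA_integer_
  if (method == "anova_bonferroni") {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                  levels = names(groups))
    dfRes <- length(values) - length(groups)
    pooledVar <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                            numeric(1))) / dfRes
    if (pooledVar > 0) {
      fit <- aov(values ~ fac)
      anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
  }

  comp <- lapply(seq_len(nComp), function(i) {
    g1 <- groups[[pairs[1, i]]]
    g2 <- groups[[pairs[2, i]]]
    degenerate <- sd(g1) == 0 && sd(g2) == 0
    if (degenerate) {
      stat <- if (mean(g1) == mean(g2)) 0 else Inf
      praw <- if (mean(g1) == mean(g2)) 1 else 0
    } else if (method == "welch_t") {
      tt <- t.test(g1, g2, var.equal = FALSE)
      stat <- unname(tt$statistic)
      praw <- tt$p.value
    } else {
      if (pooledVar == 0) {
        stat <- if (mean(g1) == mean(g2)) 0 else Inf
        praw <- if (mean(g1) == mean(g2)) 1 else 0
        degenerate <- TRUE
      } else {
        se <- sqrt(pooledVar * (1 / length(g1) + 1 / length(g2)))
        stat <- (mean(g1) - mean(g2)) / se
        praw <- 2 * pt(-abs(stat), dfRes)
      }
    }
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               statistic = stat, p_raw = praw,
               p_adjusted = if (method == "anova_bonferroni")
                 min(1, praw * nComp) else praw,
               degenerate = degenerate)
  })
  list(method = method, anova_p = anovaP,
       comparisons = do.call(rbind, c(comp, list(make.row.names = FALSE))))
}
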