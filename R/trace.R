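#' Per-cell relative-intensity time series
#'
#' A trace of background-relative intensity (Ca_R or RPS, dimensionless fold
#' over background) on an irregular time grid, in minutes post-first
#' embryonic division.
#'
#' @param times Strictly increasing numeric vector of times (minutes).
#' @param values Nonnegative numeric vector of relative intensities.
#' @param cell Cell identifier (character).
#' @param channel Channel label, `"Ca"` or `"PS"`.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, values, cell = "cell", channel = "Ca") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (!length(times)) stop("`times` must be nonempty")
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (anyNA(times) || anyNA(values)) stop("trace contains missing values")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(values < 0)) stop("relative intensities must be nonnegative")
  structure(list(times = times, values = values,
                 cell = as.character(cell), channel = as.character(channel)),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %s/%s: %d points on [%.6g, %.6g] min\n",
              x$cell, x$channel, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Named analysis time windows
#'
#' The standard integration windows, in minutes post-first embryonic
#' division: the full recording (560-900), the overall analysis window
#' (560-800), the pre-swelling period 1 (560-695; 695 min is the mean time at
#' which cell swelling becomes visible) and the post-swelling period 2
#' (696-800), during which surface PS becomes detectable.
#'
#' @return Named list of `c(lower, upper)` windows.
#' @export
time_windows <- function() {
  list(recording = c(560, 900),
       overall   = c(560, 800),
       period1   = c(560, 695),
       period2   = c(696, 800))
}

# trapezoid rule on an irregular grid
.trapz <- function(t, v) {
  n <- length(t)
  if (n < 2) return(0)
  sum((v[-1] + v[-n]) / 2 * diff(t))
}

#' Windowed trapezoidal integral of a trace
#'
#' Integrates a relative-intensity trace over a time window with the
#' trapezoid rule on the native irregular grid (no smoothing). By default the
#' trace is linearly interpolated to the exact window bounds; in
#' `mode = "observed"` only observed samples inside the window are used, with
#' no edge interpolation. Traces with fewer than 10 points do not qualify for
#' integral analysis unless `allow_short = TRUE`.
#'
#' @param trace An `intensity_trace`.
#' @param window `c(lower, upper)` in minutes (default the overall 560-800
#'   window).
#' @param mode `"interpolate"` (default) or `"observed"`.
#' @param allow_short Override the 10-point qualification rule.
#' @return Numeric integral in fold-minutes.
#' @export
integrate_trace <- function(trace, window = time_windows()$overall,
                            mode = c("interpolate", "observed"),
                            allow_short = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  mode <- match.arg(mode)
  if (length(window) != 2 || window[1] >= window[2])
    stop("`window` must be c(lower, upper) with lower < upper")
  if (length(trace$times) < 10 && !allow_short)
    stop("trace has fewer than 10 time points and does not qualify for ",
         "integral analysis (set allow_short = TRUE to override)")
  t <- trace$times; v <- trace$values
  lo <- max(window[1], t[1]); hi <- min(window[2], t[length(t)])
  if (lo >= hi)
    stop("window [", window[1], ", ", window[2],
         "] lies outside the trace support")
  if (lo > window[1] || hi < window[2])
    warning("trace does not cover the full window; truncated to [",
            signif(lo, 6), ", ", signif(hi, 6), "]")
  inside <- t > lo & t < hi
  if (mode == "interpolate") {
    tt <- c(lo, t[inside], hi)
    vv <- c(stats::approx(t, v, xout = lo)$y, v[inside],
            stats::approx(t, v, xout = hi)$y)
  } else {
    keep <- t >= lo & t <= hi
    if (sum(keep) < 2) stop("fewer than 2 observed points inside the window")
    tt <- t[keep]; vv <- v[keep]
  }
  .trapz(tt, vv)
}

# first index of a run of >= min_run TRUEs, NA if none
.first_run <- function(flag, min_run) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_run)
  if (!length(ok)) return(NA_integer_)
  starts[ok[1]]
}

#' Detect the onset of a sustained intensity rise
#'
#' Returns the first time at which the trace exceeds `threshold_fold` for at
#' least `min_run` consecutive samples, or `NA` if it never does. The default
#' threshold of 1.2-fold is the level that calcium traces of cells with a
#' disabled ER calcium pool never exceed, making it a conservative criterion
#' for a genuine cytoplasmic calcium rise.
#'
#' @param trace An `intensity_trace`.
#' @param threshold_fold Fold-over-background threshold (default 1.2).
#' @param min_run Minimum consecutive samples above threshold (default 2).
#' @return Onset time in minutes, or `NA_real_`.
#' @export
detect_onset <- function(trace, threshold_fold = 1.2, min_run = 2) {
  stopifnot(inherits(trace, "intensity_trace"), threshold_fold > 0,
            min_run >= 1)
  i <- .first_run(trace$values > threshold_fold, min_run)
  if (is.na(i)) NA_real_ else trace$times[i]
}

#' Detect the onset of cell swelling from a radius track
#'
#' Returns the first time the equivalent cell radius exceeds
#' `fold_threshold` times its initial value, or `NA` if it never does.
#'
#' @param times Strictly increasing times (minutes), or a data frame with
#'   columns `time` and `radius`.
#' @param radius Radii in pixels (ignored when `times` is a data frame).
#' @param fold_threshold Fold over the initial radius (default 1.02; with
#'   the generator's default growth rate this detects swelling within one
#'   sampling interval of its onset).
#' @return Onset time in minutes, or `NA_real_`.
#' @export
detect_swelling <- function(times, radius = NULL, fold_threshold = 1.02) {
  if (is.data.frame(times)) {
    radius <- times$radius; times <- times$time
  }
  stopifnot(length(times) == length(radius), fold_threshold > 1)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  r0 <- radius[1]
  if (!is.finite(r0) || r0 <= 0) stop("initial radius must be positive")
  i <- which(radius > fold_threshold * r0)
  if (!length(i)) NA_real_ else times[i[1]]
}

#' Characterize transient peaks of a trace
#'
#' Identifies maximal runs of samples above `threshold_fold` and reports, for
#' each, the peak value, the peak time, and the duration above threshold.
#' Run boundaries are refined by linear interpolation of the threshold
#' crossings, so single-sample excursions still have positive duration.
#'
#' @param trace An `intensity_trace`.
#' @param threshold_fold Fold-over-background threshold (default 1.2).
#' @return Data frame with columns `peak_value`, `peak_time`,
#'   `duration_min`, `start_time`, `end_time`; zero rows if no peaks.
#' @export
peak_metrics <- function(trace, threshold_fold = 1.2) {
  stopifnot(inherits(trace, "intensity_trace"), threshold_fold > 0)
  t <- trace$times; v <- trace$values
  above <- v > threshold_fold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  idx <- which(r$values)
  out <- data.frame(peak_value = numeric(0), peak_time = numeric(0),
                    duration_min = numeric(0), start_time = numeric(0),
                    end_time = numeric(0))
  cross <- function(i1, i2) {
    # interpolated time where the trace crosses the threshold between samples
    t[i1] + (threshold_fold - v[i1]) * (t[i2] - t[i1]) / (v[i2] - v[i1])
  }
  for (k in idx) {
    s <- starts[k]; e <- ends[k]
    tstart <- if (s > 1) cross(s - 1, s) else t[s]
    tend <- if (e < length(t)) cross(e + 1, e) else t[e]
    imax <- s - 1 + which.max(v[s:e])
    out <- rbind(out, data.frame(
      peak_value = v[imax], peak_time = t[imax],
      duration_min = tend - tstart, start_time = tstart, end_time = tend))
  }
  out
}

#' Standard error of the mean
#'
#' @param x Numeric vector.
#' @return `sd(x) / sqrt(length(x))`; 0 for a single value.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  stats::sd(x) / sqrt(length(x))
}

#' Ratio of cohort mean integrals, as a percentage
#'
#' Summarizes two cohorts of per-cell integral values and reports
#' `100 * mean(test) / mean(reference)` together with each cohort's mean and
#' standard error, the form in which integrated calcium signals of different
#' genotypes are compared.
#'
#' @param test,reference Numeric vectors of per-cell integrals.
#' @return List with `ratio_pct`, `test_mean`, `test_sem`, `reference_mean`,
#'   `reference_sem`, `n_test`, `n_reference`.
#' @export
integral_ratio <- function(test, reference) {
  if (!length(test) || !length(reference))
    stop("both cohorts must be nonempty")
  mref <- mean(reference)
  if (!is.finite(mref) || mref <= 0)
    stop("reference cohort mean must be positive")
  list(ratio_pct = 100 * mean(test) / mref,
       test_mean = mean(test), test_sem = sem(test),
       reference_mean = mref, reference_sem = sem(reference),
       n_test = length(test), n_reference = length(reference))
}
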