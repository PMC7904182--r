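#' Normalize per-cell intensities to a reference condition
#'
#' Divides every cell's relative intensity by the mean of the reference
#' condition's cohort, so the reference cohort's normalized mean is exactly
#' 1. This is the "normalized relative PS intensity" convention used to
#' compare genotypes and drug doses to a control.
#'
#' @param values Numeric vector of per-cell relative intensities (RPS).
#' @param condition Character/factor vector of condition labels, same length.
#' @param reference Label of the reference condition.
#' @return List with `table` (per-cell data frame: `condition`, `value`,
#'   `normalized`) and `summary` (per-condition data frame: `condition`,
#'   `n`, `mean`, `sem`).
#' @export
normalize_to_reference <- function(values, condition, reference) {
  stopifnot(length(values) == length(condition))
  condition <- as.character(condition)
  if (!reference %in% condition)
    stop("reference condition '", reference, "' not present")
  ref_mean <- mean(values[condition == reference])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference cohort mean must be positive")
  norm <- values / ref_mean
  tab <- data.frame(condition = condition, value = values,
                    normalized = norm, stringsAsFactors = FALSE)
  conds <- unique(condition)
  summ <- data.frame(
    condition = conds,
    n = vapply(conds, function(cc) sum(condition == cc), integer(1)),
    mean = vapply(conds, function(cc) mean(norm[condition == cc]),
                  numeric(1)),
    sem = vapply(conds, function(cc) sem(norm[condition == cc]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, summary = summ)
}

#' Log-log linear regression between integrated signals
#'
#' Ordinary least squares of `log(y)` on `log(x)` (natural log), the
#' analysis relating the integrated cytoplasmic calcium signal to the
#' integrated surface-PS signal across cells or time points. Returns the
#' slope, intercept, Pearson correlation coefficient r of the
#' log-transformed pairs, and the coefficient of determination R^2 (equal to
#' r^2 for simple linear regression).
#'
#' @param x,y Paired positive numeric vectors (n >= 3).
#' @return List of class `loglog_regression` with `slope`, `intercept`, `r`,
#'   `r_squared`, `n`.
#' @export
log_integral_regression <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired")
  if (length(x) < 3) stop("at least 3 paired points are required")
  bad <- which(!(is.finite(x) & is.finite(y) & x > 0 & y > 0))
  if (length(bad))
    stop("non-positive or non-finite values cannot be log-transformed ",
         "(pairs: ", paste(utils::head(bad, 10), collapse = ", "), ")")
  lx <- log(x); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  r <- stats::cor(lx, ly)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, r_squared = r^2, n = length(x)),
            class = "loglog_regression")
}

#' @export
print.loglog_regression <- function(x, ...) {
  cat(sprintf(
    "<loglog_regression> n=%d  slope=%.4g  intercept=%.4g  r=%.4g  R2=%.4g\n",
    x$n, x$slope, x$intercept, x$r, x$r_squared))
  invisible(x)
}

#' Grouped summary of per-animal cell counts
#'
#' Animals are partitioned into consecutive groups of `group_size` (the
#' scoring convention: e.g. 10 animals per group), the mean count per group
#' is computed, and the cohort is summarized as the mean of group means with
#' its standard error over groups. A trailing partial group is kept and
#' flagged.
#'
#' @param counts Nonnegative integer vector of per-animal cell counts.
#' @param group_size Animals per group (default 10).
#' @return List with `group_means`, `mean`, `sem`, `n_animals`, `n_groups`,
#'   `partial_last_group`.
#' @export
grouped_count_summary <- function(counts, group_size = 10) {
  if (group_size < 1) stop("`group_size` must be at least 1")
  if (!length(counts)) stop("`counts` must be nonempty")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be nonnegative integers")
  grp <- ceiling(seq_along(counts) / group_size)
  gm <- as.numeric(tapply(counts, grp, mean))
  partial <- length(counts) %% group_size != 0
  if (partial)
    warning("trailing partial group of ", length(counts) %% group_size,
            " animals kept")
  list(group_means = gm, mean = mean(gm), sem = sem(gm),
       n_animals = length(counts), n_groups = length(gm),
       partial_last_group = partial)
}

#' Fraction of live cells exposing surface PS
#'
#' Percentage of live (non-swollen) cells whose relative surface-PS
#' intensity exceeds a positivity threshold, with a binomial standard error.
#'
#' @param rps Numeric vector of per-cell RPS values of live cells.
#' @param threshold Positivity threshold on RPS (default 1.5).
#' @return List with `n`, `n_positive`, `percentage`, `sem`.
#' @export
ps_positive_fraction <- function(rps, threshold = 1.5) {
  if (!length(rps)) stop("`rps` must be nonempty")
  pos <- rps > threshold
  p <- mean(pos)
  list(n = length(rps), n_positive = sum(pos), percentage = 100 * p,
       sem = 100 * sqrt(p * (1 - p) / length(rps)))
}

#' Dose-response summary table
#'
#' Summarizes per-cell PS intensities (and optionally per-animal necrotic
#' cell counts) across drug doses: intensities are normalized to the
#' zero/vehicle dose, each dose gets a mean with standard error, and
#' monotonicity of the normalized means across increasing dose is reported.
#'
#' @param dose Numeric dose per measurement.
#' @param rps Per-cell relative PS intensity, paired with `dose`.
#' @param count_dose,counts Optional per-animal necrotic-cell counts and
#'   their doses.
#' @param group_size Group size for the count summary (default 10).
#' @return List with `intensity` (data frame: `dose`, `n`,
#'   `normalized_mean`, `sem`), optional `counts` (data frame: `dose`,
#'   `mean_count`, `sem`, `n_animals`), and `monotone` (list with
#'   `non_increasing` and `non_decreasing` flags for the normalized means).
#' @export
dose_response_table <- function(dose, rps, count_dose = NULL, counts = NULL,
                                group_size = 10) {
  stopifnot(length(dose) == length(rps))
  doses <- sort(unique(dose))
  if (!0 %in% doses) stop("a zero/vehicle dose is required")
  norm <- normalize_to_reference(rps, as.character(dose), "0")
  summ <- norm$summary
  summ$dose <- as.numeric(summ$condition)
  summ <- summ[order(summ$dose), c("dose", "n", "mean", "sem")]
  names(summ)[3] <- "normalized_mean"
  rownames(summ) <- NULL
  res <- list(intensity = summ,
              monotone = list(
                non_increasing = all(diff(summ$normalized_mean) <= 1e-12),
                non_decreasing = all(diff(summ$normalized_mean) >= -1e-12)))
  if (!is.null(counts)) {
    stopifnot(length(count_dose) == length(counts))
    cd <- sort(unique(count_dose))
    res$counts <- do.call(rbind, lapply(cd, function(d) {
      g <- grouped_count_summary(counts[count_dose == d], group_size)
      data.frame(dose = d, mean_count = g$mean, sem = g$sem,
                 n_animals = g$n_animals)
    }))
  }
  res
}

#' Convenience two-sample t test
#'
#' Thin wrapper around [stats::t.test()] (Welch by default) returning the
#' pieces reported alongside cohort comparisons.
#'
#' @param x,y Numeric vectors.
#' @param ... Passed to [stats::t.test()].
#' @return List with `p_value`, `t`, `df`, `mean_x`, `mean_y`.
#' @export
cohort_t_test <- function(x, y, ...) {
  tt <- stats::t.test(x, y, ...)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), mean_x = mean(x), mean_y = mean(y))
}
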