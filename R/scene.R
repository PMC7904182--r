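# Synthetic two-channel time-lapse scenes with per-cell ground truth.
#
# The generator produces cytoplasmic-calcium and surface-PS relative
# intensity traces with the phenomenology of excitotoxic touch-neuron
# necrosis: baseline-plus-transient Ca traces, threshold-triggered swelling,
# delayed sigmoidal PS onset, and an exact log-linear coupling between the
# integrated Ca and PS signals.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.cumtrapz <- function(t, v) {
  n <- length(t)
  c(0, cumsum((v[-1] + v[-n]) / 2 * diff(t)))
}

#' Default time-lapse recording grid
#'
#' Times in minutes post-first embryonic division: 2.5-min intervals from 560
#' to 680 min and 5-min intervals from 685 to 900 min, the schedule used for
#' embryonic time-lapse recordings of touch-neuron necrosis.
#'
#' @return Numeric vector of 93 strictly increasing times.
#' @export
recording_times <- function() {
  c(seq(560, 680, by = 2.5), seq(685, 900, by = 5))
}

#' Parameters of a simulated calcium transient trace
#'
#' @param peak_amplitudes Fold-over-background peak heights (1 = baseline).
#'   Necrotic cells show peaks of 1.4- to 5-fold of background; cells with a
#'   disabled ER calcium pool never exceed 1.2-fold.
#' @param peak_times Peak times in minutes; must lie within the recording
#'   window of the `times` grid the trace is evaluated on.
#' @param rise_width Half-Gaussian rise width(s) in minutes (> 0).
#' @param decay_width Exponential decay time(s) in minutes (> 0).
#' @param baseline_fold Baseline relative intensity (default 1; raised by
#'   blocked calcium reuptake).
#' @param peak_cap Maximum allowed fold over background (`Inf` = uncapped).
#' @param noise_sd Fractional multiplicative Gaussian noise (0 = noise-free).
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(peak_amplitudes = numeric(0),
                         peak_times = numeric(0),
                         rise_width = 6, decay_width = 20,
                         baseline_fold = 1, peak_cap = Inf,
                         noise_sd = 0, seed = NULL) {
  np <- length(peak_amplitudes)
  if (length(peak_times) != np)
    stop("`peak_amplitudes` and `peak_times` must have equal length")
  rise_width <- rep_len(rise_width, max(np, 1))
  decay_width <- rep_len(decay_width, max(np, 1))
  if (any(rise_width <= 0) || any(decay_width <= 0))
    stop("all peak widths must be positive")
  if (baseline_fold <= 0) stop("`baseline_fold` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  structure(list(peak_amplitudes = as.numeric(peak_amplitudes),
                 peak_times = as.numeric(peak_times),
                 rise_width = rise_width, decay_width = decay_width,
                 baseline_fold = baseline_fold, peak_cap = peak_cap,
                 noise_sd = noise_sd, seed = seed),
            class = "trace_params")
}

# smooth bump: half-Gaussian rise, exponential decay, height 1 at the peak
.bump <- function(t, tp, rise, decay) {
  ifelse(t <= tp, exp(-0.5 * ((t - tp) / rise)^2), exp(-(t - tp) / decay))
}

#' Simulate a relative calcium-intensity trace
#'
#' Evaluates a baseline-plus-transients trace on a time grid: each transient
#' is a smooth bump (half-Gaussian rise, exponential decay) of the stated
#' fold amplitude, the sum is truncated at `peak_cap`, and optional
#' multiplicative Gaussian noise is applied (clipped at 0).
#'
#' @param params A `trace_params` object.
#' @param times Strictly increasing times in minutes.
#' @param cell,channel Labels for the returned trace.
#' @return An `intensity_trace` of relative intensity (fold over background).
#' @export
simulate_ca_trace <- function(params, times, cell = "cell", channel = "Ca") {
  stopifnot(inherits(params, "trace_params"))
  times <- as.numeric(times)
  if (!length(times)) stop("`times` must be nonempty")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  np <- length(params$peak_amplitudes)
  if (np && (min(params$peak_times) < min(times) ||
             max(params$peak_times) > max(times)))
    stop("peak times must lie within the recording window")
  v <- rep(params$baseline_fold, length(times))
  for (i in seq_len(np)) {
    v <- v + (params$peak_amplitudes[i] - 1) *
      .bump(times, params$peak_times[i], params$rise_width[i],
            params$decay_width[i])
  }
  v <- pmin(v, params$peak_cap)
  if (params$noise_sd > 0) {
    v <- .with_seed(params$seed,
                    v * (1 + stats::rnorm(length(v), 0, params$noise_sd)))
    # the cap bounds the observed signal, not just the underlying one
    v <- pmin(pmax(v, 0), params$peak_cap)
  }
  intensity_trace(times, v, cell = cell, channel = channel)
}

#' Genotype/drug scenario configuration for the synthetic generator
#'
#' Phenomenological parameterization of a cohort: how much calcium the
#' ER releases (`er_release_gain`; dantrolene dose lowers it, a calreticulin
#' null sets it to ~0), how much the baseline is elevated by blocked reuptake
#' (`reuptake_block`; thapsigargin dose raises it), the integrated-calcium
#' threshold at which swelling begins, and the log-linear coupling from the
#' integrated calcium signal to the integrated surface-PS signal.
#'
#' @param name Scenario label (unique within a cohort).
#' @param n_cells Number of cells (>= 1).
#' @param channel_leak Relative amplitude of small leak-driven fluctuations.
#' @param er_release_gain Multiplier (>= 0) on the drawn peak enrichments.
#' @param reuptake_block Baseline elevation (fold - 1) from blocked reuptake.
#' @param swelling_threshold Integrated (Ca_R - 1) level, in fold-minutes,
#'   above which swelling begins. The default is calibrated so that the mean
#'   swelling onset of the default necrotic cohort falls near 695 min, the
#'   mean time at which swelling becomes visible in recordings.
#' @param ps_coupling_slope,ps_coupling_intercept Slope and intercept (natural
#'   log) of the map from log integrated Ca_R to log integrated RPS over the
#'   recording window.
#' @param ps_delay Minutes between swelling onset and PS onset.
#' @param ps_tau Time constant (min) of the saturating PS rise.
#' @param peak_cap Maximum fold over background for the calcium trace.
#' @param noise_sd Fractional multiplicative noise on both channels.
#' @param cell_radius Initial cell radius in pixels.
#' @param swell_fold,swell_duration Radius growth target (fold over initial)
#'   and the time (min) over which it is reached after swelling onset.
#' @param dropout_prob Probability that an observed time point is lost
#'   (emulates focal drift); ground truth keeps the full grid.
#' @param times Recording grid (default [recording_times()]).
#' @param seed Integer seed; per-cell streams are derived from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name, n_cells = 4, channel_leak = 0.1,
                            er_release_gain = 1, reuptake_block = 0,
                            swelling_threshold = 90,
                            ps_coupling_slope = 1,
                            ps_coupling_intercept = log(1.6),
                            ps_delay = 15, ps_tau = 25,
                            peak_cap = Inf, noise_sd = 0.05,
                            cell_radius = 10, swell_fold = 2.5,
                            swell_duration = 150,
                            dropout_prob = 0, times = recording_times(),
                            seed = 1) {
  if (missing(name) || !nzchar(name)) stop("scenario `name` is required")
  if (n_cells < 1) stop("`n_cells` must be at least 1")
  if (er_release_gain < 0 || reuptake_block < 0 || channel_leak < 0)
    stop("all gains must be nonnegative")
  if (swelling_threshold <= 0) stop("`swelling_threshold` must be positive")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("`dropout_prob` must be in [0, 1)")
  structure(list(name = name, n_cells = as.integer(n_cells),
                 channel_leak = channel_leak,
                 er_release_gain = er_release_gain,
                 reuptake_block = reuptake_block,
                 swelling_threshold = swelling_threshold,
                 ps_coupling_slope = ps_coupling_slope,
                 ps_coupling_intercept = ps_coupling_intercept,
                 ps_delay = ps_delay, ps_tau = ps_tau,
                 peak_cap = peak_cap, noise_sd = noise_sd,
                 cell_radius = cell_radius, swell_fold = swell_fold,
                 swell_duration = swell_duration,
                 dropout_prob = dropout_prob,
                 times = as.numeric(times), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Preset scenarios
#'
#' Convenience constructors for the standard study conditions:
#' `scenario_mec4d()` is the necrotic reference (full ER release, uncapped
#' peaks drawn from 1.4-5 fold); `scenario_wildtype()` has weak release and
#' no swelling; `scenario_crt1()` disables ER release and caps the trace at
#' 1.2-fold of background; `scenario_dantrolene(dose)` lowers the ER release
#' gain with dose (micromolar); `scenario_thapsigargin(dose)` raises the
#' baseline with dose (micrograms per ml) by blocking reuptake.
#'
#' @param seed Integer seed.
#' @param dose Drug dose (see above for units).
#' @param ... Further arguments passed to [scenario_config()].
#' @return A `scenario_config`.
#' @name scenario_presets
NULL

#' @rdname scenario_presets
#' @export
scenario_mec4d <- function(seed = 1, ...) {
  scenario_config("mec-4d", seed = seed, ...)
}

#' @rdname scenario_presets
#' @export
scenario_wildtype <- function(seed = 1, ...) {
  scenario_config("wild-type", er_release_gain = 0.25, seed = seed, ...)
}

#' @rdname scenario_presets
#' @export
scenario_crt1 <- function(seed = 1, ...) {
  scenario_config("crt-1", er_release_gain = 0, channel_leak = 0.15,
                  peak_cap = 1.2, seed = seed, ...)
}

#' @rdname scenario_presets
#' @export
scenario_dantrolene <- function(dose = 0, seed = 1, ...) {
  stopifnot(dose >= 0)
  scenario_config(sprintf("dantrolene_%guM", dose),
                  er_release_gain = max(0, 1 - 0.22 * dose),
                  seed = seed, ...)
}

#' @rdname scenario_presets
#' @export
scenario_thapsigargin <- function(dose = 0, seed = 1, ...) {
  stopifnot(dose >= 0)
  scenario_config(sprintf("thapsigargin_%gug_ml", dose),
                  er_release_gain = 0.25, reuptake_block = 0.06 * dose,
                  seed = seed, ...)
}

#' Simulate one cell of a scenario
#'
#' Generates the cell's calcium trace, surface-PS trace, radius track and
#' ground-truth record. Swelling onset is the first grid time at which the
#' running trapezoidal integral of (Ca_R - 1) exceeds the scenario's
#' swelling threshold; the radius then grows linearly to `swell_fold` times
#' its initial value. PS onset follows swelling by `ps_delay` minutes, after
#' which the RPS trace rises as a saturating exponential to a plateau chosen
#' so that the trapezoidal integral of RPS over the recording grid equals
#' `exp(intercept + slope * log(integral of Ca_R))` exactly. All noise is
#' multiplicative on intensities; ground truth is computed noise-free.
#'
#' @param config A `scenario_config`.
#' @param cell_index Positive integer; also seeds the per-cell RNG stream.
#' @return List with elements `ca` and `ps` (`intensity_trace`s), `radius`
#'   (data frame `time`, `radius`) and `truth` (one-row data frame).
#' @export
simulate_cell <- function(config, cell_index = 1) {
  stopifnot(inherits(config, "scenario_config"), cell_index >= 1)
  times <- config$times
  cell_id <- sprintf("%s_cell%02d", config$name, cell_index)
  cell_seed <- config$seed + 7919L * as.integer(cell_index)

  # transient and leak-bump time ranges, clipped to the recording grid
  tmin <- min(times); tmax <- max(times)
  pk_lo <- max(570, tmin); pk_hi <- min(760, tmax)
  if (pk_lo >= pk_hi) {
    pk_lo <- tmin + 0.1 * (tmax - tmin); pk_hi <- tmin + 0.8 * (tmax - tmin)
  }
  lk_lo <- max(565, tmin); lk_hi <- min(880, tmax)
  if (lk_lo >= lk_hi) { lk_lo <- tmin; lk_hi <- tmax }

  draws <- .with_seed(cell_seed, {
    n_peaks <- sample(2:4, 1)
    list(
      n_peaks = n_peaks,
      peak_times = sort(stats::runif(n_peaks, pk_lo, pk_hi)),
      raw_amp = stats::runif(n_peaks, 1.4, 5.0),
      rise = stats::runif(n_peaks, 4, 8),
      decay = stats::runif(n_peaks, 15, 30),
      leak_times = stats::runif(2, lk_lo, lk_hi),
      leak_amp = 1 + config$channel_leak * stats::runif(2, 0.5, 1.5),
      noise_ca = stats::rnorm(length(times)),
      noise_ps = stats::rnorm(length(times)),
      dropout = stats::runif(length(times))
    )
  })

  amp <- 1 + (draws$raw_amp - 1) * config$er_release_gain
  params0 <- trace_params(
    peak_amplitudes = c(amp, draws$leak_amp),
    peak_times = c(draws$peak_times, draws$leak_times),
    rise_width = c(draws$rise, rep(3, 2)),
    decay_width = c(draws$decay, rep(8, 2)),
    baseline_fold = 1 + config$reuptake_block,
    peak_cap = config$peak_cap, noise_sd = 0)
  ca0 <- simulate_ca_trace(params0, times, cell = cell_id, channel = "Ca")

  # event times from the noise-free trace
  i_on <- which(ca0$values > 1.2)
  ca_onset <- if (length(i_on)) times[i_on[1]] else NA_real_
  cum <- .cumtrapz(times, ca0$values - 1)
  i_sw <- which(cum > config$swelling_threshold)
  swelling_onset <- if (length(i_sw)) times[i_sw[1]] else NA_real_

  r0 <- config$cell_radius
  radius <- rep(r0, length(times))
  if (!is.na(swelling_onset)) {
    grow <- pmax(0, times - swelling_onset) / config$swell_duration
    radius <- r0 * pmin(config$swell_fold, 1 + (config$swell_fold - 1) * grow)
  }

  ca_integral <- .trapz(times, ca0$values)
  span <- max(times) - min(times)
  ps_onset <- NA_real_
  plateau <- 1
  ps0_values <- rep(1, length(times))
  if (!is.na(swelling_onset)) {
    ps_onset <- swelling_onset + config$ps_delay
    ramp <- ifelse(times >= ps_onset,
                   1 - exp(-(times - ps_onset) / config$ps_tau), 0)
    r_int <- .trapz(times, ramp)
    target <- exp(config$ps_coupling_intercept +
                    config$ps_coupling_slope * log(ca_integral))
    enrich <- if (r_int > 0) max(0, (target - span) / r_int) else 0
    plateau <- 1 + enrich
    ps0_values <- 1 + enrich * ramp
  }
  ps_integral <- .trapz(times, ps0_values)

  ca_values <- ca0$values
  ps_values <- ps0_values
  if (config$noise_sd > 0) {
    ca_values <- pmin(pmax(0, ca_values * (1 + config$noise_sd *
                                             draws$noise_ca)),
                      config$peak_cap)
    ps_values <- pmax(0, ps_values * (1 + config$noise_sd * draws$noise_ps))
  }

  list(
    ca = intensity_trace(times, ca_values, cell = cell_id, channel = "Ca"),
    ps = intensity_trace(times, ps_values, cell = cell_id, channel = "PS"),
    radius = data.frame(time = times, radius = radius),
    truth = data.frame(
      scenario = config$name, cell = cell_id,
      ca_onset = ca_onset, swelling_onset = swelling_onset,
      ps_onset = ps_onset, ca_integral = ca_integral,
      ps_integral = ps_integral, ps_plateau = plateau,
      radius0 = r0, stringsAsFactors = FALSE),
    dropout_keep = draws$dropout >= config$dropout_prob
  )
}

#' Simulate a cohort of scenarios
#'
#' Runs [simulate_cell()] for every cell of every scenario and assembles a
#' long-format observation table plus the ground-truth table. Reproducible:
#' identical configurations (including seeds) give bit-identical tables.
#'
#' @param configs A `scenario_config` or list of them (unique names).
#' @return List with `traces` (data frame: `scenario`, `cell`, `time_min`,
#'   `ca_r`, `rps`, `radius_px`), `truth` (one row per cell) and `cells`
#'   (the raw per-cell simulation objects).
#' @export
simulate_cohort <- function(configs) {
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  if (!length(configs)) stop("at least one scenario is required")
  nms <- vapply(configs, function(cf) cf$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate scenario names: ",
                               paste(unique(nms[duplicated(nms)]),
                                     collapse = ", "))
  traces <- list(); truth <- list(); cells <- list()
  for (cf in configs) {
    if (cf$n_cells < 1) stop("`n_cells` must be at least 1")
    for (i in seq_len(cf$n_cells)) {
      cell <- simulate_cell(cf, i)
      keep <- cell$dropout_keep
      if (sum(keep) < 2) keep[1:2] <- TRUE
      traces[[length(traces) + 1]] <- data.frame(
        scenario = cf$name, cell = cell$ca$cell,
        time_min = cell$ca$times[keep],
        ca_r = cell$ca$values[keep], rps = cell$ps$values[keep],
        radius_px = cell$radius$radius[keep], stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- cell$truth
      cells[[cell$ca$cell]] <- cell
    }
  }
  list(traces = do.call(rbind, traces), truth = do.call(rbind, truth),
       cells = cells)
}

# ---- frame rendering ------------------------------------------------------

.disk_mask <- function(nr, nc, cx, cy, r_in, r_out) {
  dx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  dy <- matrix(rep(seq_len(nr), nc), nr, nc) - cy
  d <- sqrt(dx^2 + dy^2)
  d > r_in & d <= r_out
}

#' Render a simulated cohort as two-channel image stacks
#'
#' Rasterizes simulated cells into per-time-point grayscale frames over an
#' additive background plane of known unit intensity. The calcium channel
#' fills the cell disk with `Ca_R x background`; the PS channel places
#' `RPS x background` only in a ring of `ring_width` pixels at the cell
#' boundary. Cell centers are offset from the pixel lattice so that ROI
#' polygons and rendered masks agree to rasterization tolerance.
#'
#' @param cells List of [simulate_cell()] results (or a [simulate_cohort()]
#'   result, whose `cells` element is used).
#' @param centers Two-column matrix of cell centers `(x, y)`; `NULL` places
#'   cells automatically on a grid.
#' @param width,height Image dimensions in pixels.
#' @param background_unit Background plane intensity (arbitrary units).
#' @param ring_width PS ring width in pixels (2-4 typical).
#' @param noise_sd Fractional per-pixel multiplicative noise (0 = clean).
#' @param seed Seed for the pixel noise.
#' @return An object of class `frame_stack`: lists of matrices `ca` and
#'   `ps`, plus `times`, `centers`, `radii` (cells x times), and geometry.
#' @export
render_frames <- function(cells, centers = NULL, width = 128, height = 128,
                          background_unit = 100, ring_width = 3,
                          noise_sd = 0, seed = NULL) {
  if (is.list(cells) && !is.null(cells$cells)) cells <- cells$cells
  if (!length(cells)) stop("no cells to render")
  n <- length(cells)
  times <- cells[[1]]$ca$times
  radii <- t(vapply(cells, function(cl) cl$radius$radius,
                    numeric(length(times))))
  rmax <- apply(radii, 1, max)
  if (is.null(centers)) {
    k <- ceiling(sqrt(n))
    gx <- seq_len(k); gy <- seq_len(ceiling(n / k))
    pos <- expand.grid(x = gx, y = gy)[seq_len(n), ]
    margin <- max(rmax) + ring_width + 2
    centers <- cbind(
      x = margin + (pos$x - 1) * (width - 2 * margin) / max(1, k - 1) + 0.37,
      y = margin + (pos$y - 1) * (height - 2 * margin) /
        max(1, length(gy) - 1) + 0.61)
    if (k == 1) centers[, "x"] <- width / 2 + 0.37
    if (length(gy) == 1) centers[, "y"] <- height / 2 + 0.61
  }
  centers <- as.matrix(centers)
  lim <- rmax + ring_width + 1
  if (any(centers[, 1] - lim < 0.5) || any(centers[, 1] + lim > width + 0.5) ||
      any(centers[, 2] - lim < 0.5) || any(centers[, 2] + lim > height + 0.5))
    stop("cells overlap the image border; enlarge the image or move centers")

  noise <- NULL
  if (noise_sd > 0)
    noise <- .with_seed(seed,
      lapply(seq_along(times), function(i)
        matrix(stats::rnorm(width * height, 0, noise_sd), height, width)))

  ca_frames <- vector("list", length(times))
  ps_frames <- vector("list", length(times))
  for (ti in seq_along(times)) {
    ca_img <- matrix(background_unit, height, width)
    ps_img <- matrix(background_unit, height, width)
    for (ci in seq_len(n)) {
      r <- radii[ci, ti]
      disk <- .disk_mask(height, width, centers[ci, 1], centers[ci, 2], 0, r)
      ring <- .disk_mask(height, width, centers[ci, 1], centers[ci, 2],
                         r, r + ring_width)
      ca_img[disk] <- cells[[ci]]$ca$values[ti] * background_unit
      ps_img[ring] <- cells[[ci]]$ps$values[ti] * background_unit
    }
    if (!is.null(noise)) {
      ca_img <- pmax(0, ca_img * (1 + noise[[ti]]))
      ps_img <- pmax(0, ps_img * (1 + noise[[ti]]))
    }
    ca_frames[[ti]] <- ca_img
    ps_frames[[ti]] <- ps_img
  }
  structure(list(ca = ca_frames, ps = ps_frames, times = times,
                 centers = centers, radii = radii,
                 cell_ids = vapply(cells, function(cl) cl$ca$cell,
                                   character(1)),
                 background_unit = background_unit, ring_width = ring_width,
                 width = width, height = height),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d cells x %d frames, %dx%d px, background %g\n",
              nrow(x$centers), length(x$times), x$height, x$width,
              x$background_unit))
  invisible(x)
}

#' Quantify a rendered frame stack with the annulus pipeline
#'
#' Applies the polygon/annulus quantification to every cell and frame of a
#' rendered stack: Ca_R from a disk polygon over the cell body against a
#' matched background disk, and RPS from the donut annulus at the cell
#' boundary against the same background. The background disk is placed in
#' the image corner farthest from all cells.
#'
#' @param stack A `frame_stack`.
#' @param n_vertices Vertices of the disk/annulus polygons (default 256).
#' @return Long-format data frame: `cell`, `time_min`, `ca_r`, `rps`.
#' @export
quantify_stack <- function(stack, n_vertices = 256) {
  stopifnot(inherits(stack, "frame_stack"))
  rbg <- max(stack$radii)
  margin <- rbg + 2
  corners <- cbind(x = c(margin, stack$width - margin,
                         margin, stack$width - margin) + 0.29,
                   y = c(margin, margin,
                         stack$height - margin, stack$height - margin) + 0.43)
  dmin <- apply(corners, 1, function(p)
    min(sqrt((stack$centers[, 1] - p[1])^2 + (stack$centers[, 2] - p[2])^2)))
  bg_center <- corners[which.max(dmin), ]
  if (max(dmin) < rbg + stack$ring_width + rbg)
    stop("no corner far enough from the cells for a background region")
  out <- list()
  for (ci in seq_len(nrow(stack$centers))) {
    cx <- stack$centers[ci, 1]; cy <- stack$centers[ci, 2]
    for (ti in seq_along(stack$times)) {
      r <- stack$radii[ci, ti]
      cell_poly <- disk_polygon(cx, cy, r, n_vertices)
      bg_poly <- disk_polygon(bg_center[1], bg_center[2], r, n_vertices)
      ca_bg <- measure_region(stack$ca[[ti]], bg_poly)
      ca_r <- relative_intensity(measure_region(stack$ca[[ti]], cell_poly),
                                 ca_bg)
      ann <- roi_annulus(disk_polygon(cx, cy, r + stack$ring_width,
                                      n_vertices),
                         cell_poly)
      ups <- annulus_unit_intensity(stack$ps[[ti]], ann)
      ps_bg <- measure_region(stack$ps[[ti]], bg_poly)
      rps <- relative_intensity(ups, ps_bg)
      out[[length(out) + 1]] <- data.frame(
        cell = stack$cell_ids[ci], time_min = stack$times[ti],
        ca_r = ca_r, rps = rps, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Equivalent-disk radius of a pixel area
#'
#' @param area Area in pixels.
#' @return `sqrt(area / pi)`.
#' @export
equivalent_radius <- function(area) sqrt(area / pi)
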