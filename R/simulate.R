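# Synthetic voltage-imaging generator.  Produces movies with known ground
# truth: static neuronal footprints whose brightness is modulated by
# millisecond-scale spike transients and slow subthreshold fluctuations,
# observed through Poisson shot noise (pixel values normalised, scaled to a
# photon budget and used as Poisson means) plus additive Gaussian read
# noise, with negative values truncated to zero.  Optional low-pass
# filtered rigid motion emulates respiration/heartbeat displacement.
#
# Movies are stored as [T, H, W] arrays throughout the package.

#' Simulation parameters
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames.
#' @param frame_rate Acquisition rate in Hz.
#' @param n_neurons Number of neuronal footprints.
#' @param spike_width_ms Full width at half maximum of the spike-evoked
#'   fluorescence transient, in milliseconds (1-9 ms covers fast voltage
#'   indicators).
#' @param spike_rate_hz Mean firing rate per neuron (homogeneous Poisson
#'   with a refractory gap equal to the spike width; the gap is compensated
#'   so the mean rate is exact).
#' @param amplitude_dff Peak |dF/F0| of a single spike.
#' @param subthreshold_sigma Standard deviation of the slow subthreshold
#'   dF/F0 fluctuation (AR(1), ~20 ms correlation time).
#' @param baseline_level Mean intensity scale of the clean movie.
#' @param polarity `"negative_going"` (fluorescence dips at spikes, as for
#'   Voltron-family indicators) or `"positive_going"`.
#' @param poisson_scale Photon budget: the clean movie is normalised by its
#'   maximum and multiplied by this value before Poisson sampling.
#' @param gauss_sigma Standard deviation of the additive Gaussian read
#'   noise (intensity units of the noisy movie).
#' @param bleach_tau Photobleaching time constant in seconds, or `NULL` for
#'   no bleaching.
#' @param motion_sigma_px Standard deviation of the rigid-motion
#'   displacement in pixels (0 = no motion).
#' @param motion_cutoff_hz Low-pass cut-off of the motion trajectory.
#' @param seed Integer seed; every random stage derives its state from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(height = 64L, width = 64L, n_frames = 2000L,
                              frame_rate = 500, n_neurons = 20L,
                              spike_width_ms = 3, spike_rate_hz = 5,
                              amplitude_dff = 0.1, subthreshold_sigma = 0.02,
                              baseline_level = 100, polarity = "negative_going",
                              poisson_scale = 1000, gauss_sigma = 5,
                              bleach_tau = NULL, motion_sigma_px = 0,
                              motion_cutoff_hz = 5, seed = 0L) {
  polarity <- match.arg(polarity, c("negative_going", "positive_going"))
  stopifnot(height > 0, width > 0, n_frames > 0, frame_rate > 0,
            n_neurons >= 0, spike_width_ms > 0, spike_rate_hz >= 0,
            amplitude_dff >= 0, subthreshold_sigma >= 0, baseline_level > 0,
            poisson_scale > 0, gauss_sigma >= 0, motion_sigma_px >= 0)
  if (!is.null(bleach_tau)) stopifnot(bleach_tau > 0)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_frames = as.integer(n_frames), frame_rate = frame_rate,
    n_neurons = as.integer(n_neurons), spike_width_ms = spike_width_ms,
    spike_rate_hz = spike_rate_hz, amplitude_dff = amplitude_dff,
    subthreshold_sigma = subthreshold_sigma, baseline_level = baseline_level,
    polarity = polarity, poisson_scale = poisson_scale,
    gauss_sigma = gauss_sigma, bleach_tau = bleach_tau,
    motion_sigma_px = motion_sigma_px, motion_cutoff_hz = motion_cutoff_hz,
    seed = as.integer(seed)), class = "simulation_config")
}

polarity_sign <- function(polarity) {
  if (polarity == "positive_going") 1 else -1
}

#' Spike transient kernel
#'
#' Instantaneous rise followed by an exponential decay whose full width at
#' half maximum equals `spike_width_ms` (at least one frame).
#'
#' @param spike_width_ms FWHM in milliseconds.
#' @param frame_rate Frames per second.
#' @param amplitude_dff Peak dF/F0 (the kernel's first sample).
#' @return Numeric vector; `kernel[1]` is the spike frame.
#' @export
make_spike_waveform <- function(spike_width_ms, frame_rate, amplitude_dff) {
  stopifnot(spike_width_ms > 0, frame_rate > 0, amplitude_dff >= 0)
  dt_ms <- 1000 / frame_rate
  if (spike_width_ms < dt_ms / 2) {
    warning("spike width shorter than half a frame; using a single-frame ",
            "impulse")
    return(amplitude_dff)
  }
  tau_ms <- spike_width_ms / log(2)
  n <- max(2L, ceiling(6 * tau_ms / dt_ms))
  t_ms <- (seq_len(n) - 1) * dt_ms
  amplitude_dff * exp(-t_ms / tau_ms)
}

#' Generate per-neuron spike trains
#'
#' Homogeneous Poisson process at `spike_rate_hz` per neuron with a
#' refractory gap of one spike width; inter-spike intervals are drawn so
#' that the mean rate stays exactly `spike_rate_hz` despite the gap.
#'
#' @param config A [simulation_config()].
#' @return List of length `n_neurons`; each element an integer vector of
#'   strictly increasing spike frames (1-based).
#' @export
generate_spike_trains <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  wf <- suppressWarnings(
    make_spike_waveform(config$spike_width_ms, config$frame_rate, 1))
  if (length(wf) > config$n_frames)
    stop("degenerate config: movie shorter than one spike duration")
  set.seed(config$seed + 1L)
  r <- config$spike_rate_hz
  t_total <- config$n_frames / config$frame_rate
  refr <- config$spike_width_ms / 1000
  lapply(seq_len(config$n_neurons), function(n) {
    if (r <= 0) return(integer(0))
    if (r * refr >= 1)
      stop("spike_rate_hz too high for the refractory gap")
    r_adj <- r / (1 - r * refr)
    times <- numeric(0)
    t <- stats::rexp(1, r_adj)
    while (t < t_total) {
      times <- c(times, t)
      t <- t + refr + stats::rexp(1, r_adj)
    }
    sort(unique(pmin(config$n_frames, floor(times * config$frame_rate) + 1L)))
  })
}

#' Per-neuron dF/F0 traces
#'
#' Spike deltas convolved with the transient kernel plus a slow AR(1)
#' subthreshold fluctuation.
#'
#' @param config A [simulation_config()].
#' @param spikes Output of [generate_spike_trains()].
#' @return Matrix `[n_neurons, n_frames]` of dF/F0 values (unsigned; the
#'   indicator polarity is applied at render time).
#' @export
make_dff_traces <- function(config, spikes) {
  t_n <- config$n_frames
  kern <- suppressWarnings(make_spike_waveform(
    config$spike_width_ms, config$frame_rate, config$amplitude_dff))
  set.seed(config$seed + 3L)
  rho <- exp(-1 / (0.02 * config$frame_rate))  # ~20 ms correlation time
  out <- matrix(0, max(1L, config$n_neurons), t_n)
  for (n in seq_len(config$n_neurons)) {
    tr <- numeric(t_n)
    s <- spikes[[n]]
    if (length(s)) {
      delta <- numeric(t_n)
      delta[s] <- 1
      full <- numeric(t_n + length(kern) - 1L)
      for (i in seq_along(kern)) full[seq_len(t_n) + i - 1L] <-
          full[seq_len(t_n) + i - 1L] + delta * kern[i]
      tr <- full[seq_len(t_n)]
    }
    if (config$subthreshold_sigma > 0) {
      e <- stats::rnorm(t_n, sd = config$subthreshold_sigma * sqrt(1 - rho^2))
      z <- numeric(t_n)
      z[1] <- stats::rnorm(1, sd = config$subthreshold_sigma)
      for (t in 2:t_n) z[t] <- rho * z[t - 1] + e[t]
      tr <- tr + z
    }
    out[n, ] <- tr
  }
  out[seq_len(config$n_neurons), , drop = FALSE]
}

#' Random neuronal footprints
#'
#' Soft-edged elliptical rings (membrane-bound indicator) with a dim
#' interior fill, at random non-overlapping-ish centres.
#'
#' @param config A [simulation_config()].
#' @return Array `[height, width, n_neurons]`, each map with maximum 1.
#' @export
make_footprints <- function(config) {
  set.seed(config$seed + 2L)
  h <- config$height; w <- config$width; n <- config$n_neurons
  out <- array(0, c(h, w, max(1L, n)))
  centres <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      cand <- c(runif(1, 5, h - 4), runif(1, 5, w - 4))
      if (i == 1 || all(sqrt(rowSums(
        sweep(centres[seq_len(i - 1), , drop = FALSE], 2, cand)^2)) > 7) ||
        try == 200) break
    }
    centres[i, ] <- cand
    r0 <- runif(1, 2.5, 4.5)
    b <- runif(1, 0.7, 1)
    th <- runif(1, 0, pi)
    yy <- matrix(seq_len(h) - cand[1], h, w)
    xx <- matrix(seq_len(w) - cand[2], h, w, byrow = TRUE)
    u <- yy * cos(th) + xx * sin(th)
    v <- (-yy * sin(th) + xx * cos(th)) / b
    d <- sqrt(u^2 + v^2)
    fp <- exp(-((d - r0) / 1.0)^2) + 0.35 * exp(-(d / r0)^2)
    fp[fp < 0.01] <- 0
    out[, , i] <- fp / max(fp)
  }
  out[, , seq_len(n), drop = FALSE]
}

# Smooth background field in [0.1, 0.3] (out-of-focus fluorescence).
make_background <- function(h, w) {
  z <- matrix(stats::rnorm(h * w), h, w)
  hw <- min(8L, (min(h, w) - 1L) %/% 2L)
  k <- stats::dnorm(seq(-hw, hw), sd = 3)
  k <- k / sum(k)
  sm <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, circular = TRUE)))
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  0.1 + 0.2 * sm
}

#' Render the clean movie
#'
#' `clean[t] = baseline_level * bleach(t) * (background + sum_n
#' footprint_n * (1 + sign * dff_n(t)))` with `sign = -1` for
#' negative-going indicators. Negative intensities (possible for large
#' negative-going amplitudes) are clipped to zero with a warning.
#'
#' @param config A [simulation_config()].
#' @param footprints Array `[H, W, n]` of non-negative weight maps.
#' @param spikes Spike trains as from [generate_spike_trains()].
#' @param traces Optional precomputed dF/F0 matrix `[n, T]`; defaults to
#'   [make_dff_traces()] (which also draws the background, so pass traces
#'   explicitly only together with a seeded RNG state).
#' @return List with `video` (`[T, H, W]` clean movie), `traces` and
#'   `background`.
#' @export
render_clean_video <- function(config, footprints, spikes, traces = NULL) {
  if (is.null(traces)) traces <- make_dff_traces(config, spikes)
  h <- config$height; w <- config$width; t_n <- config$n_frames
  bg <- make_background(h, w)  # RNG state follows make_dff_traces
  sign <- polarity_sign(config$polarity)
  fmat <- matrix(footprints, h * w, dim(footprints)[3])
  static <- as.vector(bg) + rowSums(fmat)
  vid <- matrix(static, h * w, t_n) + fmat %*% (sign * traces)
  vid <- vid * config$baseline_level
  if (!is.null(config$bleach_tau)) {
    decay <- exp(-(seq_len(t_n) - 1) /
                   (config$bleach_tau * config$frame_rate))
    vid <- sweep(vid, 2, decay, "*")
  }
  if (any(vid < 0)) {
    warning("negative clean intensities clipped to 0")
    vid[vid < 0] <- 0
  }
  video <- aperm(array(vid, c(h, w, t_n)), c(3, 1, 2))
  list(video = video, traces = traces, background = bg)
}

#' Add Poisson-Gaussian microscope noise
#'
#' The clean movie is normalised by its maximum, scaled by `poisson_scale`
#' and used pixel-wise as the Poisson mean; zero-mean Gaussian noise of
#' standard deviation `gauss_sigma` is added and negative values are
#' truncated to zero.
#'
#' @param clean Non-negative array (any shape).
#' @param poisson_scale Photon budget (default 1000).
#' @param gauss_sigma Read-noise standard deviation (default 5).
#' @param seed Integer seed.
#' @return Noisy array of the same shape, all values >= 0.
#' @export
add_poisson_gaussian_noise <- function(clean, poisson_scale = 1000,
                                       gauss_sigma = 5, seed = 0L) {
  if (any(clean < 0)) stop("clean movie must be non-negative")
  mx <- max(clean)
  if (mx == 0) stop("degenerate input: all-zero clean movie")
  set.seed(seed)
  lam <- poisson_scale * clean / mx
  noisy <- stats::rpois(length(lam), lam) +
    stats::rnorm(length(lam), sd = gauss_sigma)
  noisy <- pmax(noisy, 0)
  dim(noisy) <- dim(clean)
  noisy
}

#' Rigid-motion trajectory
#'
#' Per-axis white Gaussian sequences, low-pass filtered (4th-order
#' Butterworth, zero phase via forward-backward filtering), mean-centred
#' and rescaled to the requested displacement standard deviation.
#'
#' @param n_frames Trajectory length.
#' @param frame_rate Hz.
#' @param sigma_px Sample standard deviation of each axis in pixels.
#' @param cutoff_hz Low-pass cut-off (must be below the Nyquist rate).
#' @param seed Integer seed.
#' @return List with numeric vectors `dx` and `dy` of length `n_frames`.
#' @export
generate_motion_trajectory <- function(n_frames, frame_rate, sigma_px,
                                       cutoff_hz = 5, seed = 0L) {
  stopifnot(cutoff_hz < frame_rate / 2, sigma_px >= 0, n_frames > 0)
  set.seed(seed)
  one_axis <- function() {
    if (sigma_px == 0) return(numeric(n_frames))
    x <- stats::rnorm(n_frames)
    bf <- signal::butter(4, cutoff_hz / (frame_rate / 2))
    xf <- signal::filtfilt(bf, x)
    xf <- xf - mean(xf)
    xf * sigma_px / stats::sd(xf)
  }
  list(dx = one_axis(), dy = one_axis())
}

#' Apply rigid translation to a movie
#'
#' Each frame `t` is shifted by `(dx[t], dy[t])`; pixels sampled outside
#' the field of view replicate the frame edge.
#'
#' @param video `[T, H, W]` array.
#' @param trajectory List with `dx`, `dy` (length `T`).
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return Translated `[T, H, W]` array.
#' @export
apply_rigid_motion <- function(video, trajectory,
                               interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(video)
  if (length(trajectory$dx) != d[1] || length(trajectory$dy) != d[1])
    stop("trajectory length must equal the number of frames")
  if (max(abs(c(trajectory$dx, trajectory$dy))) >= min(d[2], d[3]))
    stop("displacement larger than the field of view")
  out <- video
  bil <- interpolation == "bilinear"
  for (t in seq_len(d[1]))
    out[t, , ] <- cpp_translate(video[t, , ], trajectory$dy[t],
                                trajectory$dx[t], bil)
  out
}

#' Run the full simulation
#'
#' Generates spike trains, footprints and traces, renders the clean movie,
#' applies optional rigid motion and adds Poisson-Gaussian noise.
#'
#' @param config A [simulation_config()].
#' @return A `simulation_bundle`: list with `clean` and `noisy` movies
#'   (`[T, H, W]`), `footprints`, `spikes`, `clean_traces` (`[n, T]`
#'   dF/F0), `background`, `trajectory` (or `NULL`) and `config`.
#' @export
simulate_voltage_movie <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  spikes <- generate_spike_trains(config)
  footprints <- make_footprints(config)
  rend <- render_clean_video(config, footprints, spikes)
  clean <- rend$video
  trajectory <- NULL
  if (config$motion_sigma_px > 0) {
    trajectory <- generate_motion_trajectory(
      config$n_frames, config$frame_rate, config$motion_sigma_px,
      config$motion_cutoff_hz, seed = config$seed + 5L)
    clean <- apply_rigid_motion(clean, trajectory)
  }
  noisy <- add_poisson_gaussian_noise(clean, config$poisson_scale,
                                      config$gauss_sigma,
                                      seed = config$seed + 4L)
  structure(list(clean = clean, noisy = noisy, footprints = footprints,
                 spikes = spikes, clean_traces = rend$traces,
                 background = rend$background, trajectory = trajectory,
                 config = config),
            class = "simulation_bundle")
}

#' @export
print.simulation_bundle <- function(x, ...) {
  d <- dim(x$clean)
  cat(sprintf(paste0("simulation_bundle: %d frames of %dx%d @ %g Hz, ",
                     "%d neurons, spike width %g ms%s\n"),
              d[1], d[2], d[3], x$config$frame_rate, x$config$n_neurons,
              x$config$spike_width_ms,
              if (is.null(x$trajectory)) "" else ", with motion"))
  invisible(x)
}
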