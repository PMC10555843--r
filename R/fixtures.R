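# Frozen desk-scale simulation presets used by examples and tests.

fixture_presets <- function() {
  list(
    spike1ms = simulation_config(spike_width_ms = 1, seed = 101L),
    spike9ms = simulation_config(spike_width_ms = 9, seed = 109L),
    motion = simulation_config(spike_width_ms = 3, motion_sigma_px = 2,
                               seed = 103L),
    bleach = simulation_config(spike_width_ms = 3, bleach_tau = 20,
                               seed = 104L))
}

#' Deterministic simulation fixtures
#'
#' Named desk-scale presets (64 x 64 x 2000 frames at 500 Hz, 20 neurons,
#' Voltron-like negative-going indicator, photon budget 1000, read noise
#' 5): `"spike1ms"` and `"spike9ms"` bracket the spike-width range,
#' `"motion"` adds 2 px low-pass-filtered rigid motion, `"bleach"` adds a
#' 20 s photobleaching decay, and `"structural"` is a synthetic static
#' volume (a z-stack of 3-D filament/blob structures, no temporal
#' dynamics) for the +/-10-slice structural mode. The same name always
#' yields the identical bundle.
#'
#' @param name Preset name.
#' @return A `simulation_bundle` (for `"structural"`, `clean`/`noisy` are
#'   the z-stack with z mapped to the time axis and all spike fields
#'   empty).
#' @export
make_fixture <- function(name) {
  presets <- fixture_presets()
  if (identical(name, "structural")) return(structural_fixture())
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(c(names(presets), "structural"), collapse = ", "))
  simulate_voltage_movie(presets[[name]])
}

# Static volume: soft 3-D blobs and curved filaments, Poisson-Gaussian
# noise, z treated as time.
structural_fixture <- function() {
  nz <- 64L; h <- 64L; w <- 64L
  set.seed(77L)
  vol <- array(0, c(nz, h, w))
  zz <- seq_len(nz)
  for (b in 1:12) {
    c0 <- c(runif(1, 8, nz - 8), runif(1, 8, h - 8), runif(1, 8, w - 8))
    s <- runif(3, 2, 5)
    dz2 <- ((zz - c0[1]) / s[1])^2
    dy2 <- ((seq_len(h) - c0[2]) / s[2])^2
    dx2 <- ((seq_len(w) - c0[3]) / s[3])^2
    g <- outer(outer(dz2, dy2, "+"), dx2, "+")
    vol <- vol + runif(1, 0.5, 1) * exp(-g / 2)
  }
  for (f in 1:4) {  # curved filaments drifting through z
    y0 <- runif(1, 10, h - 10); x0 <- runif(1, 10, w - 10)
    ay <- runif(1, -0.4, 0.4); ax <- runif(1, -0.4, 0.4)
    py <- runif(1, 0.05, 0.15); amp <- runif(1, 3, 8)
    for (z in zz) {
      yc <- y0 + ay * z + amp * sin(py * z)
      xc <- x0 + ax * z
      dy2 <- ((seq_len(h) - yc) / 1.5)^2
      dx2 <- ((seq_len(w) - xc) / 1.5)^2
      vol[z, , ] <- vol[z, , ] + 0.8 * exp(-outer(dy2, dx2, "+") / 2)
    }
  }
  clean <- 100 * (0.1 + vol)
  cfg <- simulation_config(height = h, width = w, n_frames = nz,
                           frame_rate = 1, n_neurons = 0L,
                           spike_rate_hz = 0, subthreshold_sigma = 0,
                           seed = 77L)
  noisy <- add_poisson_gaussian_noise(clean, cfg$poisson_scale,
                                      cfg$gauss_sigma, seed = 78L)
  structure(list(clean = clean, noisy = noisy,
                 footprints = array(0, c(h, w, 0)), spikes = list(),
                 clean_traces = matrix(0, 0, nz), background = NULL,
                 trajectory = NULL, config = cfg),
            class = "simulation_bundle")
}
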