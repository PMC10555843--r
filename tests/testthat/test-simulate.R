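# Simulator: spike statistics, waveform geometry, noise moments, motion.

test_that("spike waveform has the requested FWHM and peak", {
  # 2 ms at 500 Hz: above-half-max samples span exactly 1 frame
  k <- make_spike_waveform(2, 500, 0.1)
  expect_equal(max(k), 0.1)
  expect_equal(which.max(k), 1L)
  expect_equal(sum(k > 0.05), 1L)
  # 9 ms at 500 Hz: 4-5 frames above half maximum
  k9 <- make_spike_waveform(9, 500, 0.1)
  expect_true(sum(k9 > 0.05) %in% 4:5)
  expect_true(all(diff(k9) < 0))  # monotone decay after instant rise
  expect_identical(make_spike_waveform(3, 500, 0), rep(0, length(
    make_spike_waveform(3, 500, 1))))
  expect_warning(make_spike_waveform(0.5, 500, 0.1), "impulse")
})

test_that("spike trains follow the requested Poisson rate", {
  cfg <- simulation_config(n_frames = 5000L, frame_rate = 500,
                           n_neurons = 100L, spike_rate_hz = 5,
                           spike_width_ms = 3, seed = 42L)
  trains <- generate_spike_trains(cfg)
  expect_length(trains, 100)
  counts <- vapply(trains, length, integer(1))
  # 5 Hz x 10 s = 50 expected; refractory gap is rate-compensated.
  # Standard error of the mean over 100 neurons ~ sqrt(50)/10.
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50) / sqrt(100))
  for (tr in trains[1:10]) {
    expect_true(all(diff(tr) > 0))
    expect_true(all(tr >= 1 & tr <= cfg$n_frames))
  }
  # zero rate: empty trains
  cfg0 <- simulation_config(spike_rate_hz = 0)
  expect_true(all(lengths(generate_spike_trains(cfg0)) == 0))
  # determinism
  expect_identical(trains, generate_spike_trains(cfg))
})

test_that("degenerate configurations are rejected", {
  cfg <- simulation_config(n_frames = 5L, spike_width_ms = 9,
                           frame_rate = 500)
  expect_error(generate_spike_trains(cfg), "degenerate")
})

test_that("clean rendering follows the footprint/trace model", {
  cfg <- simulation_config(height = 24L, width = 24L, n_frames = 50L,
                           n_neurons = 2L, subthreshold_sigma = 0,
                           polarity = "positive_going", seed = 1L)
  spikes <- generate_spike_trains(cfg)
  fp <- make_footprints(cfg)
  rend <- render_clean_video(cfg, fp, spikes)
  expect_equal(dim(rend$video), c(50, 24, 24))
  expect_true(all(rend$video >= 0))
  # conservation: pixel sums reconstructed from footprints and traces
  fsum <- colSums(matrix(fp, 24 * 24, 2))
  expected <- cfg$baseline_level *
    (sum(rend$background) + sum(fsum) +
       as.numeric(t(fsum) %*% rend$traces))
  expect_equal(apply(rend$video, 1, sum), expected, tolerance = 1e-12)
  # no neurons: every frame identical background
  cfg0 <- simulation_config(height = 16L, width = 16L, n_frames = 5L,
                            n_neurons = 0L, seed = 2L)
  r0 <- render_clean_video(cfg0, make_footprints(cfg0) * 0,
                           generate_spike_trains(cfg0))
  expect_equal(r0$video[1, , ], r0$video[5, , ])
})

test_that("polarity flips the spike direction of the rendered trace", {
  base <- list(height = 20L, width = 20L, n_frames = 200L, n_neurons = 1L,
               spike_rate_hz = 10, subthreshold_sigma = 0,
               amplitude_dff = 0.1, seed = 3L)
  neg <- do.call(simulation_config, c(base, polarity = "negative_going"))
  pos <- do.call(simulation_config, c(base, polarity = "positive_going"))
  sp <- generate_spike_trains(neg)
  fp <- make_footprints(neg)
  rn <- render_clean_video(neg, fp, sp)
  rp <- render_clean_video(pos, fp, sp)
  s <- sp[[1]][1]
  px <- which(fp[, , 1] == max(fp[, , 1]), arr.ind = TRUE)[1, ]
  expect_lt(rn$video[s, px[1], px[2]], rn$video[max(1, s - 5), px[1], px[2]])
  expect_gt(rp$video[s, px[1], px[2]], rp$video[max(1, s - 5), px[1], px[2]])
  # positive-going spike peak ~ amplitude_dff at the footprint maximum
  trace_peak <- max(rp$video[, px[1], px[2]]) /
    rp$video[max(1, s - 5), px[1], px[2]] - 1
  expect_gt(trace_peak, 0.05)
})

test_that("noise moments match the Poisson-Gaussian model", {
  # constant bright region: mean ~ poisson_scale, var ~ poisson_scale
  clean <- array(1, c(50, 40, 40))
  noisy <- add_poisson_gaussian_noise(clean, 1000, 0, seed = 1L)
  n <- length(noisy)
  expect_lt(abs(mean(noisy) - 1000), 5 * sqrt(1000 / n))
  expect_lt(abs(var(as.vector(noisy)) - 1000),
            5 * 1000 * sqrt(2 / (n - 1)))
  expect_true(all(noisy >= 0))
  # zero region with Gaussian noise: rectified-Gaussian mean sigma/sqrt(2 pi)
  clean2 <- array(0, c(50, 40, 40))
  clean2[1] <- 1  # keep the maximum finite and positive
  noisy2 <- add_poisson_gaussian_noise(clean2, 1, 5, seed = 2L)
  zeros <- noisy2[-1]
  se <- 5 / sqrt(length(zeros))  # conservative SE of the rectified mean
  expect_lt(abs(mean(zeros) - 5 / sqrt(2 * pi)), 5 * se)
  expect_error(add_poisson_gaussian_noise(clean * 0, 1000, 5),
               "all-zero")
  # determinism
  expect_identical(noisy, add_poisson_gaussian_noise(clean, 1000, 0,
                                                     seed = 1L))
})

test_that("motion trajectory is zero-mean, sigma-scaled and low-passed", {
  tr <- generate_motion_trajectory(4000, 500, sigma_px = 2, cutoff_hz = 5,
                                   seed = 1L)
  expect_equal(sd(tr$dx), 2, tolerance = 1e-10)
  expect_lt(abs(mean(tr$dx)), 1e-8)
  # spectral check: power above 1.5 x cutoff at least 20 dB below passband
  ps <- function(v) {
    sp <- Mod(stats::fft(v))^2
    f <- (seq_along(v) - 1) / length(v) * 500
    list(f = f[1:(length(v) / 2)], p = sp[1:(length(v) / 2)])
  }
  s <- ps(tr$dx)
  pass <- mean(s$p[s$f <= 5])
  stopb <- mean(s$p[s$f >= 7.5])
  expect_gt(10 * log10(pass / stopb), 20)
  # zero sigma: all-zero trajectory
  tr0 <- generate_motion_trajectory(100, 500, 0, seed = 2L)
  expect_identical(tr0$dx, numeric(100))
  expect_error(generate_motion_trajectory(100, 8, 1, cutoff_hz = 5))
})

test_that("rigid motion equals an array roll for integer shifts", {
  set.seed(9)
  video <- array(rnorm(3 * 10 * 12), c(3, 10, 12))
  tr <- list(dx = c(0, 2, -1), dy = c(0, 1, 3))
  out <- apply_rigid_motion(video, tr, "nearest")
  expect_identical(out[1, , ], video[1, , ])
  # frame 2: shift rows by +1 (dy), cols by +2 (dx), edge-replicated
  f2 <- video[2, , ]
  roll <- f2[c(1, 1:9), c(1, 1, 1:10)]
  expect_identical(out[2, , ], roll)
  # round trip of an interior crop
  fwd <- apply_rigid_motion(video, list(dx = c(3, 3, 3), dy = c(2, 2, 2)),
                            "nearest")
  back <- apply_rigid_motion(fwd, list(dx = -c(3, 3, 3), dy = -c(2, 2, 2)),
                             "nearest")
  expect_identical(back[, 3:8, 4:9], video[, 3:8, 4:9])
  expect_error(apply_rigid_motion(video, list(dx = c(0, 0, 99),
                                              dy = c(0, 0, 0))),
               "larger")
})

test_that("the full simulation is reproducible and self-consistent", {
  cfg <- simulation_config(height = 32L, width = 32L, n_frames = 200L,
                           n_neurons = 5L, seed = 11L)
  b1 <- simulate_voltage_movie(cfg)
  b2 <- simulate_voltage_movie(cfg)
  expect_identical(b1$noisy, b2$noisy)
  expect_identical(b1$clean_traces, b2$clean_traces)
  expect_true(all(b1$clean >= 0) && all(b1$noisy >= 0))
  expect_identical(dim(b1$clean), dim(b1$noisy))
  # noisy movie is noisy but finite: PSNR below 40 dB on the photon scale
  scale <- cfg$poisson_scale / max(b1$clean)
  p <- psnr(b1$noisy, b1$clean * scale)
  expect_true(is.finite(p) && p < 40)
  # motion variant carries its trajectory and stays non-negative
  cfgm <- simulation_config(height = 32L, width = 32L, n_frames = 100L,
                            n_neurons = 3L, motion_sigma_px = 1.5,
                            seed = 12L)
  bm <- simulate_voltage_movie(cfgm)
  expect_length(bm$trajectory$dx, 100)
  expect_true(all(bm$noisy >= 0))
  # bleaching decays the frame sums
  cfgb <- simulation_config(height = 32L, width = 32L, n_frames = 400L,
                            n_neurons = 3L, bleach_tau = 0.2, seed = 13L)
  bb <- simulate_voltage_movie(cfgb)
  sums <- apply(bb$clean, 1, sum)
  expect_lt(sums[400], 0.7 * sums[1])
})
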