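full_band_cube <- function(echo) {
  segment_bandwidth(echo, segmentation_params(echo$sweep$M, 1))
}

test_that("IFFT to range localizes a static scatterer and inverts exactly", {
  # single scatterer at 3 m on the reference frequency grid: bin spacing
  # ~0.0299 m, peak expected at the bin nearest 3 m
  sw <- reference_sweep()
  sw <- sweep_config(sw$f0, sw$delta_f, sw$M, sw$Ts, N = 4)
  echo <- simulate_static_echo(
    sw, clutter_scene(data.frame(range = 3, reflectivity = 1 + 0i)), seed = 1)
  rt <- ifft_to_range(full_band_cube(echo))
  peak_bin <- which.max(Mod(rt$data[1, , 1]))
  expect_lt(abs(rt$range_axis[peak_bin] - 3), sw$unambiguous_range / sw$M)

  # all-ones spectrum -> impulse at range bin 0
  ones <- echo_matrix(matrix(1 + 0i, 32, 3),
                      sweep_config(1e9, 10e6, 32, 0.01, 3))
  rt1 <- ifft_to_range(full_band_cube(ones))
  expect_equal(Mod(rt1$data[1, 1, 1]), 1)
  expect_lt(max(Mod(rt1$data[1, -1, 1])), 1e-13)

  # transform identity fft(ifft(X)) = X
  set.seed(3)
  x <- matrix(complex(real = rnorm(96), imaginary = rnorm(96)), 16, 6)
  rt2 <- ifft_to_range(full_band_cube(
    echo_matrix(x, sweep_config(1e9, 10e6, 16, 0.01, 6))))
  back <- stats::mvfft(rt2$data[1, , ])
  expect_lt(max(Mod(back - x)), 1e-12)
})

rt_from_series <- function(x, Ts = 0.005) {
  structure(list(data = array(as.complex(x), dim = c(1L, 1L, length(x))),
                 range_axis = 0, Ts = Ts, sweep = NULL, subband_count = 1L),
            class = "range_time_cube")
}

test_that("background removal subtracts the static component", {
  # mean subtraction arithmetic
  rt <- rt_from_series(c(1, 2, 3, 4))
  out <- remove_background(rt, "mean_subtraction")
  expect_equal(as.numeric(Re(out$data[1, 1, ])), c(-1.5, -0.5, 0.5, 1.5))

  # a constant series is its own background in either mode
  const <- rt_from_series(rep(5 + 2i, 400))
  expect_true(all(remove_background(const, "mean_subtraction")$data == 0))
  expect_true(all(Mod(remove_background(const, "moving_average", 160)$data)
                  < 1e-12))

  # moving-average mode passes a breathing-band sinusoid nearly untouched
  # (slow-time rate chosen so 0.2 Hz sits above the filter's ~1/window
  # highpass corner)
  tt <- (0:2000) * 0.05
  sig <- sin(2 * pi * 0.2 * tt)
  out2 <- remove_background(rt_from_series(sig + 5, Ts = 0.05),
                            "moving_average", 160)
  expect_gt(stats::cor(Re(out2$data[1, 1, ]), sig), 0.99)

  # series shorter than the filter falls back with a warning
  expect_warning(remove_background(rt_from_series(1:10), "moving_average", 160),
                 "mean subtraction")
})

test_that("range resampling block-averages with a trailing partial block", {
  rt3 <- structure(list(data = array(as.complex(c(2, 4, 6)), c(1L, 3L, 1L)),
                        range_axis = c(0, 1, 2), Ts = 1, sweep = NULL,
                        subband_count = 1L), class = "range_time_cube")
  expect_equal(as.complex(range_average_resample(rt3, 3)$data), 4 + 0i)
  expect_identical(range_average_resample(rt3, 1), rt3)

  big <- structure(list(data = array(1 + 0i, c(1L, 874L, 2L)),
                        range_axis = seq(0, 30, length.out = 874), Ts = 1,
                        sweep = NULL, subband_count = 1L),
                   class = "range_time_cube")
  expect_equal(dim(range_average_resample(big, 10)$data)[2], 88L)

  # partial block is averaged as-is
  rt5 <- structure(list(data = array(as.complex(1:5), c(1L, 5L, 1L)),
                        range_axis = 0:4, Ts = 1, sweep = NULL,
                        subband_count = 1L), class = "range_time_cube")
  out <- range_average_resample(rt5, 3)
  expect_equal(as.complex(out$data), c(2, 4.5) + 0i)
})

test_that("power normalization bounds each slow-time series by unit modulus", {
  rt <- rt_from_series(c(0, 3, -3))
  expect_equal(as.numeric(Re(power_normalize(rt)$data)), c(0, 1, -1))

  zeros <- rt_from_series(rep(0, 8))
  out <- power_normalize(zeros)
  expect_true(all(out$data == 0))
  expect_false(any(is.nan(Re(out$data))))

  set.seed(9)
  arr <- array(complex(real = rnorm(120), imaginary = rnorm(120)),
               c(2L, 3L, 20L))
  rnd <- structure(list(data = arr, range_axis = 0:2, Ts = 1, sweep = NULL,
                        subband_count = 2L), class = "range_time_cube")
  mx <- apply(Mod(power_normalize(rnd)$data), c(1, 2), max)
  expect_equal(unname(mx), matrix(1, 2, 3))
})

tone_gain <- function(f, Ts = 0.005, n = 2001, cutoff = 0.5, order = 321) {
  tt <- (seq_len(n) - 1) * Ts
  out <- lowpass_breath(rt_from_series(exp(2i * pi * f * tt), Ts),
                        cutoff, order)
  # steady-state amplitude away from the startup/teardown transients
  max(Mod(out$data[1, 1, 400:1600]))
}

test_that("breathing low-pass keeps the sub-hertz band and rejects above", {
  expect_equal(tone_gain(0), 1, tolerance = 1e-6)     # unit DC gain
  g02 <- tone_gain(0.2)
  expect_gte(g02, 0.9)                                 # passband
  expect_lte(g02, 1.0 + 1e-6)
  expect_lt(20 * log10(tone_gain(2)), -20)             # stopband, dB
  expect_lt(tone_gain(5), 0.1)
  expect_warning(lowpass_breath(rt_from_series(rep(1, 100)), 0.5, 321),
                 "skipped")
  expect_error(lowpass_breath(rt_from_series(rep(1, 400), Ts = 2), 0.5, 321),
               class = "sfcw_validation_error")       # cutoff above Nyquist
})

test_that("slow-time FFT places a tone in the right frequency bin", {
  tt <- (0:2000) * 0.005
  fcube <- fft_on_time(rt_from_series(exp(2i * pi * 0.2 * tt)))
  expect_equal(diff(fcube$freq_axis[1:2]), 1 / (2001 * 0.005))
  expect_equal(fcube$freq_axis[which.max(Mod(fcube$data[1, 1, ]))], 0.2,
               tolerance = diff(fcube$freq_axis[1:2]))

  # constant input concentrates at DC only
  fc0 <- fft_on_time(rt_from_series(rep(1 + 0i, 64)))
  expect_lt(max(Mod(fc0$data[1, 1, -1])), 1e-12)

  # linearity
  set.seed(11)
  a <- rnorm(64) + 1i * rnorm(64)
  b <- rnorm(64) + 1i * rnorm(64)
  fa <- fft_on_time(rt_from_series(a))$data
  fb <- fft_on_time(rt_from_series(b))$data
  fab <- fft_on_time(rt_from_series(3 * a - 2i * b))$data
  expect_lt(max(Mod(fab - (3 * fa - 2i * fb))), 1e-10)
})

test_that("sub-band averaging is a complex or magnitude mean by stage", {
  arr <- array(0 + 0i, c(2L, 1L, 4L))
  arr[1, 1, ] <- c(1, 1i, -1, 3)
  arr[2, 1, ] <- c(3, 1i, 1, -3)
  rt <- structure(list(data = arr, range_axis = 0, Ts = 1, sweep = NULL,
                       subband_count = 2L), class = "range_time_cube")
  out <- average_subbands(rt, "AaT")
  expect_equal(as.complex(out$data[1, 1, ]), c(2, 1i, 0, 0))

  fc <- structure(list(data = arr, range_axis = 0, freq_axis = 0:3,
                       subband_count = 2L), class = "freq_cube")
  # AaA averages magnitudes: |1|,|3| -> 2 in bin 1; |-1|,|1| -> 1 in bin 3
  aaa <- average_subbands(fc, "AaA")
  expect_equal(Re(aaa$data[1, 1, ]), c(2, 1, 1, 3))
  # phase-coherent vs incoherent averaging of exp(+-j pi/2)
  ph <- array(c(exp(1i * pi / 2), exp(-1i * pi / 2)), c(2L, 1L, 1L))
  fc2 <- structure(list(data = ph, range_axis = 0, freq_axis = 0,
                        subband_count = 2L), class = "freq_cube")
  expect_equal(Mod(average_subbands(fc2, "AaF")$data[1, 1, 1]), 0)
  expect_equal(Mod(average_subbands(fc2, "AaA")$data[1, 1, 1]), 1)

  # identical slices: mean equals one slice
  same <- rt; same$data[2, , ] <- same$data[1, , ]
  expect_equal(average_subbands(same, "AoR")$data[1, , ],
               same$data[1, , ])

  expect_error(average_subbands(rt, "AaF"), class = "sfcw_validation_error")
})

test_that("the orchestrated pipeline matches the chained stage operations", {
  sw <- small_sweep()
  echo <- simulate_breathing_echo(sw, breathing_target(),
                                  clutter_scene(NULL, "random", 0.05),
                                  seed = 2)
  seg <- segmentation_params(L = 20, delta_l = 10)
  ref <- segment_bandwidth(echo, seg)
  ref <- ifft_to_range(ref)
  ref <- range_average_resample(ref, 5)
  ref <- remove_background(ref, "moving_average", 160)
  ref <- power_normalize(ref)
  ref <- lowpass_breath(ref, 0.5, 321)
  ref <- average_subbands(ref, "AaT")
  ref <- fft_on_time(ref)
  ref_mag <- Mod(matrix(ref$data[1, , ], dim(ref$data)[2], dim(ref$data)[3]))

  em <- run_enhancement(echo, seg,
                        pipeline_params("AaT", range_resample_factor = 5))
  expect_equal(em$data, ref_mag, tolerance = 1e-10)
  expect_equal(em$range_axis, ref$range_axis)
  expect_equal(em$freq_axis, ref$freq_axis)
})

test_that("degenerate inputs and single-band equivalences hold exactly", {
  sw <- small_sweep()
  zero <- echo_matrix(matrix(0 + 0i, sw$M, sw$N), sw)
  em0 <- run_enhancement(zero, segmentation_params(20, 10), pipeline_params())
  expect_true(all(em0$data == 0))

  # with a single full-band window every averaging case equals NON bit for bit
  echo <- simulate_breathing_echo(sw, breathing_target(),
                                  clutter_scene(NULL, "random", 0.1), seed = 6)
  segM <- segmentation_params(sw$M, 10)
  non <- run_enhancement(echo, segM, pipeline_params("NON"))
  for (stage in c("AoF", "AoR", "AaT", "AaF", "AaA")) {
    em <- run_enhancement(echo, segM, pipeline_params(stage))
    expect_identical(em$data, non$data, info = stage)
  }
})

test_that("enhancement recovers the breathing frequency end to end", {
  sw <- small_sweep(N = 2001)
  echo <- simulate_breathing_echo(sw, breathing_target(), seed = 7)
  em <- run_enhancement(echo, segmentation_params(20, 10),
                        pipeline_params("AaT"))
  pk <- enhanced_peak(em)
  expect_equal(pk$frequency, 0.2, tolerance = diff(em$freq_axis[1:2]))
})

test_that("power-range plot normalizes to 0 dB and reads the SNCR floor", {
  em <- enhanced_matrix(rbind(c(1, 0.5), c(10, 2), c(100, 7)),
                        range_axis = c(0, 1, 2), freq_axis = c(0.1, 0.2),
                        band = c(0, 0.5))
  pl <- power_range_plot(em, guard_bins = 0L)
  expect_equal(pl$values, c(-40, -20, 0))
  expect_equal(pl$peak_range, 2)

  # single nonzero entry: 0 dB there, clamp floor elsewhere
  one <- enhanced_matrix(diag(c(0, 1, 0)), 0:2, c(0.1, 0.2, 0.3), c(0, 0.5))
  pl1 <- power_range_plot(one, guard_bins = 0L)
  expect_equal(pl1$values, c(-120, 0, -120))

  # synthetic floor drawn in [-55, -45] dB: estimate lands in [45, 55]
  set.seed(21)
  vals <- runif(101, -55, -45)
  vals[51] <- 0
  plot <- structure(list(values = vals, range_axis = seq(0, 15, length.out = 101),
                         peak_range = 7.5, peak_bin = 51L, sncr = NA_real_),
                    class = "power_range_plot")
  est <- estimate_sncr(plot, guard_bins = 3L)
  expect_gte(est, 45); expect_lte(est, 55)

  flat <- structure(list(values = rep(0, 31), range_axis = 1:31,
                         peak_range = 1, peak_bin = 1L, sncr = NA_real_),
                    class = "power_range_plot")
  expect_equal(estimate_sncr(flat, 3L), 0)
  expect_error(estimate_sncr(flat, 20L), class = "sfcw_validation_error")

  expect_error(power_range_plot(enhanced_matrix(matrix(0, 2, 2), 0:1,
                                                c(0.1, 0.2), c(0, 0.5))),
               class = "sfcw_validation_error")
})

test_that("sub-band averaging improves the SNCR over the unsegmented flow", {
  ens <- breathing_ensemble()
  aat <- vapply(ens, `[[`, numeric(1), "sncr_aat")
  non <- vapply(ens, `[[`, numeric(1), "sncr_non")
  expect_gt(mean(aat - non), 0)            # paired one-sided comparison
  expect_gte(mean(aat > non), 0.9)
})

test_that("the pipeline recovers range and breathing frequency under
           moderate clutter and noise", {
  ens <- breathing_ensemble()
  ok_r <- vapply(ens, function(e) abs(e$peak$range - 3) <= e$range_bin,
                 logical(1))
  ok_f <- vapply(ens, function(e) abs(e$peak$frequency - 0.2) <= e$freq_bin,
                 logical(1))
  expect_gte(mean(ok_r), 0.9)
  expect_gte(mean(ok_f), 0.9)
})

test_that("peak width does not grow as the window length increases", {
  width6 <- function(pl) {
    v <- pl$values
    lo <- pl$peak_bin; while (lo > 1 && v[lo - 1] > -6) lo <- lo - 1
    hi <- pl$peak_bin; while (hi < length(v) && v[hi + 1] > -6) hi <- hi + 1
    hi - lo + 1
  }
  echo <- simulate_breathing_echo(reference_sweep(), breathing_target(),
                                  seed = 5)
  widths <- vapply(c(10, 50, 100), function(L) {
    width6(power_range_plot(run_enhancement(echo, segmentation_params(L, 10),
                                            pipeline_params("AaT"))))
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("the short-record mode still localizes the target in range", {
  echo <- generate_fixture("short_2s", seed = 3)
  expect_equal(ncol(echo$data), 401L)  # ceiling(2 s / 5 ms) + 1 sweeps
  em <- suppressWarnings(
    run_enhancement(echo, segmentation_params(100, 10),
                    pipeline_params("AaT", short_mode = TRUE)))
  pk <- enhanced_peak(em)
  expect_lt(abs(pk$range - 3), 2 * diff(em$range_axis[1:2]))
})
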