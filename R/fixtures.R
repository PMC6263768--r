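# Seeded fixture generator: the canonical input source for tests and
# examples, since no measured radar data are distributed. The "moderate"
# clutter-and-noise condition used by all statistical checks is defined once,
# here.

# Moderate clutter/noise condition: five static scatterers uniformly placed
# over the usable range with circular-Gaussian reflectivities of mean
# magnitude 1.5 (stronger than the unit-reflectivity target), a random
# per-frequency spectrum profile, and additive complex noise of sigma 0.1
# per sample.
#' @noRd
moderate_scene <- function(sweep, seed) {
  with_local_seed(seed, {
    n_scatter <- 5L
    s <- sqrt(2 / pi)  # unit mean magnitude for circular Gaussian
    scat <- data.frame(
      range = stats::runif(n_scatter, 1, 0.9 * sweep$unambiguous_range),
      reflectivity = 1.5 * complex(real = stats::rnorm(n_scatter, sd = s),
                                   imaginary = stats::rnorm(n_scatter, sd = s)))
    clutter_scene(scat, spectrum_profile = "random", noise_sigma = 0.1)
  })
}

# Breathing target (flat spectrum, no noise) superposed on frequency-random
# static clutter with receiver noise; the echo model is linear in the
# scatterer sum, so the composition is itself a valid scene.
#' @noRd
cluttered_breathing <- function(sweep, target, seed) {
  sim_seed <- as.integer(seed) + 1L
  breath <- simulate_breathing_echo(sweep, target, clutter_scene(),
                                    seed = sim_seed)
  clutter <- simulate_static_echo(sweep, moderate_scene(sweep, seed),
                                  seed = sim_seed)
  echo_matrix(breath$data + clutter$data, sweep)
}

#' Generate a named simulation fixture
#'
#' Deterministic, seeded scenes covering the situations the method is meant
#' to handle:
#' \describe{
#'   \item{`breathing_clean`}{The reference breathing target in an empty
#'     scene with a flat spectrum and no noise.}
#'   \item{`breathing_cluttered`}{The same target plus the moderate
#'     clutter/noise condition (five static scatterers with mean reflectivity
#'     magnitude 1.5, random spectrum profile, noise sigma 0.1).}
#'   \item{`clutter_only`}{The moderate clutter/noise scene with no target —
#'     the false-alarm case.}
#'   \item{`short_2s`}{`breathing_cluttered` truncated to the first
#'     `ceiling(2 / Ts) + 1` slow-time samples — the fast-detection case.}
#'   \item{`two_tone`}{A real range x slow-time matrix holding two spatial
#'     tones (range-frequency components), for exercising the range-domain
#'     segmentation variant.}
#' }
#'
#' Cluttered profiles are composed by superposition: the breathing target is
#' simulated with a flat spectrum (the transmit spectrum is set uniformly, as
#' in the reference simulation) and the static clutter with a random
#' per-frequency spectrum plus receiver noise, and the two echo matrices are
#' summed. Applying a zero-mean frequency-random gain to the target path
#' would scramble its range compression, which is not what the clutter
#' randomness models: it stands for the unknown distortion of the
#' clutter-path returns.
#'
#' @param profile One of the profile names above.
#' @param seed Integer seed; the scene layout uses `seed` and the
#'   simulator's spectrum/noise draws use `seed + 1`.
#' @param sweep A [sweep_config()]; defaults to the reference sweep of
#'   [default_run_config()] (501 x 2001). Smaller sweeps give faster,
#'   statistically equivalent fixtures.
#' @param target A [breathing_target()] for the breathing profiles.
#' @return An [echo_matrix()], or a real matrix for `"two_tone"`.
#' @export
generate_fixture <- function(profile = c("breathing_clean",
                                         "breathing_cluttered",
                                         "clutter_only", "short_2s",
                                         "two_tone"),
                             seed = 1L, sweep = NULL,
                             target = breathing_target()) {
  profile <- match.arg(profile)
  if (is.null(sweep)) {
    sw <- default_run_config()$sweep
    sweep <- sweep_config(sw$f0, sw$delta_f, sw$M, sw$Ts, sw$N)
  }
  sim_seed <- as.integer(seed) + 1L
  switch(profile,
    breathing_clean = simulate_breathing_echo(sweep, target, clutter_scene(),
                                              seed = sim_seed),
    breathing_cluttered = cluttered_breathing(sweep, target, seed),
    clutter_only = simulate_static_echo(sweep, moderate_scene(sweep, seed),
                                        seed = sim_seed),
    short_2s = {
      n_short <- as.integer(ceiling(2 / sweep$Ts) + 1)
      short_sweep <- sweep_config(sweep$f0, sweep$delta_f, sweep$M,
                                  sweep$Ts, n_short)
      cluttered_breathing(short_sweep, target, seed)
    },
    two_tone = {
      M <- 128L; N <- 64L
      p <- seq_len(M) - 1
      sig <- cos(2 * pi * 10 * p / M) + cos(2 * pi * 40 * p / M)
      matrix(sig, M, N)
    })
}
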