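# Seeded SFCW echo simulator: a sinusoidally breathing point target, static
# clutter with a frequency-random spectrum, and additive receiver noise.

# Materialize the scene's spectrum profile for a given sweep. Consumes RNG
# draws only for the "random" profile; callers seed via with_local_seed().
#' @noRd
resolve_spectrum_profile <- function(scene, sweep) {
  sp <- scene$spectrum_profile
  if (is.character(sp)) {
    if (sp == "flat") return(rep(1 + 0i, sweep$M))
    # circular complex Gaussian gains, unit mean magnitude (Rayleigh mean 1)
    s <- sqrt(2 / pi)
    return(complex(real = stats::rnorm(sweep$M, sd = s),
                   imaginary = stats::rnorm(sweep$M, sd = s)))
  }
  if (length(sp) != sweep$M)
    stop_dimension(sprintf("spectrum_profile has length %d but sweep has M=%d",
                           length(sp), sweep$M))
  as.complex(sp)
}

# Static-scatterer contribution per entry: sum_i alpha_i exp(-j 2 pi f tau_i),
# constant along slow time.
#' @noRd
static_column <- function(scene, freqs) {
  col <- rep(0 + 0i, length(freqs))
  sc <- scene$static_scatterers
  if (!is.null(sc) && nrow(sc) > 0) {
    for (i in seq_len(nrow(sc))) {
      tau_i <- 2 * sc$range[i] / C_LIGHT
      col <- col + as.complex(sc$reflectivity[i]) * exp(-2i * pi * freqs * tau_i)
    }
  }
  col
}

#' @noRd
draw_noise <- function(M, N, sigma) {
  if (sigma <= 0) return(matrix(0 + 0i, M, N))
  matrix(complex(real = stats::rnorm(M * N, sd = sigma / sqrt(2)),
                 imaginary = stats::rnorm(M * N, sd = sigma / sqrt(2))), M, N)
}

#' Simulate the SFCW echo of a breathing target in a cluttered scene
#'
#' Builds the complex operational-frequency x slow-time echo matrix entry by
#' entry from the stepped-frequency echo model: at frequency
#' `f_m = f0 + m * delta_f` and slow time `t_n = n * Ts`,
#'
#' \deqn{R[m,n] = S[m] \left( \alpha e^{-j 2\pi f_m \tau_0}
#'   e^{-j 2\pi f_m \Delta\tau \sin(2\pi f_b t_n)} +
#'   \sum_i \alpha_i e^{-j 2\pi f_m \tau_i} \right) + w[m,n]}
#'
#' with `tau0 = 2 d0 / c`, `delta_tau = 2 delta_d / c`, static-scatterer
#' delays `tau_i = 2 r_i / c`, spectrum gains `S[m]` from the scene, and
#' complex Gaussian noise `w`. The breathing displacement phase-modulates
#' every operational frequency coherently, which is what the downstream
#' sub-band averaging exploits.
#'
#' @param sweep A [sweep_config()].
#' @param target A [breathing_target()]; its nominal range must lie inside
#'   the sweep's unambiguous range.
#' @param scene A [clutter_scene()]; defaults to empty, flat spectrum,
#'   no noise.
#' @param seed Integer seed controlling the random spectrum profile and the
#'   noise; identical seeds give bit-identical matrices.
#'
#' @return An [echo_matrix()].
#' @examples
#' sw <- sweep_config(500e6, 10e6, M = 64, Ts = 0.005, N = 128)
#' em <- simulate_breathing_echo(sw, breathing_target(), seed = 1)
#' dim(em$data)
#' @export
simulate_breathing_echo <- function(sweep, target,
                                    scene = clutter_scene(), seed = 1L) {
  stopifnot(inherits(sweep, "sweep_config"), inherits(target, "breathing_target"),
            inherits(scene, "clutter_scene"))
  if (target$d0 >= sweep$unambiguous_range)
    stop_validation(sprintf("target d0 = %g m is outside the unambiguous range %.3f m",
                            target$d0, sweep$unambiguous_range))
  check_scene_ranges(scene, sweep)
  freqs <- sweep_frequencies(sweep)
  tt <- sweep_times(sweep)
  tau0 <- 2 * target$d0 / C_LIGHT
  dtau <- 2 * target$delta_d / C_LIGHT
  with_local_seed(seed, {
    S <- resolve_spectrum_profile(scene, sweep)
    # M x N breathing phase: exp(-j 2 pi f_m dtau sin(2 pi fb t_n))
    breathing <- exp(-2i * pi * outer(freqs * dtau, sin(2 * pi * target$fb * tt)))
    tgt <- target$alpha * exp(-2i * pi * freqs * tau0) * breathing
    base <- tgt + static_column(scene, freqs)  # static column recycles over n
    echo_matrix(S * base + draw_noise(sweep$M, sweep$N, scene$noise_sigma), sweep)
  })
}

#' Simulate a static (non-breathing) SFCW echo
#'
#' The clutter-only model: every scatterer return
#' `S[m] * alpha_i * exp(-j 2 pi f_m tau_i)` is constant along slow time, so
#' before noise all columns of the echo matrix are identical. With a random
#' spectrum profile the rows vary irregularly across operational frequency —
#' the defining contrast with the breathing target, whose slow-time
#' modulation is consistent across frequencies.
#'
#' @inheritParams simulate_breathing_echo
#' @param scene A [clutter_scene()] with at least one scatterer or positive
#'   noise.
#' @return An [echo_matrix()].
#' @export
simulate_static_echo <- function(sweep, scene, seed = 1L) {
  stopifnot(inherits(sweep, "sweep_config"), inherits(scene, "clutter_scene"))
  empty <- is.null(scene$static_scatterers) || nrow(scene$static_scatterers) == 0
  if (empty && scene$noise_sigma <= 0)
    stop_validation("static scene must contain a scatterer or noise")
  check_scene_ranges(scene, sweep)
  freqs <- sweep_frequencies(sweep)
  with_local_seed(seed, {
    S <- resolve_spectrum_profile(scene, sweep)
    col <- S * static_column(scene, freqs)
    echo_matrix(matrix(col, sweep$M, sweep$N) +
                  draw_noise(sweep$M, sweep$N, scene$noise_sigma), sweep)
  })
}

#' @noRd
check_scene_ranges <- function(scene, sweep) {
  sc <- scene$static_scatterers
  if (!is.null(sc) && nrow(sc) > 0 && any(sc$range >= sweep$unambiguous_range))
    stop_validation("scatterer range outside the unambiguous range")
  invisible(TRUE)
}

#' Truncated Bessel (Jacobi-Anger) expansion of the breathing phase factor
#'
#' The sinusoidal delay modulation enters the echo as
#' `exp(-j x sin(2 pi fb t))` with modulation index `x = omega * delta_tau`.
#' By the Jacobi-Anger identity its Fourier series is
#' `sum_n J_n(x) exp(-j n 2 pi fb t)` over integer orders `n`, with `J_n`
#' the Bessel function of the first kind. The
#' truncated series is an independent closed-form oracle for the simulator's
#' phase factor, and shows why the breathing line structure is regular in
#' slow time at every operational frequency.
#'
#' @param omega_delta_tau Modulation index `omega * delta_tau` [rad], >= 0.
#' @param fb Breathing frequency [Hz].
#' @param t Time instant(s) [s]; vectorized.
#' @param n_terms Truncation order; terms `n = -n_terms, ..., n_terms` are
#'   summed (`n_terms = 0` keeps only `J_0`).
#'
#' @return Complex value(s), one per element of `t`.
#' @examples
#' bessel_phase_series(0, 0.2, 1, n_terms = 1)  # exactly 1+0i
#' @export
bessel_phase_series <- function(omega_delta_tau, fb, t, n_terms = 25L) {
  if (omega_delta_tau < 0) stop_validation("omega_delta_tau must be >= 0")
  n_terms <- as.integer(n_terms)
  if (n_terms < 0L) stop_validation("n_terms must be >= 0")
  out <- rep(0 + 0i, length(t))
  for (n in -n_terms:n_terms) {
    # J_{-n}(x) = (-1)^n J_n(x) for integer order
    jn <- if (n >= 0) besselJ(omega_delta_tau, n)
          else (-1)^(-n) * besselJ(omega_delta_tau, -n)
    out <- out + jn * exp(-1i * n * 2 * pi * fb * t)
  }
  out
}

#' Per-frequency echo power spectrum
#'
#' Diagnoses how the echo energy is spread across the operational bandwidth:
#' for an SFCW echo matrix, the mean over slow time of the squared magnitude
#' in each operational-frequency bin; for a real range-time matrix (the
#' impulse-radio UWB observable) the matrix is first transformed along range
#' by FFT. An energy distribution that roughly overspreads the bandwidth is
#' what makes sub-band segmentation informative; concentration in a narrow
#' section (typical of equivalent-time-sampled impulse radios) makes it
#' fruitless.
#'
#' @param x An [echo_matrix()], or a real matrix of range (rows) x slow time
#'   (columns).
#' @return Numeric vector of per-bin mean power, one entry per row of the
#'   (transformed) matrix.
#' @export
echo_spectrum <- function(x) {
  if (inherits(x, "echo_matrix")) {
    d <- x$data
  } else {
    d <- as.matrix(x)
    if (nrow(d) < 1L || ncol(d) < 1L) stop_validation("matrix must be nonempty")
    d <- stats::mvfft(d)  # range -> frequency per slow-time column
  }
  rowMeans(Mod(d)^2)
}

#' Spectral concentration ratio
#'
#' Fraction of total spectral energy held by the strongest `top_frac` of
#' frequency bins; near `top_frac` for a flat spectrum and near 1 for a
#' concentrated one.
#'
#' @param spectrum Nonnegative per-bin power vector, e.g. from
#'   [echo_spectrum()].
#' @param top_frac Fraction of bins counted as the "top" bins, in (0, 1].
#' @return A number in \[0, 1\].
#' @export
spectral_concentration <- function(spectrum, top_frac = 0.1) {
  if (any(spectrum < 0)) stop_validation("spectrum must be nonnegative")
  tot <- sum(spectrum)
  if (tot == 0) return(0)
  k <- max(1L, ceiling(top_frac * length(spectrum)))
  sum(sort(spectrum, decreasing = TRUE)[seq_len(k)]) / tot
}
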