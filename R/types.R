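#' Stepped-frequency sweep configuration
#'
#' Defines both axes of every echo matrix: the operational-frequency grid
#' `f0 + m * delta_f` (m = 0, ..., M-1) swept by the radar, and the slow-time
#' grid `n * Ts` (n = 0, ..., N-1) of repeated sweeps.
#'
#' Derived quantities are attached on construction: the operational bandwidth
#' `(M - 1) * delta_f` [Hz], the unambiguous range `c / (2 * delta_f)` [m]
#' (maximum range representable without aliasing after the IFFT to range),
#' and the observation duration `(N - 1) * Ts` [s].
#'
#' @param f0 Start frequency [Hz], > 0.
#' @param delta_f Frequency step [Hz], > 0.
#' @param M Number of operational-frequency samples, >= 2.
#' @param Ts Slow-time sampling period [s], > 0.
#' @param N Number of slow-time samples, >= 1.
#'
#' @return An object of class `sweep_config`.
#' @examples
#' sw <- sweep_config(f0 = 500e6, delta_f = 10e6, M = 501, Ts = 0.005, N = 2001)
#' sw$unambiguous_range  # 14.99 m (c / (2 * 10 MHz))
#' @export
sweep_config <- function(f0, delta_f, M, Ts, N) {
  if (!is.numeric(f0) || f0 <= 0) stop_validation("f0 must be > 0")
  if (!is.numeric(delta_f) || delta_f <= 0) stop_validation("delta_f must be > 0")
  M <- as.integer(M); N <- as.integer(N)
  if (is.na(M) || M < 2L) stop_validation("M must be an integer >= 2")
  if (!is.numeric(Ts) || Ts <= 0) stop_validation("Ts must be > 0")
  if (is.na(N) || N < 1L) stop_validation("N must be an integer >= 1")
  structure(list(
    f0 = f0, delta_f = delta_f, M = M, Ts = Ts, N = N,
    bandwidth = (M - 1) * delta_f,
    unambiguous_range = C_LIGHT / (2 * delta_f),
    duration = (N - 1) * Ts
  ), class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf(
    "<sweep_config> f0=%.4g MHz, delta_f=%.4g MHz, M=%d, Ts=%g s, N=%d\n",
    x$f0 / 1e6, x$delta_f / 1e6, x$M, x$Ts, x$N))
  cat(sprintf("  bandwidth %.4g MHz | unambiguous range %.4g m | duration %g s\n",
              x$bandwidth / 1e6, x$unambiguous_range, x$duration))
  invisible(x)
}

#' Breathing point target
#'
#' A stationary human modelled as a point scatterer whose range oscillates
#' with the chest wall: `d(t) = d0 + delta_d * sin(2 * pi * fb * t)`. The
#' corresponding two-way delay is `tau0 + delta_tau * sin(2 * pi * fb * t)`
#' with `tau0 = 2 * d0 / c` and `delta_tau = 2 * delta_d / c`.
#'
#' @param alpha Complex reflectivity (frequency independent), dimensionless.
#' @param d0 Nominal range [m], > 0.
#' @param delta_d Breathing displacement amplitude [m], >= 0; 0 reduces the
#'   target to a static scatterer.
#' @param fb Breathing frequency [Hz], >= 0.
#'
#' @return An object of class `breathing_target`.
#' @examples
#' breathing_target(alpha = 1, d0 = 3, delta_d = 0.005, fb = 0.2)
#' @export
breathing_target <- function(alpha = 1 + 0i, d0 = 3, delta_d = 0.005, fb = 0.2) {
  if (!is.numeric(d0) || d0 <= 0) stop_validation("d0 must be > 0")
  if (delta_d < 0) stop_validation("delta_d must be >= 0")
  if (fb < 0) stop_validation("fb must be >= 0")
  structure(list(alpha = as.complex(alpha), d0 = d0,
                 delta_d = delta_d, fb = fb),
            class = "breathing_target")
}

#' Static clutter scene
#'
#' Collects everything in the echo besides the breathing target: static point
#' scatterers (walls, furniture), a per-frequency complex gain profile
#' standing for the effective transmit spectrum `S(omega)` as distorted by
#' propagation, and additive receiver noise.
#'
#' The spectrum profile may be `"flat"` (unit gain at every operational
#' frequency) or `"random"`: independent complex circular Gaussian gains per
#' frequency bin, scaled to unit mean magnitude, drawn once per simulation and
#' held fixed over slow time. The random profile models the unknown,
#' frequency-irregular distortion that through-obstacle propagation imposes on
#' static clutter. A numeric complex vector of length `M` may also be given
#' directly.
#'
#' @param static_scatterers A data frame with columns `range` [m] and
#'   `reflectivity` (complex), one row per scatterer; or `NULL` for an empty
#'   scene.
#' @param spectrum_profile `"flat"`, `"random"`, or a complex vector whose
#'   length must match the sweep's `M`.
#' @param noise_sigma Standard deviation of additive complex circular Gaussian
#'   noise per matrix sample (per real/imaginary component it is
#'   `noise_sigma / sqrt(2)`), >= 0.
#'
#' @return An object of class `clutter_scene`.
#' @examples
#' clutter_scene(data.frame(range = c(2.5, 6), reflectivity = c(2 + 0i, 1i)),
#'               spectrum_profile = "random", noise_sigma = 0.1)
#' @export
clutter_scene <- function(static_scatterers = NULL,
                          spectrum_profile = "flat",
                          noise_sigma = 0) {
  if (!is.null(static_scatterers)) {
    if (!is.data.frame(static_scatterers) ||
        !all(c("range", "reflectivity") %in% names(static_scatterers)))
      stop_validation("static_scatterers needs columns 'range' and 'reflectivity'")
    if (any(static_scatterers$range <= 0))
      stop_validation("scatterer ranges must be > 0")
  }
  if (is.character(spectrum_profile)) {
    spectrum_profile <- match.arg(spectrum_profile, c("flat", "random"))
  } else if (!is.numeric(spectrum_profile) && !is.complex(spectrum_profile)) {
    stop_validation("spectrum_profile must be 'flat', 'random', or a complex vector")
  }
  if (noise_sigma < 0) stop_validation("noise_sigma must be >= 0")
  structure(list(static_scatterers = static_scatterers,
                 spectrum_profile = spectrum_profile,
                 noise_sigma = noise_sigma),
            class = "clutter_scene")
}

#' Echo matrix container
#'
#' The raw SFCW radar observable: a complex `M x N` matrix whose rows index
#' the operational frequency `f0 + m * delta_f` and whose columns index slow
#' time `n * Ts`.
#'
#' @param data Complex matrix with `sweep$M` rows and `sweep$N` columns.
#' @param sweep A [sweep_config()].
#'
#' @return An object of class `echo_matrix`.
#' @export
echo_matrix <- function(data, sweep) {
  stopifnot(inherits(sweep, "sweep_config"))
  data <- as.matrix(data)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (nrow(data) != sweep$M || ncol(data) != sweep$N)
    stop_dimension(sprintf("echo matrix is %d x %d but sweep expects %d x %d",
                           nrow(data), ncol(data), sweep$M, sweep$N))
  structure(list(data = data, sweep = sweep), class = "echo_matrix")
}

#' @export
print.echo_matrix <- function(x, ...) {
  cat(sprintf("<echo_matrix> %d operational frequencies x %d slow-time samples\n",
              nrow(x$data), ncol(x$data)))
  print(x$sweep)
  invisible(x)
}

# Operational frequencies [Hz] of a sweep.
#' @noRd
sweep_frequencies <- function(sweep) sweep$f0 + (seq_len(sweep$M) - 1) * sweep$delta_f

# Slow-time instants [s] of a sweep.
#' @noRd
sweep_times <- function(sweep) (seq_len(sweep$N) - 1) * sweep$Ts
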