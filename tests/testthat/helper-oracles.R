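# Independent oracles: direct scalar evaluation of the echo model and a
# brute-force window enumeration for the segmentation count. These stay
# deliberately naive (entry-by-entry loops) so they share no code with the
# vectorized implementation.

C0 <- 299792458

# Direct per-entry evaluation of the stepped-frequency echo model:
# S[m] * (alpha exp(-j2pi f_m tau0) exp(-j2pi f_m dtau sin(2pi fb t_n))
#         + sum_i alpha_i exp(-j2pi f_m tau_i))
brute_force_echo <- function(sweep, target = NULL, scatterers = NULL,
                             spectrum = rep(1 + 0i, sweep$M)) {
  out <- matrix(0 + 0i, sweep$M, sweep$N)
  for (m in 0:(sweep$M - 1)) {
    f <- sweep$f0 + m * sweep$delta_f
    for (n in 0:(sweep$N - 1)) {
      t <- n * sweep$Ts
      val <- 0 + 0i
      if (!is.null(target)) {
        tau0 <- 2 * target$d0 / C0
        dtau <- 2 * target$delta_d / C0
        val <- val + target$alpha * exp(-2i * pi * f * tau0) *
          exp(-2i * pi * f * dtau * sin(2 * pi * target$fb * t))
      }
      if (!is.null(scatterers)) {
        for (i in seq_len(nrow(scatterers))) {
          val <- val + scatterers$reflectivity[i] *
            exp(-2i * pi * f * 2 * scatterers$range[i] / C0)
        }
      }
      out[m + 1, n + 1] <- spectrum[m + 1] * val
    }
  }
  out
}

# Count sliding-window positions by explicit enumeration.
brute_force_subband_count <- function(M, L, delta_l) {
  count <- 0L
  p <- 0L
  while (p + L <= M) {
    count <- count + 1L
    p <- p + delta_l
  }
  count
}

# Reference sweep of the simulation study (5 GHz band, 15 m unambiguous
# range, 30 s record).
reference_sweep <- function() sweep_config(500e6, 10e6, 501, 0.005, 2001)

# Small sweep for cheap pipeline unit tests (same Ts so the slow-time
# filters behave identically; 601 samples still exceed the low-pass length).
small_sweep <- function(N = 601) sweep_config(500e6, 10e6, 101, 0.005, N)
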