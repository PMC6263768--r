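# Operational bandwidth segmentation: a rectangular window of length L slides
# along the operational-frequency axis in steps of delta_l, producing a stack
# of band-limited copies of the echo matrix.

#' Segmentation parameters
#'
#' @param L Window length in operational-frequency bins.
#' @param delta_l Window moving step in bins.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(L = 100L, delta_l = 10L) {
  L <- as.integer(L); delta_l <- as.integer(delta_l)
  if (is.na(L) || L < 1L) stop_validation("L must be an integer >= 1")
  if (is.na(delta_l) || delta_l < 1L) stop_validation("delta_l must be an integer >= 1")
  structure(list(L = L, delta_l = delta_l), class = "segmentation_params")
}

#' Number of sub-bands produced by a sliding rectangular window
#'
#' A window of `L` bins stepping by `delta_l` bins over an `M`-bin band fits
#' `floor((M - L) / delta_l) + 1` times (window start positions
#' `0, delta_l, 2 delta_l, ...` with the window end inside the band). With
#' the radar's 874 frequency samples and the default window (L = 100,
#' delta_l = 10) this gives 78 sub-bands.
#'
#' @param M Number of operational-frequency bins.
#' @param L Window length in bins, `1 <= L <= M`.
#' @param delta_l Moving step in bins, >= 1.
#' @return Integer sub-band count.
#' @examples
#' count_subbands(874, 100, 10)  # 78
#' @export
count_subbands <- function(M, L, delta_l) {
  M <- as.integer(M); L <- as.integer(L); delta_l <- as.integer(delta_l)
  if (L > M) stop_validation("window length L exceeds the number of bins M")
  if (L < 1L || delta_l < 1L) stop_validation("L and delta_l must be >= 1")
  as.integer((M - L) %/% delta_l + 1L)
}

#' Segment an echo matrix into overlapping sub-bands
#'
#' Applies the sliding rectangular mask along the operational frequency:
#' sub-band `l` (0-based) keeps rows `[l * delta_l, l * delta_l + L)` of the
#' echo matrix and zeroes all other rows. Slices retain the full frequency
#' axis (zero-padded outside the window) so that the subsequent IFFT of every
#' slice lands on one common range grid and sub-bands can be averaged
#' bin-wise.
#'
#' @param echo An [echo_matrix()].
#' @param params A [segmentation_params()]; the window must fit within the
#'   sweep's `M` bins.
#' @return A `subband_cube`: list with `data` (complex array, sub-band x
#'   frequency x slow time), `params`, `sweep`, `subband_count`.
#' @export
segment_bandwidth <- function(echo, params = segmentation_params()) {
  stopifnot(inherits(echo, "echo_matrix"), inherits(params, "segmentation_params"))
  M <- echo$sweep$M
  nsub <- count_subbands(M, params$L, params$delta_l)
  cube <- array(0 + 0i, dim = c(nsub, M, echo$sweep$N))
  for (l in seq_len(nsub) - 1L) {
    rows <- (l * params$delta_l + 1L):(l * params$delta_l + params$L)
    cube[l + 1L, rows, ] <- echo$data[rows, ]
  }
  structure(list(data = cube, params = params, sweep = echo$sweep,
                 subband_count = nsub, domain = "frequency"),
            class = "subband_cube")
}

#' @export
print.subband_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<subband_cube> %d sub-bands x %d bins x %d slow-time samples (%s domain)\n",
              d[1], d[2], d[3], x$domain))
  invisible(x)
}

#' Sub-band segmentation of a range-time matrix (impulse-radio variant)
#'
#' Impulse-radio UWB radars deliver real range x slow-time matrices rather
#' than frequency x slow-time ones. The same operational-bandwidth
#' segmentation is obtained by transforming the range axis to frequency by
#' FFT, applying the sliding rectangular mask of [segment_bandwidth()] per
#' sub-band, and transforming each masked slice back to range by IFFT. Each
#' slice is then a band-limited range-time matrix on the original range grid.
#'
#' @param rt_matrix Real (or complex) matrix, range bins x slow-time samples.
#' @param params A [segmentation_params()] in frequency bins of the
#'   range-FFT grid.
#' @return A `subband_cube` in the range domain (complex slices).
#' @export
segment_range_time <- function(rt_matrix, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  rt_matrix <- as.matrix(rt_matrix)
  if (nrow(rt_matrix) < 1L || ncol(rt_matrix) < 1L)
    stop_validation("rt_matrix must be nonempty")
  if (!is.complex(rt_matrix)) storage.mode(rt_matrix) <- "complex"
  M <- nrow(rt_matrix)
  nsub <- count_subbands(M, params$L, params$delta_l)
  spec <- stats::mvfft(rt_matrix)
  cube <- array(0 + 0i, dim = c(nsub, M, ncol(rt_matrix)))
  for (l in seq_len(nsub) - 1L) {
    rows <- (l * params$delta_l + 1L):(l * params$delta_l + params$L)
    masked <- matrix(0 + 0i, M, ncol(rt_matrix))
    masked[rows, ] <- spec[rows, ]
    cube[l + 1L, , ] <- imvfft(masked)
  }
  structure(list(data = cube, params = params, sweep = NULL,
                 subband_count = nsub, domain = "range"),
            class = "subband_cube")
}
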