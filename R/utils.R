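# Internal numerical helpers shared across the pipeline.

# Exact speed of light [m/s].
C_LIGHT <- 299792458

#' @noRd
stop_validation <- function(...) {
  stop(structure(class = c("sfcw_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
stop_dimension <- function(...) {
  stop(structure(class = c("sfcw_dimension_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Inverse DFT along the rows of a matrix (each column transformed), with the
# conventional 1/M normalization so that fft(ifft(x)) == x.
#' @noRd
imvfft <- function(x) stats::mvfft(x, inverse = TRUE) / nrow(x)

# Linear convolution of a (possibly complex) series with a symmetric FIR,
# trimmed to the input length at the filter's group delay so the output is
# time-aligned with the input (zero-phase for linear-phase taps). Samples
# beyond the ends of the series are treated as zero.
#' @noRd
fir_apply <- function(x, taps) {
  n <- length(x)
  nt <- length(taps)
  gd <- (nt - 1L) %/% 2L
  L <- stats::nextn(n + nt - 1L)
  X <- stats::fft(c(x, rep(0 + 0i, L - n)))
  H <- stats::fft(c(as.complex(taps), rep(0 + 0i, L - nt)))
  y <- stats::fft(X * H, inverse = TRUE) / L
  y[(gd + 1L):(gd + n)]
}

# Centered moving average with the window shrunk at the edges, so every output
# sample is the mean of the available samples within +/- halfwidth.
#' @noRd
moving_average <- function(x, halfwidth) {
  n <- length(x)
  s <- c(0 + 0i, cumsum(as.complex(x)))
  i <- seq_len(n)
  lo <- pmax(1L, i - halfwidth)
  hi <- pmin(n, i + halfwidth)
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

# Apply a function f(series) -> series over the slow-time axis (3rd dim) of a
# (subband x range x time) complex array; f must preserve length.
#' @noRd
apply_slow_time <- function(a, f) {
  d <- dim(a)
  m <- matrix(aperm(a, c(3L, 1L, 2L)), nrow = d[3L])
  for (j in seq_len(ncol(m))) m[, j] <- f(m[, j])
  aperm(array(m, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
}

#' @noRd
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS2"),
                  stage, paste0(...)))
}
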