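#' Butterworth band-pass filtering of a UEG recording
#'
#' Removes the DC component, baseline wander and high-frequency low-amplitude
#' noise with a digital Butterworth band-pass (defaults 0.5-40 Hz, order 4).
#' By default the filter is applied forward-backward (zero phase): a causal
#' pass would delay every deflection and bias the activation times the rest
#' of the pipeline measures. The zero-phase effective attenuation is the
#' squared single-pass magnitude response.
#'
#' Each pass is initialised at the steady state of a constant input equal to
#' the first sample (so a pure DC offset is removed exactly, with no edge
#' transient) and the signal is extended by odd reflection over a pad scaled
#' to the slowest pole's time constant before the forward-backward pass.
#'
#' @param recording a [UegRecording-class].
#' @param fc1,fc2 low/high cutoff frequencies in Hz (0 < fc1 < fc2 < fs/2).
#' @param order filter order of the band-pass (even; default 4).
#' @param zeroPhase apply forward-backward (default) or single causal pass.
#' @return a [UegRecording-class] of identical shape and metadata.
#' @examples
#' g <- ElectrodeGrid(6, 8)
#' rec <- simulateRecording(g, planarWave(100), beatTrainSpec(nBeats = 2),
#'                          fs = 500)
#' filt <- bandpassFilter(rec)
#' dim(filt)
#' @export
bandpassFilter <- function(recording, fc1 = 0.5, fc2 = 40, order = 4,
                           zeroPhase = TRUE) {
  stopifnot(is(recording, "UegRecording"))
  fs <- recording@fs
  if (!is.finite(fc1) || !is.finite(fc2) || fc1 <= 0 || fc1 >= fc2)
    stop("configuration error: need 0 < fc1 < fc2")
  if (fc2 >= fs / 2)
    stop("configuration error: fc2 must be below the Nyquist frequency fs/2")
  if (order < 2 || order %% 2 != 0)
    stop("configuration error: band-pass order must be a positive even ",
         "number")
  co <- designBandpass(fc1, fc2, order, fs)
  x <- recording@samples
  y <- x
  for (j in seq_len(ncol(x))) {
    y[, j] <- if (zeroPhase) {
      zeroPhaseFilter(co$b, co$a, x[, j], co$padlen)
    } else {
      iirConstPast(co$b, co$a, x[, j])
    }
  }
  out <- recording
  out@samples <- y
  out
}

# Butterworth band-pass coefficients; an order-n band-pass comes from an
# order n/2 low-pass prototype. padlen covers ~6 time constants of the
# slowest pole so reflection-padded transients die before reaching the data.
designBandpass <- function(fc1, fc2, order, fs) {
  bf <- signal::butter(order / 2, c(fc1, fc2) / (fs / 2), type = "pass")
  r <- max(Mod(polyroot(rev(bf$a))))
  padlen <- as.integer(ceiling(6 / max(1 - r, 1e-6)))
  list(b = bf$b, a = bf$a, padlen = padlen)
}

# single causal IIR pass, initialised as if the input had been constant at
# x[1] for all past time (linearity: response = zero-state response of
# (x - x[1]) plus the steady-state response x[1] * H(1)). The FIR and AR
# recursions run in C via stats::filter.
iirConstPast <- function(b, a, x) {
  nb <- length(b)
  x0 <- x[1L]
  v <- stats::filter(c(rep(0, nb - 1L), x - x0), b, method = "convolution",
                     sides = 1L)
  v <- as.numeric(v)[nb:(nb - 1L + length(x))]
  y <- as.numeric(stats::filter(v / a[1L], -a[-1L] / a[1L],
                                method = "recursive"))
  y + x0 * sum(b) / sum(a)
}

# forward-backward pass over an odd-reflection-padded signal
zeroPhaseFilter <- function(b, a, x, padlen) {
  n <- length(x)
  p <- min(n - 1L, padlen)
  xe <- if (p > 0L) {
    c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  } else {
    x
  }
  y <- iirConstPast(b, a, xe)
  y <- rev(iirConstPast(b, a, rev(y)))
  y[(p + 1L):(p + n)]
}
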