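#' Construct a UegRecording
#'
#' Wrap an existing sample matrix (e.g. loaded from an acquisition system
#' export) together with its grid geometry and pacing metadata. For synthetic
#' data use [simulateRecording()], which also attaches the ground truth.
#'
#' @param samples numeric matrix, rows = time samples, columns = channels in
#'   row-major \code{(row, col)} order.
#' @param fs sampling rate in Hz.
#' @param grid an [ElectrodeGrid-class].
#' @param pacingTimes pacing stimulus times in ms (empty for sinus rhythm).
#' @param pacingRate pacing rate in beats/min (\code{NA} for sinus rhythm).
#' @param groundTruthAT optional per-channel ground-truth activation time in
#'   ms relative to the stimulus.
#' @return a [UegRecording-class].
#' @export
UegRecording <- function(samples, fs, grid, pacingTimes = numeric(0),
                         pacingRate = NA_real_,
                         groundTruthAT = numeric(0)) {
  new("UegRecording", samples = samples, fs = as.numeric(fs), grid = grid,
      pacingTimes = as.numeric(pacingTimes),
      pacingRate = as.numeric(pacingRate),
      groundTruthAT = as.numeric(groundTruthAT))
}

#' Accessors for UegRecording
#'
#' @param x a [UegRecording-class].
#' @return \code{samples}: the sample matrix; \code{samplingRate}: Hz;
#'   \code{pacingTimes}: ms; \code{electrodeGrid}: the grid;
#'   \code{groundTruth}: per-channel ground-truth AT (ms) or
#'   \code{numeric(0)}.
#' @name UegRecording-accessors
NULL

#' @rdname UegRecording-accessors
#' @export
setMethod("samples", "UegRecording", function(x) x@samples)

#' @rdname UegRecording-accessors
#' @export
setMethod("samplingRate", "UegRecording", function(x) x@fs)

#' @rdname UegRecording-accessors
#' @export
setMethod("pacingTimes", "UegRecording", function(x) x@pacingTimes)

#' @rdname UegRecording-accessors
#' @export
setMethod("electrodeGrid", "UegRecording", function(x) x@grid)

#' @rdname UegRecording-accessors
#' @export
setMethod("groundTruth", "UegRecording", function(x) x@groundTruthAT)

#' @rdname UegRecording-accessors
#' @export
setMethod("dim", "UegRecording", function(x) dim(x@samples))

setMethod("show", "UegRecording", function(object) {
  dur <- nrow(object@samples) / object@fs
  cat(sprintf("UegRecording: %d channels x %.2f s at %g Hz\n",
              ncol(object@samples), dur, object@fs))
  show(object@grid)
  np <- length(object@pacingTimes)
  if (np) {
    cat(sprintf("  paced: %d stimuli%s\n", np,
                if (is.na(object@pacingRate)) "" else
                  sprintf(" at %g bpm", object@pacingRate)))
  } else {
    cat("  sinus rhythm (no pacing times)\n")
  }
  if (length(object@groundTruthAT))
    cat("  synthetic: ground-truth activation times attached\n")
})

# duration of the recording in ms
recordingDurationMs <- function(x) nrow(x@samples) / x@fs * 1000

# sample times in ms (first sample at t = 0)
sampleTimesMs <- function(x) (seq_len(nrow(x@samples)) - 1) / x@fs * 1000
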