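#' @rdname ElectrodeGrid-accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname ElectrodeGrid-accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' @rdname ElectrodeGrid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname ElectrodeGrid-accessors
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))

#' @rdname ElectrodeGrid-accessors
#' @export
setGeneric("electrodePositions", function(x) {
  standardGeneric("electrodePositions")
})

#' @rdname ElectrodeGrid-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Ground-truth activation times of a kinematic wavefront
#'
#' Evaluate the analytic activation time (ms, relative to the pacing
#' stimulus) of a wavefront at arbitrary positions or at every electrode of a
#' grid. Speeds are cm/s, positions mm; 1 mm/ms = 100 cm/s.
#'
#' @param wavefront a [WavefrontSpec-class].
#' @param where either a numeric matrix of positions (columns x, y in mm) or
#'   an [ElectrodeGrid-class] (ground truth at every electrode, row-major).
#' @return numeric vector of activation times in ms.
#' @examples
#' g <- ElectrodeGrid(11, 11, spacing = 5)
#' w <- planarWave(speed = 100, direction = c(1, 0), onsetDelay = 130)
#' at <- groundTruthAT(w, g)
#' # column-adjacent electrodes are 5 mm apart: 5 mm / (100 cm/s) = 5 ms
#' diff(at[1:2])
#' @export
setGeneric("groundTruthAT", function(wavefront, where) {
  standardGeneric("groundTruthAT")
})

#' @rdname UegRecording-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname UegRecording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname UegRecording-accessors
#' @export
setGeneric("pacingTimes", function(x) standardGeneric("pacingTimes"))

#' @rdname UegRecording-accessors
#' @export
setGeneric("electrodeGrid", function(x) standardGeneric("electrodeGrid"))

#' @rdname UegRecording-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("activationTimes", function(x) standardGeneric("activationTimes"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("validChannels", function(x) standardGeneric("validChannels"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("atMatrix", function(x) standardGeneric("atMatrix"))

#' @rdname ActivationMap-accessors
#' @export
setGeneric("arrivalTime", function(x) standardGeneric("arrivalTime"))

#' @rdname IsochroneSet-accessors
#' @export
setGeneric("isochroneLevels", function(x) standardGeneric("isochroneLevels"))

#' @rdname IsochroneSet-accessors
#' @export
setGeneric("regionAssignment", function(x) {
  standardGeneric("regionAssignment")
})

#' @rdname VelocityEstimate-accessors
#' @export
setGeneric("wpv", function(x) standardGeneric("wpv"))

#' @rdname VelocityEstimate-accessors
#' @export
setGeneric("propagationDirection", function(x) {
  standardGeneric("propagationDirection")
})
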