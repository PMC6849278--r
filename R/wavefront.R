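#' Planar and focal wavefront constructors
#'
#' A planar wave activates position \code{x} at
#' \code{onsetDelay + (x . direction) / speed}; a focal wave at
#' \code{onsetDelay + |x - sourcePosition| / speed}. Note that for a planar
#' wave \code{onsetDelay} is the activation time at the coordinate origin, so
#' directions with negative components need an onset delay large enough to
#' keep every electrode's activation time positive (the simulator checks).
#'
#' @param speed conduction speed in cm/s.
#' @param direction direction of propagation (planar); normalised internally.
#' @param sourcePosition focus position in mm (focal).
#' @param onsetDelay ms from the pacing stimulus to activation at the
#'   reference point. Observed epicardial arrival delays in ex vivo paced
#'   hearts are on the order of 130-150 ms, hence the default.
#' @return a [WavefrontSpec-class].
#' @examples
#' planarWave(100, direction = c(1, 0))
#' focalWave(50, sourcePosition = c(25, 25))
#' @export
planarWave <- function(speed, direction = c(1, 0), onsetDelay = 130) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("direction must be a nonzero vector")
  new("WavefrontSpec", kind = "planar", speed = as.numeric(speed),
      direction = direction / nrm, sourcePosition = numeric(0),
      onsetDelay = as.numeric(onsetDelay))
}

#' @rdname planarWave
#' @export
focalWave <- function(speed, sourcePosition, onsetDelay = 130) {
  if (missing(sourcePosition) || length(sourcePosition) != 2L)
    stop("focal wavefront requested without a sourcePosition (x, y) in mm")
  new("WavefrontSpec", kind = "focal", speed = as.numeric(speed),
      direction = numeric(0),
      sourcePosition = as.numeric(sourcePosition),
      onsetDelay = as.numeric(onsetDelay))
}

#' @rdname groundTruthAT
#' @export
setMethod("groundTruthAT", signature("WavefrontSpec", "matrix"),
  function(wavefront, where) {
    speedMmMs <- wavefront@speed / CM_S_PER_MM_MS
    if (wavefront@kind == "planar") {
      proj <- where %*% wavefront@direction
      wavefront@onsetDelay + as.numeric(proj) / speedMmMs
    } else {
      dx <- sweep(where, 2L, wavefront@sourcePosition)
      wavefront@onsetDelay + sqrt(rowSums(dx^2)) / speedMmMs
    }
  })

#' @rdname groundTruthAT
#' @export
setMethod("groundTruthAT", signature("WavefrontSpec", "ElectrodeGrid"),
  function(wavefront, where) {
    groundTruthAT(wavefront, electrodePositions(where))
  })

setMethod("show", "WavefrontSpec", function(object) {
  if (object@kind == "planar") {
    cat(sprintf(
      "WavefrontSpec: planar, %g cm/s along (%.3f, %.3f), onset %g ms\n",
      object@speed, object@direction[1L], object@direction[2L],
      object@onsetDelay))
  } else {
    cat(sprintf(
      "WavefrontSpec: focal at (%g, %g) mm, %g cm/s, onset %g ms\n",
      object@sourcePosition[1L], object@sourcePosition[2L], object@speed,
      object@onsetDelay))
  }
})
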