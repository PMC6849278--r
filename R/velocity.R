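#' Two-point wave propagation velocity
#'
#' The literal definition of the wave propagation velocity on an activation
#' map: \code{WPV = d(p2, p1) / (AT(p2) - AT(p1))}, where p1 and p2 are two
#' electrodes in the direction of propagation and d is their Euclidean
#' distance. Distances are mm, AT differences ms, and the result is reported
#' in cm/s (1 mm/ms = 100 cm/s).
#'
#' If \code{p1}/\code{p2} are omitted the pair is chosen deterministically:
#' the propagation direction is taken from the least-squares plane fit, and
#' among the valid electrode pairs most aligned with it the pair at maximal
#' separation wins (lowest channel indices on ties).
#'
#' @param map an [ActivationMap-class].
#' @param p1,p2 electrode labels \code{c(row, col)}; p2 must activate later
#'   than p1.
#' @return a [VelocityEstimate-class] with \code{method = "two_point"}.
#' @examples
#' g <- ElectrodeGrid(11, 11, spacing = 5)
#' at <- groundTruthAT(planarWave(100, c(1, 0)), g)
#' map <- new("ActivationMap", beatIndex = 1L, stimulusTime = 0,
#'            at = at, valid = rep(TRUE, length(at)), grid = g)
#' wpv(estimateWpvTwoPoint(map, c(1, 1), c(1, 11)))  # 100 cm/s
#' @export
estimateWpvTwoPoint <- function(map, p1 = NULL, p2 = NULL) {
  stopifnot(is(map, "ActivationMap"))
  if (is.null(p1) != is.null(p2))
    stop("supply both p1 and p2, or neither")
  if (is.null(p1)) {
    pair <- selectPropagationPair(map)
    p1 <- pair$p1
    p2 <- pair$p2
  }
  i1 <- channelIndex(map@grid, p1)
  i2 <- channelIndex(map@grid, p2)
  if (!map@valid[i1] || !map@valid[i2])
    stop("two-point velocity requires two valid electrodes")
  dAt <- map@at[i2] - map@at[i1]
  if (dAt == 0)
    stop("undefined velocity: AT(p2) equals AT(p1)")
  if (dAt < 0)
    stop("p2 must activate after p1 (swap the points)")
  pos <- electrodePositions(map@grid)
  dvec <- pos[i2, ] - pos[i1, ]
  dMm <- sqrt(sum(dvec^2))
  new("VelocityEstimate", beatIndex = map@beatIndex,
      wpv = CM_S_PER_MM_MS * dMm / dAt, method = "two_point",
      direction = dvec / dMm,
      points = normalizeLabels(list(p1, p2)), residual = NA_real_)
}

#' Deterministic electrode-pair choice for two-point velocity
#'
#' Takes the propagation direction from the plane fit, keeps the valid
#' electrode pairs whose axis is most aligned with it (largest |cosine|,
#' within 1e-9 of the best), and among those returns the pair at maximal
#' separation; remaining ties go to the lowest channel indices.
#'
#' @param map an [ActivationMap-class].
#' @return list with elements \code{p1}, \code{p2} (labels, earlier electrode
#'   first).
#' @export
selectPropagationPair <- function(map) {
  fit <- fitPlaneVelocity(map)
  dir <- fit@direction
  idx <- which(map@valid)
  pos <- electrodePositions(map@grid)
  best <- NULL
  bestSep <- -Inf
  bestAlign <- -Inf
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      v <- pos[j, ] - pos[i, ]
      sep <- sqrt(sum(v^2))
      al <- abs(sum(v * dir)) / sep
      if (al > bestAlign + 1e-9 ||
          (al > bestAlign - 1e-9 && sep > bestSep + 1e-9)) {
        bestAlign <- max(al, bestAlign)
        bestSep <- sep
        best <- c(i, j)
      }
    }
  }
  if (map@at[best[2L]] < map@at[best[1L]]) best <- rev(best)
  lab <- channelLabels(map@grid)
  list(p1 = lab[best[1L], ], p2 = lab[best[2L], ])
}

#' Plane-fit wave propagation velocity
#'
#' Fits \code{AT(x, y) = a x + b y + c} by least squares over the valid
#' electrodes of an activation map. The gradient \code{(a, b)} (ms/mm) points
#' along propagation; the speed is the inverse gradient magnitude,
#' \code{1 / |(a, b)|}, converted to cm/s. This is the robust default
#' map-to-velocity reduction; [estimateWpvTwoPoint()] reproduces the textbook
#' two-point quotient.
#'
#' @param map an [ActivationMap-class] with >= 4 valid, non-collinear
#'   electrodes.
#' @param degenerateTol gradient magnitudes below this (ms/mm) are treated as
#'   simultaneous activation - far below any physiological value.
#' @return a [VelocityEstimate-class] with \code{method = "plane_fit"} and
#'   the RMS residual in ms.
#' @export
fitPlaneVelocity <- function(map, degenerateTol = 1e-6) {
  stopifnot(is(map, "ActivationMap"))
  idx <- which(map@valid)
  if (length(idx) < 4L)
    stop("plane fit requires at least 4 valid electrodes")
  pos <- electrodePositions(map@grid)[idx, , drop = FALSE]
  if (qr(sweep(pos, 2L, colMeans(pos)))$rank < 2L)
    stop("valid electrodes are collinear: plane fit is underdetermined")
  X <- cbind(1, pos)
  fit <- stats::lm.fit(X, map@at[idx])
  grad <- fit$coefficients[c(2L, 3L)]
  g <- sqrt(sum(grad^2))
  if (!is.finite(g) || g < degenerateTol)
    stop("degenerate wave: activation is simultaneous across the map")
  new("VelocityEstimate", beatIndex = map@beatIndex,
      wpv = CM_S_PER_MM_MS / g, method = "plane_fit",
      direction = as.numeric(grad / g), points = normalizeLabels(NULL),
      residual = sqrt(mean(fit$residuals^2)))
}

#' Accessors for VelocityEstimate
#'
#' @param x a [VelocityEstimate-class].
#' @return \code{wpv}: speed in cm/s; \code{propagationDirection}: unit
#'   vector.
#' @name VelocityEstimate-accessors
NULL

#' @rdname VelocityEstimate-accessors
#' @export
setMethod("wpv", "VelocityEstimate", function(x) x@wpv)

#' @rdname VelocityEstimate-accessors
#' @export
setMethod("propagationDirection", "VelocityEstimate", function(x) {
  x@direction
})

setMethod("show", "VelocityEstimate", function(object) {
  cat(sprintf("VelocityEstimate: beat %d, %.2f cm/s (%s)\n",
              object@beatIndex, object@wpv, object@method))
  if (object@method == "plane_fit")
    cat(sprintf("  direction (%.3f, %.3f), RMS residual %.3f ms\n",
                object@direction[1L], object@direction[2L],
                object@residual))
})

#' Restitution summary across pacing rates
#'
#' Pools per-beat velocity estimates by pacing rate and reports, per rate,
#' the mean and sample standard deviation (n - 1) of the WPV - the electrical
#' restitution curve. Healthy working hearts show WPV decreasing as the
#' pacing rate increases.
#'
#' @param estimates a named list (names = pacing rate in beats/min), each
#'   element either a list of [VelocityEstimate-class] or a numeric vector
#'   of speeds in cm/s.
#' @return data.frame with columns \code{pacingRate}, \code{muWpv},
#'   \code{sigmaWpv}, \code{nBeats}, sorted by pacing rate.
#' @examples
#' restitutionSummary(list(`100` = c(95, 105), `120` = c(78, 82)))
#' @export
restitutionSummary <- function(estimates) {
  if (!length(estimates) || is.null(names(estimates)))
    stop("estimates must be a non-empty named list (names = pacing rates)")
  rows <- lapply(names(estimates), function(nm) {
    el <- estimates[[nm]]
    v <- if (is.numeric(el)) el else vapply(el, wpv, numeric(1))
    if (!length(v)) stop("empty estimate list for rate ", nm)
    data.frame(pacingRate = as.numeric(nm), muWpv = mean(v),
               sigmaWpv = if (length(v) > 1L) stats::sd(v) else 0,
               nBeats = length(v))
  })
  out <- do.call(rbind, rows)
  out[order(out$pacingRate), , drop = FALSE]
}
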