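#' Construct an electrode grid
#'
#' @param nRows,nCols grid dimensions (>= 2 each).
#' @param spacing inter-electrode spacing in mm. The larger mapping array used
#'   with this pipeline is 11 x 11 at 5 mm; the smaller 6 x 8 array defaults
#'   to the same 5 mm (its spacing is catalogue-derived, not measured), so
#'   pass your own value if known.
#' @param badChannels malfunctioning channels as a 2-column matrix (or vector
#'   of length 2, or list of such vectors) of \code{(row, col)} labels.
#' @return an [ElectrodeGrid-class].
#' @examples
#' ElectrodeGrid(6, 8, badChannels = c(2, 6))
#' @export
ElectrodeGrid <- function(nRows, nCols, spacing = 5, badChannels = NULL) {
  bc <- normalizeLabels(badChannels)
  new("ElectrodeGrid", nRows = as.integer(nRows), nCols = as.integer(nCols),
      spacing = as.numeric(spacing), badChannels = bc)
}

# accept c(r, c), list of c(r, c), or an n x 2 matrix
normalizeLabels <- function(x) {
  if (is.null(x)) {
    m <- matrix(integer(0), ncol = 2L)
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.list(x)) {
    m <- do.call(rbind, x)
  } else if (is.numeric(x) && length(x) == 2L) {
    m <- matrix(x, ncol = 2L)
  } else {
    stop("electrode labels must be (row, col) pairs")
  }
  storage.mode(m) <- "integer"
  colnames(m) <- c("row", "col")
  m
}

#' Accessors for ElectrodeGrid
#'
#' @param x an [ElectrodeGrid-class] (or an object carrying one).
#' @return \code{nRows}/\code{nCols}: integer; \code{gridSpacing}: mm;
#'   \code{badChannels}: integer matrix of (row, col) labels;
#'   \code{electrodePositions}: numeric matrix with columns \code{x},
#'   \code{y} in mm, one row per channel in row-major order;
#'   \code{channelLabels}: integer matrix with columns \code{row},
#'   \code{col} in the same order.
#' @name ElectrodeGrid-accessors
NULL

#' @rdname ElectrodeGrid-accessors
#' @export
setMethod("nRows", "ElectrodeGrid", function(x) x@nRows)

#' @rdname ElectrodeGrid-accessors
#' @export
setMethod("nCols", "ElectrodeGrid", function(x) x@nCols)

#' @rdname ElectrodeGrid-accessors
#' @export
setMethod("gridSpacing", "ElectrodeGrid", function(x) x@spacing)

#' @rdname ElectrodeGrid-accessors
#' @export
setMethod("badChannels", "ElectrodeGrid", function(x) x@badChannels)

#' @rdname ElectrodeGrid-accessors
#' @export
setMethod("channelLabels", "ElectrodeGrid", function(x) {
  lab <- cbind(
    row = rep(seq_len(x@nRows), each = x@nCols),
    col = rep(seq_len(x@nCols), times = x@nRows)
  )
  storage.mode(lab) <- "integer"
  lab
})

#' @rdname ElectrodeGrid-accessors
#' @export
setMethod("electrodePositions", "ElectrodeGrid", function(x) {
  lab <- channelLabels(x)
  cbind(x = (lab[, "col"] - 1) * x@spacing,
        y = (lab[, "row"] - 1) * x@spacing)
})

# row-major channel index of a (row, col) label
channelIndex <- function(grid, label) {
  label <- normalizeLabels(label)
  if (any(label[, 1L] < 1L | label[, 1L] > grid@nRows |
          label[, 2L] < 1L | label[, 2L] > grid@nCols))
    stop("electrode label outside the grid")
  (label[, 1L] - 1L) * grid@nCols + label[, 2L]
}

badChannelIndices <- function(grid) {
  if (nrow(grid@badChannels) == 0L) return(integer(0))
  channelIndex(grid, grid@badChannels)
}

setMethod("show", "ElectrodeGrid", function(object) {
  cat(sprintf("ElectrodeGrid: %d x %d electrodes, %g mm spacing\n",
              object@nRows, object@nCols, object@spacing))
  nb <- nrow(object@badChannels)
  if (nb > 0L) {
    lab <- apply(object@badChannels, 1L,
                 function(p) sprintf("(%d,%d)", p[1L], p[2L]))
    cat("  bad channels:", paste(lab, collapse = ", "), "\n")
  }
})
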