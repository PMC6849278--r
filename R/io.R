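#' Save / load a recording as a single file
#'
#' The native container is R serialization (RDS): one file holding the
#' sample matrix, sampling rate, grid metadata, pacing times and - for
#' synthetic recordings - the ground-truth activation times. For
#' interoperability with other tools use [exportRecordingText()].
#'
#' @param recording a [UegRecording-class].
#' @param path file path.
#' @return \code{readUegRecording} returns the [UegRecording-class];
#'   \code{writeUegRecording} returns \code{path} invisibly.
#' @export
writeUegRecording <- function(recording, path) {
  stopifnot(is(recording, "UegRecording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname writeUegRecording
#' @export
readUegRecording <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "UegRecording"))
    stop("file does not contain a UegRecording")
  validObject(obj)
  obj
}

#' Export a recording as delimited text
#'
#' Writes one column per channel (header \code{ch_<row>_<col>}) preceded by
#' comment lines carrying the sampling rate, grid geometry, bad channels and
#' pacing times, so the file round-trips through [readRecordingText()].
#'
#' @param recording a [UegRecording-class].
#' @param path file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
exportRecordingText <- function(recording, path, sep = "\t") {
  stopifnot(is(recording, "UegRecording"))
  g <- recording@grid
  hdr <- c(
    sprintf("# fs_hz=%.10g", recording@fs),
    sprintf("# grid=%dx%d", g@nRows, g@nCols),
    sprintf("# spacing_mm=%.10g", g@spacing),
    sprintf("# bad_channels=%s",
            paste(apply(g@badChannels, 1L, paste, collapse = ","),
                  collapse = ";")),
    sprintf("# pacing_times_ms=%s",
            paste(sprintf("%.10g", recording@pacingTimes), collapse = ";")),
    sprintf("# pacing_rate_bpm=%.10g", recording@pacingRate)
  )
  lab <- channelLabels(g)
  colnames(recording@samples) <- sprintf("ch_%d_%d", lab[, 1L], lab[, 2L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(recording@samples, con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname exportRecordingText
#' @export
readRecordingText <- function(path, sep = "\t") {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  getField <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("missing header field: ", key)
    sub(paste0("^# ", key, "="), "", ln[1L])
  }
  fs <- as.numeric(getField("fs_hz"))
  dims <- as.integer(strsplit(getField("grid"), "x")[[1L]])
  spacing <- as.numeric(getField("spacing_mm"))
  bcStr <- getField("bad_channels")
  bad <- if (nzchar(bcStr)) {
    do.call(rbind, lapply(strsplit(bcStr, ";")[[1L]], function(s)
      as.integer(strsplit(s, ",")[[1L]])))
  } else NULL
  ptStr <- getField("pacing_times_ms")
  pt <- if (nzchar(ptStr)) as.numeric(strsplit(ptStr, ";")[[1L]]) else
    numeric(0)
  rate <- as.numeric(getField("pacing_rate_bpm"))
  x <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   comment.char = "#"))
  dimnames(x) <- NULL
  UegRecording(x, fs = fs,
               grid = ElectrodeGrid(dims[1L], dims[2L], spacing, bad),
               pacingTimes = pt, pacingRate = rate)
}

#' Export an activation map as a delimited text matrix
#'
#' Rows x columns matrix of activation times in ms after the stimulus, with
#' a sentinel for invalid electrodes.
#'
#' @param map an [ActivationMap-class].
#' @param path file path.
#' @param sentinel value written for invalid electrodes.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeActivationMatrix <- function(map, path, sentinel = NA, sep = "\t") {
  stopifnot(is(map, "ActivationMap"))
  m <- atMatrix(map)
  m[is.na(m)] <- sentinel
  utils::write.table(m, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
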