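#' Construct an ECoG session
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (the WIMAGINE-class implants emulated by
#'   the synthetic generator digitise at 585.6 Hz).
#' @param channelPositions optional channels x 3 electrode coordinates (mm).
#' @param windowLen decoder window length in samples; one decoder step is
#'   produced per window.
#' @param stateLabels optional factor/character of per-window movement
#'   states.
#' @param trajectoryTargets optional nWindows x 6 matrix of hand targets
#'   (left x,y,z, right x,y,z).
#' @param satisfactionLabels optional 0/1 vector per window.
#' @param updateFlags optional nWindows x 3 logical matrix (columns
#'   reinforcement, supervised, satisfaction).
#' @return an [ECoGSession-class] object.
#' @examples
#' s <- ECoGSession(matrix(rnorm(4 * 590), 4), fs = 585.6)
#' nWindows(s)
#' @export
ECoGSession <- function(signal, fs, channelPositions = NULL, windowLen = 59L,
                        stateLabels = factor(), trajectoryTargets = NULL,
                        satisfactionLabels = integer(), updateFlags = NULL) {
  if (!is.matrix(signal)) signal <- as.matrix(signal)
  if (!is.factor(stateLabels)) stateLabels <- factor(stateLabels)
  if (length(satisfactionLabels)) satisfactionLabels <- as.integer(satisfactionLabels)
  new("ECoGSession", signal = signal, fs = as.numeric(fs),
      channelPositions = channelPositions, windowLen = as.integer(windowLen),
      stateLabels = stateLabels, trajectoryTargets = trajectoryTargets,
      satisfactionLabels = as.integer(satisfactionLabels),
      updateFlags = updateFlags)
}

#' @rdname ECoGSession
#' @param x,object an `ECoGSession`.
#' @export
nChannels <- function(x) nrow(x@signal)

#' @rdname ECoGSession
#' @export
nSamples <- function(x) ncol(x@signal)

#' Number of complete decoder windows in a session
#'
#' The trailing partial window, if any, is not counted.
#' @param x an [ECoGSession-class].
#' @return integer window count, `floor(nSamples / windowLen)`.
#' @export
nWindows <- function(x) as.integer(floor(ncol(x@signal) / x@windowLen))

#' @rdname ECoGSession
#' @export
samplingRate <- function(x) x@fs

#' @rdname ECoGSession
#' @export
stateLabels <- function(x) x@stateLabels

#' @rdname ECoGSession
#' @export
channelPositions <- function(x) x@channelPositions

#' @rdname ECoGSession
#' @export
trajectoryTargets <- function(x) x@trajectoryTargets

#' @rdname ECoGSession
#' @export
satisfactionLabels <- function(x) x@satisfactionLabels

#' @rdname ECoGSession
#' @export
updateFlags <- function(x) x@updateFlags

setMethod("show", "ECoGSession", function(object) {
  cat(sprintf("ECoGSession: %d channels x %d samples @ %.1f Hz (%.1f s)\n",
              nChannels(object), nSamples(object), object@fs,
              nSamples(object) / object@fs))
  cat(sprintf("  windows: %d of %d samples", nWindows(object),
              object@windowLen))
  if (length(object@stateLabels))
    cat(sprintf("; states: %s",
                paste(levels(object@stateLabels), collapse = "/")))
  cat("\n")
  if (!is.null(object@trajectoryTargets)) cat("  trajectory targets present\n")
  if (length(object@satisfactionLabels)) cat("  satisfaction labels present\n")
  if (!is.null(object@updateFlags)) cat("  update flags present\n")
  invisible(NULL)
})

#' Select a subset of channels from a session
#'
#' Per-window annotations are unaffected; channel positions follow the
#' selection.
#'
#' @param x an [ECoGSession-class].
#' @param channels integer indices of channels to keep, in the desired
#'   order.
#' @return a new `ECoGSession`.
#' @export
selectChannels <- function(x, channels) {
  channels <- as.integer(channels)
  if (any(channels < 1L) || any(channels > nChannels(x)))
    stop("channel index out of range")
  pos <- x@channelPositions
  if (!is.null(pos)) pos <- pos[channels, , drop = FALSE]
  initialize(x, signal = x@signal[channels, , drop = FALSE],
             channelPositions = pos)
}

#' Split a session into two by window index
#'
#' Used to make a training/held-out split at a window boundary: signal,
#' labels, targets and flags are all cut at `atWindow` windows.
#'
#' @param x an [ECoGSession-class].
#' @param atWindow number of windows in the first part.
#' @return list with elements `train` and `test`, both `ECoGSession`s.
#' @export
splitSession <- function(x, atWindow) {
  nw <- nWindows(x)
  atWindow <- as.integer(atWindow)
  if (atWindow < 1L || atWindow >= nw)
    stop("atWindow must be in [1, nWindows - 1]")
  cut <- atWindow * x@windowLen
  idx1 <- seq_len(atWindow); idx2 <- seq.int(atWindow + 1L, nw)
  take <- function(samples, windows) {
    ECoGSession(x@signal[, samples, drop = FALSE], x@fs,
      channelPositions = x@channelPositions, windowLen = x@windowLen,
      stateLabels = if (length(x@stateLabels)) x@stateLabels[windows] else factor(),
      trajectoryTargets = if (!is.null(x@trajectoryTargets))
        x@trajectoryTargets[windows, , drop = FALSE] else NULL,
      satisfactionLabels = if (length(x@satisfactionLabels))
        x@satisfactionLabels[windows] else integer(),
      updateFlags = if (!is.null(x@updateFlags))
        x@updateFlags[windows, , drop = FALSE] else NULL)
  }
  list(train = take(seq_len(cut), idx1),
       test = take(seq.int(cut + 1L, nw * x@windowLen), idx2))
}
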