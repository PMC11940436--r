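#' The Morlet fundamental-frequency bank
#'
#' Fifteen fundamental frequencies from 10 to 150 Hz in steps of 10 Hz, the
#' bank over which per-frequency decoder models are trained and voted.
#'
#' @return numeric vector of 15 frequencies (Hz).
#' @export
frequencyBank <- function() seq(10, 150, by = 10)

#' The six-member "chosen" voting subset of the bank
#'
#' The default member set for six-model threshold voting: 10, 30, 50, 70,
#' 100 and 110 Hz.
#'
#' @return numeric vector of 6 frequencies (Hz).
#' @export
chosenFrequencies <- function() c(10, 30, 50, 70, 100, 110)

#' Collapse per-sample labels to per-window labels
#'
#' @param sampleLabels vector of one label per sample.
#' @param windowLen window length in samples.
#' @param mode `"last"` takes the label at each window's last sample (the
#'   default attachment rule); `"majority"` takes the window's most
#'   frequent label, ties toward the earlier-appearing label.
#' @return factor of one label per complete window.
#' @export
labelsFromSamples <- function(sampleLabels, windowLen = 59L,
                              mode = c("last", "majority")) {
  mode <- match.arg(mode)
  windowLen <- as.integer(windowLen)
  nw <- floor(length(sampleLabels) / windowLen)
  lab <- vapply(seq_len(nw), function(w) {
    block <- sampleLabels[((w - 1L) * windowLen + 1L):(w * windowLen)]
    if (mode == "last") as.character(block[windowLen])
    else names(which.max(table(factor(block, levels = unique(block)))))
  }, character(1))
  factor(lab)
}

#' Checkerboard electrode selection
#'
#' Returns the 1-based row-major indices of alternating cells of an
#' `nRows x nCols` electrode grid, starting at the first cell — the pattern
#' used to halve the channel count of a 64-electrode implant to 32 under a
#' limited radio budget.
#'
#' @param nRows,nCols grid dimensions.
#' @return integer vector of `ceiling(nRows * nCols / 2)` indices.
#' @examples
#' checkerboardSelect(2, 2)  # 1, 4
#' length(checkerboardSelect(8, 8))  # 32
#' @export
checkerboardSelect <- function(nRows, nCols) {
  if (nRows < 1 || nCols < 1) stop("grid dimensions must be positive")
  idx <- expand.grid(col = seq_len(nCols) - 1L, row = seq_len(nRows) - 1L)
  keep <- (idx$row + idx$col) %% 2L == 0L
  which(keep[order(idx$row, idx$col)])
}

#' Cut a session into consecutive decoder windows
#'
#' Non-overlapping consecutive windows of `windowLen` samples by default;
#' the trailing partial window is dropped, so with zero overlap
#' `length(out) == floor(nSamples / windowLen)`.
#'
#' @param x an [ECoGSession-class] or a channels x samples matrix.
#' @param windowLen window length in samples (59 at 585.6 Hz in the decoder's
#'   nominal configuration).
#' @param overlap samples shared by consecutive windows (0 <= overlap <
#'   windowLen); the default 0 gives the nominal non-overlapping stream.
#' @return list of channels x windowLen matrices.
#' @export
makeWindows <- function(x, windowLen = 59L, overlap = 0L) {
  sig <- if (is(x, "ECoGSession")) x@signal else as.matrix(x)
  windowLen <- as.integer(windowLen)
  overlap <- as.integer(overlap)
  if (windowLen < 1L) stop("windowLen must be >= 1")
  if (overlap < 0L || overlap >= windowLen)
    stop("overlap must lie in [0, windowLen)")
  if (windowLen > ncol(sig))
    stop("windowLen (", windowLen, ") exceeds the number of samples (",
         ncol(sig), ")")
  step <- windowLen - overlap
  starts <- seq.int(1L, ncol(sig) - windowLen + 1L, by = step)
  lapply(starts, function(s)
    sig[, s:(s + windowLen - 1L), drop = FALSE])
}

featureWindow <- function(currents, approach, windowIndex = NA_integer_,
                          f0 = NA_real_) {
  structure(currents, approach = approach, windowIndex = windowIndex,
            fundamentalFrequency = f0)
}

#' Amplitude-shift features ("Approach 1")
#'
#' Generating currents obtained by shifting each channel so its minimum
#' over the calibration reference maps to zero; values are otherwise
#' unscaled, so the features are invariant to additive per-channel offsets.
#'
#' @param window channels x samples numeric matrix (one raw window).
#' @param offsets optional per-channel reference values to subtract (a
#'   session-level calibration); by default the per-window minimum is used.
#' @return the non-negative feature matrix with attribute
#'   `approach = "shift"`.
#' @export
shiftFeatures <- function(window, offsets = NULL) {
  window <- as.matrix(window)
  if (length(window) == 0L) stop("empty window")
  if (is.null(offsets)) offsets <- apply(window, 1, min)
  out <- window - offsets
  featureWindow(pmax(out, 0), approach = "shift")
}

# cache of wavelet FFTs keyed by (f0, fs, nCycles, fftLen)
.morletCache <- new.env(parent = emptyenv())

# symmetric (reflection, no edge repeat) extension indices for positions
# k in 1-L .. n+L of a length-n signal
symIndex <- function(k, n) {
  if (n == 1L) return(rep(1L, length(k)))
  period <- 2L * n - 2L
  m <- (k - 1L) %% period
  ifelse(m < n, m + 1L, period - m + 1L)
}

morletKernel <- function(f0, fs, nCycles) {
  sigma <- nCycles / (2 * pi * f0)           # seconds
  L <- ceiling(3.5 * sigma * fs)
  t <- (-L:L) / fs
  w <- exp(2i * pi * f0 * t) * exp(-t^2 / (2 * sigma^2))
  w <- w / sum(Mod(w))                       # L1 norm: unit response scale
  list(w = w, L = L)
}

#' Squared Morlet wavelet features ("Approach 2")
#'
#' Per-channel squared magnitude of the complex Morlet wavelet convolution
#' at fundamental frequency `f0`, evaluated at every sample of the window
#' — a time-resolved band-power estimate used as generating currents.
#' Edge effects are handled by symmetric reflection of the window.
#'
#' @param window channels x samples numeric matrix (one raw window).
#' @param f0 fundamental frequency (Hz); must lie below Nyquist.
#' @param fs sampling rate (Hz).
#' @param nCycles wavelet width in cycles; the Gaussian envelope has
#'   \eqn{\sigma_t = nCycles / (2 \pi f_0)}.
#' @return the non-negative feature matrix with attributes
#'   `approach = "morlet"` and `fundamentalFrequency = f0`.
#' @export
morletFeatures <- function(window, f0, fs, nCycles = 7) {
  window <- as.matrix(window)
  if (length(window) == 0L) stop("empty window")
  if (f0 <= 0 || f0 >= fs / 2)
    stop("f0 must lie in (0, fs/2); got ", f0, " at fs = ", fs)
  n <- ncol(window)
  key <- paste(f0, fs, nCycles, n, sep = "_")
  cached <- .morletCache[[key]]
  if (is.null(cached)) {
    k <- morletKernel(f0, fs, nCycles)
    extLen <- n + 2L * k$L
    fftLen <- stats::nextn(extLen + 2L * k$L + 1L, 2)
    wpad <- complex(fftLen)
    wpad[seq_along(k$w)] <- k$w
    cached <- list(L = k$L, extLen = extLen, fftLen = fftLen,
                   Wf = stats::fft(wpad),
                   idx = symIndex(seq.int(1L - k$L, n + k$L), n))
    .morletCache[[key]] <- cached
  }
  ext <- window[, cached$idx, drop = FALSE]            # channels x extLen
  xpad <- matrix(0, cached$fftLen, nrow(window))
  xpad[seq_len(cached$extLen), ] <- t(ext)
  Y <- stats::mvfft(stats::mvfft(xpad) * cached$Wf, inverse = TRUE) /
    cached$fftLen
  # full convolution: sample s of the original window sits at offset
  # (s + L - 1) within ext, and the kernel centre adds another L
  rows <- (2L * cached$L) + seq_len(n)
  featureWindow(t(Mod(Y[rows, , drop = FALSE])^2), approach = "morlet",
                f0 = f0)
}
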