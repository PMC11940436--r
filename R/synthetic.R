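#' Planar electrode grid coordinates
#'
#' Row-major grid of electrode positions at `pitch` mm spacing in the
#' z = 0 plane, matching the geometry of a planar ECoG implant.
#'
#' @param nRows,nCols grid dimensions.
#' @param pitch inter-electrode distance (mm).
#' @return (nRows * nCols) x 3 matrix.
#' @export
electrodeGrid <- function(nRows, nCols, pitch = 4) {
  g <- expand.grid(col = seq_len(nCols) - 1L, row = seq_len(nRows) - 1L)
  cbind(x = g$col * pitch, y = g$row * pitch, z = 0)
}

#' Specification of a synthetic ECoG session
#'
#' Defines the study conditions the generator emulates: channel count and
#' grid, sampling rate, task shape (2-, 3- or 5-state), session length,
#' mean state dwell time, the carrier bands whose power is modulated by
#' state, the fractional band-power increase in active states
#' (`effectSize`), 1/f background noise amplitude, and the satisfaction
#' error rate.
#'
#' @param nChannels number of channels (grid of 8 columns).
#' @param fs sampling rate (Hz).
#' @param task `"runner"` (idle/walk), `"sixdof"` (idle/left/right hand,
#'   with 3D trajectories) or `"fivedof"` (idle plus four limb states).
#' @param minutes session length in minutes.
#' @param stateDwell mean dwell time per state bout, in windows.
#' @param carrierBands frequencies (Hz) of the state-modulated
#'   oscillations.
#' @param effectSize fractional increase of carrier band power in the
#'   active state (0 = null session).
#' @param noiseSD pink-noise amplitude (microvolts, SD).
#' @param carrierAmp baseline carrier amplitude (microvolts) on the
#'   signal-carrying channels.
#' @param signalChannels channels carrying the state signal; defaults to
#'   one quadrant of the grid so that electrode selection matters.
#' @param satisfactionErrorRate probability a window is labeled
#'   dissatisfied.
#' @param windowLen decoder window length (samples).
#' @param seed RNG seed; identical seeds give identical sessions.
#' @return a `SynthSpec` list understood by [generateSession()].
#' @export
synthSpec <- function(nChannels = 32L, fs = 585.6,
                      task = c("runner", "sixdof", "fivedof"),
                      minutes = 5, stateDwell = 20,
                      carrierBands = 30, effectSize = 1,
                      noiseSD = 20, carrierAmp = 10,
                      signalChannels = NULL,
                      satisfactionErrorRate = 0.1,
                      windowLen = 59L, seed = 1L) {
  task <- match.arg(task)
  nCols <- 8L
  nRows <- as.integer(ceiling(nChannels / nCols))
  if (is.null(signalChannels)) {
    g <- expand.grid(col = seq_len(nCols) - 1L, row = seq_len(nRows) - 1L)
    signalChannels <- which(g$col < nCols / 2 & g$row < nRows / 2)
    signalChannels <- signalChannels[signalChannels <= nChannels]
  }
  structure(list(nChannels = as.integer(nChannels), fs = fs, task = task,
                 minutes = minutes, stateDwell = stateDwell,
                 carrierBands = carrierBands, effectSize = effectSize,
                 noiseSD = noiseSD, carrierAmp = carrierAmp,
                 signalChannels = as.integer(signalChannels),
                 satisfactionErrorRate = satisfactionErrorRate,
                 windowLen = as.integer(windowLen),
                 seed = as.integer(seed), nRows = nRows, nCols = nCols),
            class = "SynthSpec")
}

taskStates <- function(task) {
  switch(task,
         runner = c("idle", "walk"),
         sixdof = c("idle", "left_hand", "right_hand"),
         fivedof = c("idle", "left_hand", "left_elbow", "right_hand",
                     "right_elbow"),
         stop("unknown task: ", task))
}

pinkNoise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  idx <- seq_len(n) - 1
  f <- pmin(idx, n - idx)               # two-sided frequency index
  f[1] <- 1
  X <- X / sqrt(f)
  X[1] <- 0
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  out / stats::sd(out)
}

smoothWalk <- function(n, span = 15) {
  w <- cumsum(stats::rnorm(n))
  k <- stats::filter(w, rep(1 / span, span), sides = 2)
  k[is.na(k)] <- 0
  as.numeric(k) / max(stats::sd(k[k != 0]), 1e-9)
}

#' Generate a synthetic ECoG session
#'
#' Per channel: 1/f (pink) background noise plus, on the signal-carrying
#' channels, band-limited carrier oscillations whose amplitude increases by
#' `sqrt(1 + effectSize)` (i.e. band power by `1 + effectSize`) when the
#' channel's associated movement state is active. For tasks with several
#' movement states, the signal channels are divided between the states so
#' the classes are spatially distinguishable. The state sequence is a
#' Markov chain with mean dwell `stateDwell` windows; trajectory targets
#' (sixdof) are smooth 3D curves active only while the matching hand moves;
#' satisfaction labels are correct-by-construction and flipped to
#' dissatisfied with probability `satisfactionErrorRate`; update flags are
#' populated per task.
#'
#' @param spec a `SynthSpec` from [synthSpec()].
#' @return an [ECoGSession-class].
#' @export
generateSession <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  n <- round(spec$minutes * 60 * spec$fs)
  if (n < spec$windowLen) stop("degenerate spec: session shorter than one window")
  nw <- floor(n / spec$windowLen)
  states <- taskStates(spec$task)
  nStates <- length(states)
  set.seed(spec$seed)

  # Markov state sequence over windows
  pStay <- max(0, 1 - 1 / spec$stateDwell)
  st <- integer(nw)
  st[1] <- sample.int(nStates, 1)
  for (w in seq_len(nw - 1L)) {
    if (stats::runif(1) < pStay) {
      st[w + 1L] <- st[w]
    } else {
      others <- setdiff(seq_len(nStates), st[w])
      st[w + 1L] <- others[sample.int(length(others), 1L)]
    }
  }
  sampleState <- c(rep(st, each = spec$windowLen),
                   rep(st[nw], n - nw * spec$windowLen))

  # assign signal channels to movement states (state 1 is idle)
  moveStates <- seq_len(nStates)[-1]
  chanGroup <- rep(moveStates, length.out = length(spec$signalChannels))

  t <- seq_len(n) / spec$fs
  boost <- sqrt(1 + spec$effectSize)
  sig <- matrix(0, spec$nChannels, n)
  for (ch in seq_len(spec$nChannels)) {
    x <- pinkNoise(n) * spec$noiseSD
    k <- match(ch, spec$signalChannels)
    if (!is.na(k)) {
      active <- sampleState == chanGroup[k]
      amp <- spec$carrierAmp * ifelse(active, boost, 1)
      for (f in spec$carrierBands)
        x <- x + amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    sig[ch, ] <- x
  }

  traj <- NULL
  if (spec$task == "sixdof") {
    traj <- matrix(0, nw, 6)
    for (h in 1:2) {                     # 1 = left hand, 2 = right hand
      on <- st == (h + 1L)
      for (axis in 1:3) {
        curve <- smoothWalk(nw)
        traj[on, (h - 1) * 3 + axis] <- curve[on]
      }
    }
  }

  sat <- as.integer(stats::runif(nw) >= spec$satisfactionErrorRate)
  flags <- matrix(FALSE, nw, 3,
                  dimnames = list(NULL, c("reinforcement", "supervised",
                                          "satisfaction")))
  flags[, "supervised"] <- TRUE
  flags[, "satisfaction"] <- TRUE
  if (spec$task == "fivedof") flags[, "reinforcement"] <- TRUE

  ECoGSession(sig, fs = spec$fs,
              channelPositions = electrodeGrid(spec$nRows, spec$nCols)[
                seq_len(spec$nChannels), , drop = FALSE],
              windowLen = spec$windowLen,
              stateLabels = factor(states[st], levels = states),
              trajectoryTargets = traj,
              satisfactionLabels = sat,
              updateFlags = flags)
}
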