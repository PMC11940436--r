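#' Build a spatially embedded small-world spiking network
#'
#' Connection strength decays exponentially with Euclidean distance:
#' `w(i,j) = w0 * exp(-d_ij / sigmaD)` for `d_ij <= dCut`, and sparse
#' long-range links beyond the cutoff are drawn with probability `pLong`
#' at the cutoff strength `w0 * exp(-dCut / sigmaD)`. Each feature channel
#' drives the neuron nearest to its electrode.
#'
#' @param positions n x 3 neuron coordinates (mm); see [neuronTemplate()].
#' @param electrodePositions m x 3 electrode coordinates (mm).
#' @param w0 base synaptic weight (at zero distance).
#' @param sigmaD exponential decay length (mm).
#' @param dCut local-connectivity cutoff distance (mm).
#' @param pLong probability of a long-range link beyond `dCut`.
#' @param seed RNG seed for the long-range links (builds are reproducible).
#' @param lif [LIFParams-class]; defaults use a -65 mV threshold, 0 ms
#'   refractory period and conventional values for the remaining constants.
#' @param stdp [STDPParams-class]; the weight ceiling defaults to `2 * w0`.
#' @param delay uniform conduction delay (ms).
#' @param synapticCharge charge (pC) per spike per unit weight.
#' @return an [SNNetwork-class].
#' @export
buildNetwork <- function(positions, electrodePositions,
                         w0 = 1, sigmaD = 10, dCut = 15, pLong = 0.01,
                         seed = 1L, lif = new("LIFParams"),
                         stdp = NULL, delay = 1, synapticCharge = 25) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("positions must contain at least one neuron")
  if (sigmaD <= 0 || dCut <= 0) stop("sigmaD and dCut must be positive")
  electrodePositions <- as.matrix(electrodePositions)
  if (is.null(stdp)) stdp <- new("STDPParams", wMax = 2 * w0)
  n <- nrow(positions)
  d <- as.matrix(stats::dist(positions))
  local <- d <= dCut
  diag(local) <- FALSE
  w <- matrix(0, n, n)
  w[local] <- w0 * exp(-d[local] / sigmaD)
  far <- which(d > dCut & !diag(n), arr.ind = TRUE)
  if (nrow(far) && pLong > 0) {
    set.seed(as.integer(seed))
    pick <- stats::runif(nrow(far)) < pLong
    w[far[pick, , drop = FALSE]] <- w0 * exp(-dCut / sigmaD)
  }
  w <- pmin(w, stdp@wMax)
  W <- as(as(Matrix::Matrix(w, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  emap <- vapply(seq_len(nrow(electrodePositions)), function(k) {
    dd <- colSums((t(positions) - electrodePositions[k, ])^2)
    which.min(dd)
  }, integer(1))
  new("SNNetwork", positions = positions, weights = W, delay = delay,
      synapticCharge = synapticCharge, lif = lif, stdp = stdp,
      electrodeMap = emap,
      state = list(v = rep(lif@eL, n), refrac = rep(0, n), t0 = 0))
}

#' Neuron positions from electrode coordinates plus filler neurons
#'
#' The default 3D template when no individual brain scan is available: one
#' neuron at each electrode position, plus `nFiller` neurons on a jittered
#' grid filling the electrode bounding box (expanded by `margin` mm).
#'
#' @param electrodePositions m x 3 coordinates (mm).
#' @param nFiller number of filler neurons.
#' @param margin bounding-box expansion (mm).
#' @param seed RNG seed for the jitter.
#' @return (m + nFiller) x 3 matrix; the first m rows are the electrode
#'   positions.
#' @export
neuronTemplate <- function(electrodePositions, nFiller = 64L, margin = 2,
                           seed = 1L) {
  electrodePositions <- as.matrix(electrodePositions)
  if (nFiller < 1L) return(electrodePositions)
  lo <- apply(electrodePositions, 2, min) - margin
  hi <- apply(electrodePositions, 2, max) + margin
  m <- ceiling(nFiller^(1 / 3))
  ax <- lapply(1:3, function(j) {
    if (hi[j] - lo[j] < 1e-9) rep((lo[j] + hi[j]) / 2, m)
    else seq(lo[j], hi[j], length.out = m)
  })
  grid <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))[seq_len(nFiller), ,
                                                            drop = FALSE]
  set.seed(as.integer(seed))
  spacing <- pmax((hi - lo) / max(m - 1, 1), 1e-3)
  jitter <- matrix(stats::runif(length(grid), -0.3, 0.3), ncol = 3) *
    rep(spacing, each = nFiller)
  out <- rbind(electrodePositions, grid + jitter)
  dimnames(out) <- NULL
  out
}

#' Read neuron or electrode coordinates from a CSV
#'
#' @param path CSV with columns x, y, z (mm), one row per neuron.
#' @return n x 3 numeric matrix.
#' @export
readCoordinatesCSV <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(tab)))
    stop("coordinate CSV needs columns x, y, z")
  as.matrix(tab[, c("x", "y", "z")])
}

#' Simulate one decoder window of the spiking network
#'
#' Forward-Euler integration of the LIF dynamics at step `dt`, driven by
#' the feature currents: one feature sample is held piecewise-constant for
#' `duration / ncol(currents)` ms at each electrode-mapped neuron, scaled
#' by `gain` (pA per feature unit). Membrane state persists across
#' consecutive windows: the returned network carries the final state.
#'
#' @param net an [SNNetwork-class].
#' @param currents feature matrix, one row per feature channel (must match
#'   the electrode count), in feature units.
#' @param gain pA per feature unit.
#' @param duration window duration (ms); defaults to 59 samples at
#'   585.6 Hz, about 100.75 ms.
#' @return list with `record` (a [SpikeRecord-class]) and `net` (the
#'   network with updated membrane state).
#' @export
simulateWindow <- function(net, currents, gain = 1,
                           duration = 59 * 1000 / 585.6) {
  currents <- as.matrix(currents)
  if (nrow(currents) != length(net@electrodeMap))
    stop("currents has ", nrow(currents), " channels but the network maps ",
         length(net@electrodeMap), " electrodes")
  if (duration <= 0) stop("duration must be positive")
  Wt <- Matrix::t(net@weights)
  lif <- net@lif
  res <- .lifSimulate(net@state$v, net@state$refrac,
                      Wt@p, Wt@i, Wt@x,
                      currents * gain, net@electrodeMap,
                      duration / ncol(currents), duration,
                      lif@vTh, lif@eL, lif@vReset, lif@tauM, lif@cM,
                      lif@tRef, lif@dt, net@delay, net@synapticCharge)
  n <- nrow(net@positions)
  spk <- split(res$time, factor(res$neuron, levels = seq_len(n)))
  names(spk) <- NULL
  record <- new("SpikeRecord", spikes = spk, windowDuration = duration)
  net@state <- list(v = res$v, refrac = res$refrac,
                    t0 = net@state$t0 + duration)
  list(record = record, net = net)
}

#' Apply one window of STDP adaptation
#'
#' Additive nearest-neighbour pair-based STDP over the window's spikes:
#' for every synapse, each postsynaptic spike pairs with the nearest
#' earlier presynaptic spike (potentiation
#' \eqn{+\lambda w_{max} e^{-\Delta t / \tau_+}}) and each presynaptic
#' spike with the nearest earlier postsynaptic spike (depression scaled by
#' the asymmetry factor). Weights are clipped to `[0, wMax]`; structural
#' zeros (absent synapses) never change.
#'
#' @param net an [SNNetwork-class].
#' @param record the [SpikeRecord-class] produced on `net`.
#' @return the network with updated weights.
#' @export
stdpStep <- function(net, record) {
  if (net@stdp@lambdaRate == 0) return(net)
  counts <- lengths(record@spikes)
  if (sum(counts) == 0L) return(net)
  offsets <- c(0L, cumsum(counts))
  W <- net@weights
  newx <- .stdpUpdate(W@p, W@i, W@x,
                      unlist(record@spikes, use.names = FALSE),
                      as.integer(offsets),
                      net@stdp@lambdaRate, net@stdp@tauPlus,
                      net@stdp@tauMinus, net@stdp@asymmetry, net@stdp@wMax)
  W@x <- newx
  net@weights <- W
  net
}

#' Per-neuron spike-rate features of one window
#'
#' The spiking-frequency readout: each selected neuron's spike count
#' divided by the window duration, in Hz.
#'
#' @param record a [SpikeRecord-class].
#' @param selected neuron indices to read out (typically the
#'   electrode-mapped neurons).
#' @return numeric vector of rates (Hz).
#' @export
spikeRateFeatures <- function(record, selected) {
  if (record@windowDuration <= 0) stop("window duration must be positive")
  selected <- as.integer(selected)
  if (any(selected < 1L) || any(selected > length(record@spikes)))
    stop("selected neuron index out of range")
  lengths(record@spikes[selected]) / (record@windowDuration / 1000)
}

#' Reset a network's persistent membrane state
#'
#' Returns the network with membrane potentials back at rest, refractory
#' clocks cleared and the window clock at zero; learned weights are kept.
#' By default state persists across windows (continuous adaptation), so
#' this is only needed to decouple runs explicitly.
#'
#' @param net an [SNNetwork-class].
#' @return the reset network.
#' @export
resetNetworkState <- function(net) {
  n <- nrow(net@positions)
  net@state <- list(v = rep(net@lif@eL, n), refrac = rep(0, n), t0 = 0)
  net
}

#' Map standardised features to generating currents
#'
#' Features are z-scored per channel (with the supplied calibration mean
#' and sd), clipped to `[-clip, clip]`, offset by `bias` and scaled by
#' `gain` to picoamperes; negative drives are clipped to zero. With the
#' default LIF constants the rheobase is 125 pA, so `gain = 25` pA and
#' `bias = 5.1` put a median (z = 0) feature just above rheobase, around
#' 20-30 Hz in an isolated neuron, leaving headroom in both directions.
#'
#' @param features feature matrix (channels x samples).
#' @param center,scale per-channel calibration mean and sd.
#' @param gain pA per standardised feature unit.
#' @param bias standardised offset added before scaling.
#' @param clip symmetric z-score clip.
#' @return current matrix (pA), same shape as `features`.
#' @export
featuresToCurrents <- function(features, center, scale, gain = 25,
                               bias = 5.1, clip = 4) {
  scale <- ifelse(scale > 1e-12, scale, 1)
  z <- (features - center) / scale
  z <- pmin(pmax(z, -clip), clip)
  pmax(gain * (z + bias), 0)
}

#' Save / load a network snapshot as portable text
#'
#' A single plain-text file: key=value parameter lines, a `positions`
#' block, and the nonzero weights as (row, col, weight) triplets.
#'
#' @param net an [SNNetwork-class].
#' @param path output path.
#' @return `path` invisibly (`saveNetwork`); the network (`loadNetwork`).
#' @export
saveNetwork <- function(net, path) {
  lif <- net@lif; stdp <- net@stdp
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#mcdecode-snn-v1",
    sprintf("param %s %.17g", c("vTh", "eL", "vReset", "tauM", "cM", "tRef",
                                "dt", "lambdaRate", "tauPlus", "tauMinus",
                                "asymmetry", "wMax", "delay",
                                "synapticCharge"),
            c(lif@vTh, lif@eL, lif@vReset, lif@tauM, lif@cM, lif@tRef,
              lif@dt, stdp@lambdaRate, stdp@tauPlus, stdp@tauMinus,
              stdp@asymmetry, stdp@wMax, net@delay, net@synapticCharge)),
    paste("electrodeMap", paste(net@electrodeMap, collapse = " ")),
    sprintf("position %.17g %.17g %.17g", net@positions[, 1],
            net@positions[, 2], net@positions[, 3])), con)
  trip <- Matrix::summary(net@weights)
  writeLines(sprintf("weight %d %d %.17g", trip$i, trip$j, trip$x), con)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#mcdecode-snn-v1")
    stop("not a network snapshot: ", path)
  getv <- function(tag) {
    sel <- startsWith(lines, paste0(tag, " "))
    do.call(rbind, lapply(strsplit(lines[sel], " ", fixed = TRUE), function(f)
      as.numeric(f[-1])))
  }
  pv <- lines[startsWith(lines, "param ")]
  pf <- do.call(rbind, strsplit(pv, " ", fixed = TRUE))
  params <- stats::setNames(as.numeric(pf[, 3]), pf[, 2])
  pos <- getv("position")
  trip <- getv("weight")
  n <- nrow(pos)
  W <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(n, n))
  emap <- as.integer(strsplit(lines[startsWith(lines, "electrodeMap ")],
                              " ")[[1]][-1])
  pv <- function(k) unname(params[k])
  lif <- new("LIFParams", vTh = pv("vTh"), eL = pv("eL"),
             vReset = pv("vReset"), tauM = pv("tauM"),
             cM = pv("cM"), tRef = pv("tRef"), dt = pv("dt"))
  stdp <- new("STDPParams", lambdaRate = pv("lambdaRate"),
              tauPlus = pv("tauPlus"), tauMinus = pv("tauMinus"),
              asymmetry = pv("asymmetry"), wMax = pv("wMax"))
  new("SNNetwork", positions = pos,
      weights = as(W, "CsparseMatrix"), delay = unname(params["delay"]),
      synapticCharge = unname(params["synapticCharge"]), lif = lif,
      stdp = stdp, electrodeMap = emap,
      state = list(v = rep(unname(params["eL"]), n), refrac = rep(0, n),
                   t0 = 0))
}

setMethod("show", "SNNetwork", function(object) {
  cat(sprintf("SNNetwork: %d neurons, %d synapses, %d electrodes mapped\n",
              nrow(object@positions), Matrix::nnzero(object@weights),
              length(object@electrodeMap)))
  cat(sprintf("  LIF: vTh %.1f mV, tauM %.1f ms, tRef %.1f ms, dt %.2f ms\n",
              object@lif@vTh, object@lif@tauM, object@lif@tRef,
              object@lif@dt))
  cat(sprintf("  STDP: lambda %.4g, wMax %.3g\n",
              object@stdp@lambdaRate, object@stdp@wMax))
  invisible(NULL)
})
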