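#' @import methods
#' @importFrom Matrix sparseMatrix Matrix t nnzero
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ECoGSession: a multichannel ECoG recording with per-window annotations
#'
#' Container for a channels x samples signal matrix together with the
#' acquisition sampling rate, 3D electrode coordinates and the per-window
#' decoder annotations (movement-state labels, optional 3D hand-trajectory
#' targets, optional satisfaction labels and optional update flags).
#' Windows are consecutive non-overlapping blocks of `windowLen` samples;
#' all per-window slots are indexed by window, not by sample.
#'
#' @slot signal numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelPositions channels x 3 matrix of electrode coordinates (mm),
#'   or NULL when unknown.
#' @slot windowLen decoder window length in samples (59 by default, i.e.
#'   about 100.8 ms at 585.6 Hz).
#' @slot stateLabels factor of length `nWindows(x)` (or length 0 when
#'   unlabeled): the movement state of each window.
#' @slot trajectoryTargets nWindows x 6 matrix of hand-trajectory targets
#'   (left x,y,z then right x,y,z), or NULL.
#' @slot satisfactionLabels integer vector (0/1) per window, or length 0.
#' @slot updateFlags nWindows x 3 logical matrix with columns
#'   `reinforcement`, `supervised`, `satisfaction`, or NULL. The columns
#'   gate, per window, the reinforcement update of the state head, the
#'   supervised RLS update of the motor heads, and the RLS update of the
#'   satisfaction head.
#' @exportClass ECoGSession
setClass("ECoGSession",
  representation(
    signal = "matrix",
    fs = "numeric",
    channelPositions = "matrixOrNULL",
    windowLen = "integer",
    stateLabels = "factor",
    trajectoryTargets = "matrixOrNULL",
    satisfactionLabels = "integer",
    updateFlags = "matrixOrNULL"
  )
)

setValidity("ECoGSession", function(object) {
  msg <- character()
  if (!is.numeric(object@signal)) msg <- c(msg, "signal must be numeric")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@windowLen) != 1L || object@windowLen < 1L)
    msg <- c(msg, "windowLen must be a positive integer")
  nw <- floor(ncol(object@signal) / object@windowLen)
  if (!is.null(object@channelPositions)) {
    if (nrow(object@channelPositions) != nrow(object@signal) ||
        ncol(object@channelPositions) != 3L)
      msg <- c(msg, "channelPositions must be n_channels x 3")
  }
  if (length(object@stateLabels) > 0L && length(object@stateLabels) != nw)
    msg <- c(msg, sprintf("stateLabels length (%d) must equal the number of windows (%d)",
                          length(object@stateLabels), nw))
  if (!is.null(object@trajectoryTargets)) {
    if (nrow(object@trajectoryTargets) != nw || ncol(object@trajectoryTargets) != 6L)
      msg <- c(msg, "trajectoryTargets must be n_windows x 6")
  }
  if (length(object@satisfactionLabels) > 0L) {
    if (length(object@satisfactionLabels) != nw)
      msg <- c(msg, "satisfactionLabels length must equal the number of windows")
    if (!all(object@satisfactionLabels %in% c(0L, 1L, NA_integer_)))
      msg <- c(msg, "satisfactionLabels must be 0/1")
  }
  if (!is.null(object@updateFlags)) {
    if (nrow(object@updateFlags) != nw || ncol(object@updateFlags) != 3L)
      msg <- c(msg, "updateFlags must be n_windows x 3")
  }
  if (length(msg)) msg else TRUE
})

#' LIFParams: leaky integrate-and-fire neuron parameters
#'
#' Membrane dynamics follow
#' \deqn{dV_m/dt = -(V_m - E_L)/\tau_m + (I_{syn} + I_e)/C_m}
#' a spike is emitted when \eqn{V_m \ge V_{th}}, after which the membrane is
#' clamped at `vReset` for the refractory period `tRef`.
#'
#' @slot vTh spike threshold (mV).
#' @slot eL resting potential (mV).
#' @slot vReset post-spike reset potential (mV).
#' @slot tauM membrane time constant (ms).
#' @slot cM membrane capacitance (pF).
#' @slot tRef refractory period (ms).
#' @slot dt integration step (ms).
#' @exportClass LIFParams
setClass("LIFParams",
  representation(vTh = "numeric", eL = "numeric", vReset = "numeric",
                 tauM = "numeric", cM = "numeric", tRef = "numeric",
                 dt = "numeric"),
  prototype(vTh = -65, eL = -70, vReset = -70, tauM = 10, cM = 250,
            tRef = 0, dt = 0.1)
)

setValidity("LIFParams", function(object) {
  msg <- character()
  if (object@vTh <= object@vReset) msg <- c(msg, "vTh must exceed vReset")
  if (object@tauM <= 0) msg <- c(msg, "tauM must be positive")
  if (object@cM <= 0) msg <- c(msg, "cM must be positive")
  if (object@tRef < 0) msg <- c(msg, "tRef must be non-negative")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' STDPParams: pair-based spike-timing-dependent plasticity parameters
#'
#' Additive nearest-neighbour STDP: a pre-before-post pair separated by
#' \eqn{\Delta t} potentiates by \eqn{\lambda w_{max} e^{-\Delta t/\tau_+}},
#' a post-before-pre pair depresses by
#' \eqn{-A \lambda w_{max} e^{-\Delta t/\tau_-}} where `A` is the
#' depression/potentiation asymmetry; weights are clipped to
#' \eqn{[0, w_{max}]}.
#'
#' @slot lambdaRate STDP learning rate (dimensionless).
#' @slot tauPlus potentiation trace time constant (ms).
#' @slot tauMinus depression trace time constant (ms).
#' @slot asymmetry ratio of depression to potentiation amplitude.
#' @slot wMax weight ceiling.
#' @exportClass STDPParams
setClass("STDPParams",
  representation(lambdaRate = "numeric", tauPlus = "numeric",
                 tauMinus = "numeric", asymmetry = "numeric",
                 wMax = "numeric"),
  prototype(lambdaRate = 0.001, tauPlus = 20, tauMinus = 20,
            asymmetry = 1.05, wMax = 2)
)

setValidity("STDPParams", function(object) {
  msg <- character()
  if (object@lambdaRate < 0) msg <- c(msg, "lambdaRate must be >= 0")
  if (object@tauPlus <= 0 || object@tauMinus <= 0)
    msg <- c(msg, "trace time constants must be positive")
  if (object@wMax <= 0) msg <- c(msg, "wMax must be positive")
  if (length(msg)) msg else TRUE
})

#' SNNetwork: a spatially embedded spiking network
#'
#' Holds the 3D neuron coordinates, the sparse plastic weight matrix
#' (`weights[i, j]` is the synapse from neuron i to neuron j), the LIF and
#' STDP parameters, the electrode-to-neuron mapping and the persistent
#' membrane state carried across consecutive windows.
#'
#' @slot positions n x 3 neuron coordinates (mm).
#' @slot weights sparse dgCMatrix of synaptic strengths in `[0, wMax]`,
#'   zero diagonal; structural zeros are absent synapses and never learn.
#' @slot delay uniform conduction delay (ms) applied to every synapse.
#' @slot synapticCharge charge (pC) transferred per spike per unit weight;
#'   a presynaptic spike deflects the postsynaptic membrane by
#'   `weight * synapticCharge / cM` mV after `delay` ms.
#' @slot lif [LIFParams-class] membrane parameters.
#' @slot stdp [STDPParams-class] plasticity parameters.
#' @slot electrodeMap integer vector: for each feature channel, the index of
#'   the neuron it drives.
#' @slot state list with persistent simulator state: membrane potentials `v`
#'   (mV), remaining refractory times `refrac` (ms), and `t0`, the absolute
#'   time (ms) at which the next window starts.
#' @exportClass SNNetwork
setClass("SNNetwork",
  representation(
    positions = "matrix",
    weights = "dgCMatrix",
    delay = "numeric",
    synapticCharge = "numeric",
    lif = "LIFParams",
    stdp = "STDPParams",
    electrodeMap = "integer",
    state = "list"
  )
)

setValidity("SNNetwork", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (n < 1L) msg <- c(msg, "network must contain at least one neuron")
  if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be n x 3")
  if (nrow(object@weights) != n || ncol(object@weights) != n)
    msg <- c(msg, "weights must be n x n")
  if (any(Matrix::diag(object@weights) != 0))
    msg <- c(msg, "self-connections are not allowed")
  if (any(object@weights@x < 0) || any(object@weights@x > object@stdp@wMax + 1e-12))
    msg <- c(msg, "weights must lie in [0, wMax]")
  if (length(object@electrodeMap) &&
      (any(object@electrodeMap < 1L) || any(object@electrodeMap > n)))
    msg <- c(msg, "electrodeMap indices out of range")
  if (object@delay < 0) msg <- c(msg, "delay must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SpikeRecord: spikes emitted during one simulated window
#'
#' @slot spikes list of numeric vectors, one per neuron, of sorted spike
#'   times (ms) relative to the window start, each in
#'   `[0, windowDuration)`.
#' @slot windowDuration duration of the simulated window (ms).
#' @exportClass SpikeRecord
setClass("SpikeRecord",
  representation(spikes = "list", windowDuration = "numeric")
)

setValidity("SpikeRecord", function(object) {
  msg <- character()
  if (object@windowDuration <= 0)
    msg <- c(msg, "windowDuration must be positive")
  bad <- vapply(object@spikes, function(s)
    length(s) && (is.unsorted(s) || min(s) < 0 || max(s) >= object@windowDuration),
    logical(1))
  if (any(bad)) msg <- c(msg, "spike times must be sorted within [0, windowDuration)")
  if (length(msg)) msg else TRUE
})

#' ReadoutHead: one linear ESN readout with online-learning state
#'
#' A readout maps the concatenated reservoir-and-input vector
#' `x = [R; in]` to `out = Wout %*% x`. `P` is the inverse-correlation
#' matrix of recursive least squares; `E` is the eligibility trace of the
#' reinforcement rule.
#'
#' @slot Wout n_outputs x (N+K) output weights.
#' @slot P (N+K) x (N+K) RLS inverse-correlation matrix.
#' @slot forgetting RLS forgetting factor in (0, 1].
#' @slot E eligibility trace, same shape as Wout.
#' @slot alpha reinforcement learning rate.
#' @slot delta eligibility-trace decay rate in `[0, 1]`.
#' @exportClass ReadoutHead
setClass("ReadoutHead",
  representation(Wout = "matrix", P = "matrix", forgetting = "numeric",
                 E = "matrix", alpha = "numeric", delta = "numeric")
)

setValidity("ReadoutHead", function(object) {
  msg <- character()
  d <- ncol(object@Wout)
  if (nrow(object@P) != d || ncol(object@P) != d)
    msg <- c(msg, "P must be (N+K) x (N+K)")
  if (!isTRUE(all.equal(object@P, t(object@P), tolerance = 1e-6)))
    msg <- c(msg, "P must be symmetric")
  if (any(dim(object@E) != dim(object@Wout)))
    msg <- c(msg, "E must match Wout's shape")
  if (object@forgetting <= 0 || object@forgetting > 1)
    msg <- c(msg, "forgetting must be in (0, 1]")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@delta < 0 || object@delta > 1)
    msg <- c(msg, "delta must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ESNModel: an Echo State Network with multiple linear readout heads
#'
#' Reservoir update:
#' \deqn{R(t) = (1-a) R(t-1) + a \tanh(W_{in} in(t) + W_{res} R(t-1))}
#' with `Wres` sparse random and rescaled to spectral radius below one, so
#' that the reservoir forgets its initial condition (echo-state property).
#'
#' @slot Win N x K input weight matrix.
#' @slot Wres N x N sparse reservoir weight matrix.
#' @slot a leaking rate in (0, 1].
#' @slot R current reservoir state (length N).
#' @slot heads named list of [ReadoutHead-class] objects (e.g. `state`,
#'   `trajectory`, `satisfaction`).
#' @slot rho spectral radius `Wres` was scaled to.
#' @exportClass ESNModel
setClass("ESNModel",
  representation(Win = "matrix", Wres = "dgCMatrix", a = "numeric",
                 R = "numeric", heads = "list", rho = "numeric")
)

setValidity("ESNModel", function(object) {
  msg <- character()
  N <- nrow(object@Win)
  if (nrow(object@Wres) != N || ncol(object@Wres) != N)
    msg <- c(msg, "Wres must be N x N")
  if (length(object@R) != N) msg <- c(msg, "R must have length N")
  if (object@a <= 0 || object@a > 1) msg <- c(msg, "a must be in (0, 1]")
  if (length(object@rho) && object@rho >= 1)
    msg <- c(msg, "spectral radius must be below 1")
  d <- N + ncol(object@Win)
  ok <- vapply(object@heads, function(h) ncol(h@Wout) == d, logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "every head must have column dimension N+K")
  if (length(msg)) msg else TRUE
})

#' MCDModel: a complete motor-control-decoder model
#'
#' Bundles the spiking feature-extraction network, the ESN decoder, the
#' frozen feature-standardisation statistics and the run configuration of
#' one frequency-bank member.
#'
#' @slot snn [SNNetwork-class] feature extractor.
#' @slot esn [ESNModel-class] decoder.
#' @slot featureStats list with per-channel `mean` and `sd` of the
#'   generating-current features, frozen after calibration, plus
#'   `calibrated` flag and the running accumulators used during
#'   calibration.
#' @slot config list of run parameters (task, approach, frequency, gains,
#'   seeds); see [runConfig()].
#' @exportClass MCDModel
setClass("MCDModel",
  representation(snn = "SNNetwork", esn = "ESNModel",
                 featureStats = "list", config = "list")
)
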