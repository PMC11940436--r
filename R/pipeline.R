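#' Run configuration for one decoder model
#'
#' Collects every tunable of one frequency-bank member: task shape,
#' feature approach and fundamental frequency, window length, the SNN and
#' ESN hyper-parameters, the current-mapping gains and the seed.
#'
#' @param task `"runner"` (2 states), `"sixdof"` (3 states + trajectory)
#'   or `"fivedof"` (5 states).
#' @param approach `"morlet"` or `"shift"` feature extraction.
#' @param frequency Morlet fundamental frequency (Hz); ignored for shift.
#' @param windowLen decoder window length (samples).
#' @param nCycles Morlet width in cycles.
#' @param gain,bias,clip current mapping, see [featuresToCurrents()].
#' @param calibWindows number of leading windows used to freeze the
#'   feature- and spike-rate-standardisation statistics.
#' @param standardizeRates z-score the spike-rate features per channel
#'   (with calibration statistics) before the ESN input; when `FALSE` the
#'   raw rates are divided by `rateNorm`.
#' @param rateNorm spike-rate normalisation (Hz) used when
#'   `standardizeRates = FALSE`.
#' @param snn named list overriding [buildNetwork()] arguments (`w0`,
#'   `sigmaD`, `dCut`, `pLong`, `nFiller`, `delay`, `synapticCharge`).
#' @param lif named list overriding [LIFParams-class] defaults.
#' @param stdp named list overriding [STDPParams-class] defaults.
#' @param esn named list overriding [esnInit()] and [readoutHead()]
#'   arguments (`N`, `a`, `sparsity`, `rho`, `inputScale`, `epsilon`,
#'   `forgetting`, `alpha`, `delta`).
#' @param rlHeads heads the reinforcement rule applies to; `"state"` by
#'   default, extendable to `c("state", "trajectory")`.
#' @param seed integer seed controlling every random draw of the build.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(task = c("runner", "sixdof", "fivedof"),
                      approach = c("morlet", "shift"), frequency = 30,
                      windowLen = 59L, nCycles = 7, gain = 25, bias = 5.1,
                      clip = 4, calibWindows = 30L, standardizeRates = TRUE,
                      rateNorm = 100, snn = list(), lif = list(),
                      stdp = list(), esn = list(), rlHeads = "state",
                      seed = 1L) {
  task <- match.arg(task)
  approach <- match.arg(approach)
  if (approach == "morlet" && !frequency %in% frequencyBank())
    warning("frequency ", frequency, " Hz is outside the standard bank")
  snnDef <- list(w0 = 1, sigmaD = 10, dCut = 15, pLong = 0.01,
                 nFiller = 64L, delay = 1, synapticCharge = 25)
  esnDef <- list(N = 1000L, a = 0.5, sparsity = 0.5, rho = 0.95,
                 inputScale = 0.1, epsilon = 10, forgetting = 1,
                 alpha = 1e-3, delta = 0.9)
  structure(list(task = task, approach = approach, frequency = frequency,
                 windowLen = as.integer(windowLen), nCycles = nCycles,
                 gain = gain, bias = bias, clip = clip,
                 calibWindows = as.integer(calibWindows),
                 standardizeRates = standardizeRates, rateNorm = rateNorm,
                 rlHeads = rlHeads,
                 snn = utils::modifyList(snnDef, snn),
                 lif = lif, stdp = stdp,
                 esn = utils::modifyList(esnDef, esn),
                 stateLevels = taskStates(task),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' The file's top-level keys mirror [runConfig()]'s arguments (`task`,
#' `approach`, `frequency`, `windowLen`, `gain`, ...), with `snn`, `lif`,
#' `stdp` and `esn` as nested blocks. Unknown keys are rejected. Note that
#' YAML 1.1 reads a bare `N` as a boolean, so the reservoir-size key must
#' be quoted: `"N": 2000`.
#'
#' @param path YAML file path.
#' @return a `RunConfig` list.
#' @export
loadRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

computeFeatures <- function(config, window, fs) {
  if (config$approach == "shift") shiftFeatures(window)
  else morletFeatures(window, f0 = config$frequency, fs = fs,
                      nCycles = config$nCycles)
}

#' Build a fresh decoder model for a session's electrode layout
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param channelPositions n_channels x 3 electrode coordinates (mm).
#' @return an [MCDModel-class] with uncalibrated feature statistics.
#' @export
newModel <- function(config, channelPositions) {
  stopifnot(inherits(config, "RunConfig"))
  channelPositions <- as.matrix(channelPositions)
  lif <- do.call(new, c(list("LIFParams"), config$lif))
  stdpArgs <- config$stdp
  if (is.null(stdpArgs$wMax)) stdpArgs$wMax <- 2 * config$snn$w0
  stdp <- do.call(new, c(list("STDPParams"), stdpArgs))
  pos <- neuronTemplate(channelPositions, nFiller = config$snn$nFiller,
                        seed = config$seed)
  snn <- buildNetwork(pos, channelPositions,
                      w0 = config$snn$w0, sigmaD = config$snn$sigmaD,
                      dCut = config$snn$dCut, pLong = config$snn$pLong,
                      seed = config$seed, lif = lif, stdp = stdp,
                      delay = config$snn$delay,
                      synapticCharge = config$snn$synapticCharge)
  e <- config$esn
  esn <- esnInit(e$N, K = nrow(channelPositions), a = e$a,
                 sparsity = e$sparsity, rho = e$rho,
                 inputScale = e$inputScale, seed = config$seed)
  nStates <- length(config$stateLevels)
  esn <- addHead(esn, "state", nStates, epsilon = e$epsilon,
                 forgetting = e$forgetting, alpha = e$alpha, delta = e$delta)
  if (config$task == "sixdof")
    esn <- addHead(esn, "trajectory", 6L, epsilon = e$epsilon,
                   forgetting = e$forgetting, alpha = e$alpha,
                   delta = e$delta)
  esn <- addHead(esn, "satisfaction", 2L, epsilon = e$epsilon,
                 forgetting = e$forgetting, alpha = e$alpha, delta = e$delta)
  new("MCDModel", snn = snn, esn = esn,
      featureStats = list(calibrated = FALSE, mean = NULL, sd = NULL),
      config = unclass(config)[c("task", "approach", "frequency",
                                 "windowLen", "nCycles", "gain", "bias",
                                 "clip", "calibWindows", "standardizeRates",
                                 "rateNorm", "rlHeads", "stateLevels",
                                 "seed")])
}

oneHot <- function(index, n) { v <- numeric(n); v[index] <- 1; v }

#' Pseudo-online decoding and training loop
#'
#' Runs the full per-window chain — features, spiking-network simulation,
#' continuous STDP adaptation, spike-rate readout, reservoir update,
#' per-head linear readout, argmax decoding — over every window of the
#' session, in order. When `train = TRUE` the per-window update flags gate
#' the learning rules: the supervised flag triggers RLS on the state head
#' (and trajectory head when present), the satisfaction flag triggers RLS
#' on the satisfaction head, and the reinforcement flag applies the
#' satisfaction-gated reinforcement rule to the state head, using the
#' ground-truth satisfaction label when present and the decoded one
#' otherwise. STDP adapts continuously regardless of the flags.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param session an [ECoGSession-class]; channel count must match the
#'   model's electrode map.
#' @param model optional [MCDModel-class] to continue from (e.g. a trained
#'   model applied to held-out data); a fresh model is built when `NULL`.
#' @param train logical: apply the flag-gated readout updates. With
#'   `train = FALSE` the readouts stay fixed and only STDP adapts.
#' @return list with `steps` (a data.frame of decoded steps: window index,
#'   state, 6 trajectory coordinates, satisfaction) and `model` (the
#'   updated model).
#' @export
runOnline <- function(config, session, model = NULL, train = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(model)) model <- newModel(config, session@channelPositions)
  windows <- makeWindows(session, config$windowLen)
  nw <- length(windows)
  fs <- session@fs
  duration <- config$windowLen / fs * 1000

  if (!isTRUE(model@featureStats$calibrated)) {
    ncal <- min(config$calibWindows, nw)
    calFeat <- lapply(windows[seq_len(ncal)], function(w)
      computeFeatures(config, w, fs))
    flat <- do.call(cbind, calFeat)
    stats <- list(calibrated = TRUE, mean = rowMeans(flat),
                  sd = apply(flat, 1, stats::sd),
                  rateMean = NULL, rateSd = NULL)
    if (isTRUE(config$standardizeRates)) {
      # throwaway pass over the calibration windows: the main loop replays
      # the same windows from the same initial state, so the observed rates
      # are identical and the statistics are causal
      calSnn <- model@snn
      calRates <- matrix(0, ncal, length(calSnn@electrodeMap))
      for (w in seq_len(ncal)) {
        cur <- featuresToCurrents(calFeat[[w]], stats$mean, stats$sd,
                                  gain = config$gain, bias = config$bias,
                                  clip = config$clip)
        sim <- simulateWindow(calSnn, cur, gain = 1, duration = duration)
        calSnn <- stdpStep(sim$net, sim$record)
        calRates[w, ] <- spikeRateFeatures(sim$record, calSnn@electrodeMap)
      }
      stats$rateMean <- colMeans(calRates)
      stats$rateSd <- pmax(apply(calRates, 2, stats::sd), 1e-6)
    }
    model@featureStats <- stats
  }

  snn <- model@snn
  esn <- model@esn
  levelsAll <- model@config$stateLevels
  labels <- session@stateLabels
  flags <- session@updateFlags
  hasTraj <- "trajectory" %in% names(esn@heads)

  stateOut <- integer(nw)
  trajOut <- matrix(0, nw, 6)
  satOut <- integer(nw)

  for (w in seq_len(nw)) {
    feat <- computeFeatures(config, windows[[w]], fs)
    cur <- featuresToCurrents(feat, model@featureStats$mean,
                              model@featureStats$sd, gain = config$gain,
                              bias = config$bias, clip = config$clip)
    sim <- simulateWindow(snn, cur, gain = 1, duration = duration)
    snn <- stdpStep(sim$net, sim$record)
    rates <- spikeRateFeatures(sim$record, snn@electrodeMap)
    input <- if (isTRUE(model@config$standardizeRates))
      (rates - model@featureStats$rateMean) / model@featureStats$rateSd
    else rates / model@config$rateNorm
    esn <- esnStep(esn, input)
    x <- c(esn@R, input)

    stateScores <- esnOutput(esn, "state", input)
    stateOut[w] <- decodeState(stateScores)
    if (hasTraj) trajOut[w, ] <- esnOutput(esn, "trajectory", input)
    satScores <- esnOutput(esn, "satisfaction", input)
    satOut[w] <- decodeSatisfaction(satScores)

    if (train) {
      fl <- if (!is.null(flags)) flags[w, ] else
        c(reinforcement = FALSE, supervised = length(labels) > 0,
          satisfaction = FALSE)
      if (isTRUE(unname(fl["supervised"]))) {
        if (length(labels) == 0L)
          stop("window ", w, " is flagged for supervised update but the ",
               "session has no state labels")
        target <- oneHot(match(as.character(labels[w]), levelsAll),
                         length(levelsAll))
        esn@heads$state <- rlsUpdate(esn@heads$state, x, target)
        if (hasTraj && !is.null(session@trajectoryTargets))
          esn@heads$trajectory <- rlsUpdate(esn@heads$trajectory, x,
                                            session@trajectoryTargets[w, ])
      }
      if (isTRUE(unname(fl["satisfaction"])) &&
          length(session@satisfactionLabels)) {
        starget <- oneHot(session@satisfactionLabels[w] + 1L, 2L)
        esn@heads$satisfaction <- rlsUpdate(esn@heads$satisfaction, x,
                                            starget)
      }
      if (isTRUE(unname(fl["reinforcement"]))) {
        satSignal <- if (length(session@satisfactionLabels))
          session@satisfactionLabels[w] else satOut[w]
        outs <- list(state = stateScores, trajectory = trajOut[w, ],
                     satisfaction = satScores)
        for (hn in intersect(model@config$rlHeads, names(esn@heads)))
          esn@heads[[hn]] <- rlUpdate(esn@heads[[hn]], x, outs[[hn]],
                                      satSignal)
      }
    }
  }

  model@snn <- snn
  model@esn <- esn
  steps <- data.frame(window = seq_len(nw),
                      state = factor(levelsAll[stateOut],
                                     levels = levelsAll),
                      lx = trajOut[, 1], ly = trajOut[, 2],
                      lz = trajOut[, 3], rx = trajOut[, 4],
                      ry = trajOut[, 5], rz = trajOut[, 6],
                      satisfaction = satOut)
  list(steps = steps, model = model)
}

#' Train and decode a bank of per-frequency models
#'
#' One independent model (own SNN and ESN) per fundamental frequency,
#' each trained on `trainSession` and decoded on `testSession`.
#'
#' @param config a `RunConfig`; its `frequency` is overridden per member.
#' @param trainSession,testSession [ECoGSession-class] objects.
#' @param frequencies member fundamental frequencies (Hz).
#' @return list with `predictions` (list of per-member decoded state
#'   factors on the test session), `models`, and `frequencies`.
#' @export
runBank <- function(config, trainSession, testSession,
                    frequencies = frequencyBank()) {
  members <- lapply(seq_along(frequencies), function(i) {
    cfg <- config
    cfg$frequency <- frequencies[i]
    cfg$seed <- config$seed + i
    fit <- runOnline(cfg, trainSession, train = TRUE)
    dec <- runOnline(cfg, testSession, model = fit$model, train = FALSE)
    list(model = dec$model, states = dec$steps$state)
  })
  list(predictions = lapply(members, `[[`, "states"),
       models = lapply(members, `[[`, "model"),
       frequencies = frequencies)
}

#' Threshold voting across ensemble members
#'
#' Per window, the plurality label among the members wins if its
#' supporter count reaches `threshold`; otherwise, and on plurality ties,
#' the `fallback` label is returned.
#'
#' @param predictions list of equal-length label vectors (one per member).
#' @param threshold minimum number of agreeing members.
#' @param fallback label used when the threshold is not met (typically the
#'   idle state).
#' @return character vector of voted labels.
#' @export
vote <- function(predictions, threshold, fallback) {
  if (length(predictions) == 0L) stop("empty member set")
  lens <- lengths(predictions)
  if (length(unique(lens)) != 1L)
    stop("member predictions must have equal length")
  if (threshold < 1 || threshold > length(predictions))
    stop("threshold must be in [1, number of members]")
  mat <- do.call(cbind, lapply(predictions, as.character))
  apply(mat, 1, function(v) {
    tab <- table(v)
    top <- tab[tab == max(tab)]
    if (length(top) > 1L || top[1] < threshold) as.character(fallback)
    else names(top)
  })
}

#' Select the voting threshold by balanced accuracy
#'
#' Evaluates every candidate threshold on validation truth and returns the
#' one maximising the balanced accuracy of the voted decision; ties go to
#' the smaller threshold.
#'
#' @param predictions list of per-member label vectors.
#' @param truth true labels.
#' @param candidates candidate thresholds; defaults to
#'   `1:length(predictions)`.
#' @param fallback fallback label passed to [vote()].
#' @return the selected threshold (integer).
#' @export
selectVotingThreshold <- function(predictions, truth,
                                  candidates = seq_along(predictions),
                                  fallback) {
  if (length(candidates) == 0L) stop("empty candidate set")
  acc <- vapply(candidates, function(th)
    balancedAccuracy(truth, vote(predictions, th, fallback)), numeric(1))
  candidates[which.max(acc)]
}

#' Write decoded steps to CSV
#'
#' One row per window with a fixed header: window index, decoded state,
#' six trajectory coordinates and the satisfaction label. Round-trips
#' losslessly through [readOutputs()].
#'
#' @param steps the `steps` data.frame from [runOnline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeOutputs <- function(steps, path) {
  cols <- c("window", "state", "lx", "ly", "lz", "rx", "ry", "rz",
            "satisfaction")
  utils::write.csv(steps[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOutputs
#' @export
readOutputs <- function(path) {
  if (!file.exists(path)) stop("output CSV not found: ", path)
  out <- utils::read.csv(path)
  out$state <- as.character(out$state)
  out
}
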