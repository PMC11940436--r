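# JSON model checkpoints. Matrices are stored as nested arrays (dense) or
# triplets (sparse); everything needed to resume decoding — both weight
# matrices, every head's weights and learning state, the frozen feature
# statistics and the run configuration — travels in one portable text file.

headToList <- function(h) {
  list(Wout = h@Wout, P = h@P, forgetting = h@forgetting, E = h@E,
       alpha = h@alpha, delta = h@delta)
}

listToHead <- function(l) {
  new("ReadoutHead", Wout = asMatrix(l$Wout), P = asMatrix(l$P),
      forgetting = l$forgetting, E = asMatrix(l$E), alpha = l$alpha,
      delta = l$delta)
}

asMatrix <- function(x) {
  if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
}

sparseToList <- function(W) {
  s <- Matrix::summary(W)
  list(i = s$i, j = s$j, x = s$x, dim = dim(W))
}

listToSparse <- function(l) {
  as(Matrix::sparseMatrix(i = l$i, j = l$j, x = l$x,
                          dims = as.integer(l$dim)), "CsparseMatrix")
}

#' Save / load a decoder model checkpoint (JSON)
#'
#' @param model an [MCDModel-class].
#' @param path checkpoint path (JSON text).
#' @return `path` invisibly (`saveModel`); the model (`loadModel`).
#' @export
saveModel <- function(model, path) {
  snn <- model@snn; esn <- model@esn
  obj <- list(
    format = "mcdecode-model-v1",
    config = model@config,
    featureStats = model@featureStats,
    snn = list(
      positions = snn@positions,
      weights = sparseToList(snn@weights),
      delay = snn@delay, synapticCharge = snn@synapticCharge,
      lif = list(vTh = snn@lif@vTh, eL = snn@lif@eL,
                 vReset = snn@lif@vReset, tauM = snn@lif@tauM,
                 cM = snn@lif@cM, tRef = snn@lif@tRef, dt = snn@lif@dt),
      stdp = list(lambdaRate = snn@stdp@lambdaRate,
                  tauPlus = snn@stdp@tauPlus,
                  tauMinus = snn@stdp@tauMinus,
                  asymmetry = snn@stdp@asymmetry, wMax = snn@stdp@wMax),
      electrodeMap = snn@electrodeMap,
      state = snn@state),
    esn = list(Win = esn@Win, Wres = sparseToList(esn@Wres), a = esn@a,
               R = esn@R, rho = esn@rho,
               heads = lapply(esn@heads, headToList)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mcdecode-model-v1"))
    stop("not a model checkpoint: ", path)
  s <- obj$snn
  snn <- new("SNNetwork", positions = asMatrix(s$positions),
             weights = listToSparse(s$weights), delay = s$delay,
             synapticCharge = s$synapticCharge,
             lif = do.call(new, c(list("LIFParams"), s$lif)),
             stdp = do.call(new, c(list("STDPParams"), s$stdp)),
             electrodeMap = as.integer(s$electrodeMap),
             state = list(v = as.numeric(s$state$v),
                          refrac = as.numeric(s$state$refrac),
                          t0 = s$state$t0))
  e <- obj$esn
  esn <- new("ESNModel", Win = asMatrix(e$Win),
             Wres = listToSparse(e$Wres), a = e$a, R = as.numeric(e$R),
             rho = e$rho, heads = lapply(e$heads, listToHead))
  cfg <- obj$config
  cfg$stateLevels <- as.character(cfg$stateLevels)
  fs <- obj$featureStats
  new("MCDModel", snn = snn, esn = esn,
      featureStats = list(calibrated = isTRUE(fs$calibrated),
                          mean = as.numeric(fs$mean),
                          sd = as.numeric(fs$sd),
                          rateMean = if (is.null(fs$rateMean)) NULL else
                            as.numeric(fs$rateMean),
                          rateSd = if (is.null(fs$rateSd)) NULL else
                            as.numeric(fs$rateSd)),
      config = cfg)
}
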