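# Small fixtures built in code: short synthetic sessions and desk-scale
# configs so unit tests stay fast.

tinySession <- function(minutes = 0.25, task = "runner", effectSize = 1,
                        seed = 5L, nChannels = 8L, ...) {
  generateSession(synthSpec(nChannels = nChannels, task = task,
                            minutes = minutes, effectSize = effectSize,
                            seed = seed, ...))
}

tinyConfig <- function(task = "runner", ...) {
  runConfig(task = task, approach = "morlet", frequency = 30,
            calibWindows = 5L, snn = list(nFiller = 4L),
            esn = list(N = 40L), seed = 11L, ...)
}

# analytic inter-spike interval of a LIF neuron under constant current
lifPeriod <- function(I, lif = new("LIFParams")) {
  x <- I * lif@tauM / lif@cM
  gap <- lif@vTh - lif@eL
  lif@tauM * log(x / (x - gap)) + lif@tRef
}

# single isolated neuron driven by a constant current for `duration` ms
isolatedNeuronSpikes <- function(I, duration = 1000, dt = 0.01,
                                 tRef = 0) {
  lif <- new("LIFParams", dt = dt, tRef = tRef)
  net <- buildNetwork(matrix(0, 1, 3), matrix(0, 1, 3), pLong = 0,
                      lif = lif)
  cur <- matrix(I, 1, 59)
  simulateWindow(net, cur, gain = 1, duration = duration)$record@spikes[[1]]
}

# FFT band power of one channel around f0 (+- half bandwidth), used as the
# independent oracle for Morlet band-power checks
fftBandPower <- function(x, fs, f0, halfWidth = 5) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  sel <- freq >= f0 - halfWidth & freq <= f0 + halfWidth
  sum(sp[sel])
}
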