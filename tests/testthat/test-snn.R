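test_that("small-world weights follow the exponential distance rule", {
  # two coincident neurons: weight w0 both directions
  pos <- matrix(0, 2, 3)
  net <- buildNetwork(pos, pos[1, , drop = FALSE], w0 = 1.5, pLong = 0)
  expect_equal(net@weights[1, 2], 1.5)
  expect_equal(net@weights[2, 1], 1.5)
  expect_equal(Matrix::diag(net@weights), c(0, 0))

  # distances d and 2d: weight ratio exp(-d / sigmaD)
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  net <- buildNetwork(pos, pos, w0 = 1, sigmaD = 5, dCut = 100, pLong = 0)
  expect_equal(net@weights[1, 2] / net@weights[1, 3], exp(3 / 5),
               tolerance = 1e-12)
  expect_equal(net@weights[1, 2], exp(-3 / 5), tolerance = 1e-12)

  # beyond the cutoff with pLong = 0: no connection
  net <- buildNetwork(pos, pos, sigmaD = 5, dCut = 4, pLong = 0)
  expect_equal(net@weights[1, 3], 0)
  expect_gt(net@weights[1, 2], 0)

  expect_error(buildNetwork(matrix(0, 0, 3), matrix(0, 1, 3)),
               "at least one")
})

test_that("network build is reproducible and maps electrodes to nearest", {
  pos <- neuronTemplate(electrodeGrid(4, 4), nFiller = 20, seed = 2)
  n1 <- buildNetwork(pos, electrodeGrid(4, 4), pLong = 0.1, seed = 42)
  n2 <- buildNetwork(pos, electrodeGrid(4, 4), pLong = 0.1, seed = 42)
  expect_identical(n1@weights, n2@weights)
  # first 16 template neurons sit exactly at the electrodes
  expect_equal(n1@electrodeMap, 1:16)
})

test_that("subthreshold and zero drive produce no spikes", {
  expect_length(isolatedNeuronSpikes(0, duration = 500, dt = 0.1), 0L)
  # rheobase: I * tau / C < vTh - eL  =>  I < 125 pA
  expect_length(isolatedNeuronSpikes(124, duration = 2000, dt = 0.1), 0L)
})

test_that("constant-current ISI matches the closed-form LIF period", {
  for (I in c(150, 300)) {
    st <- isolatedNeuronSpikes(I, duration = 1000, dt = 0.01)
    isi <- diff(st)
    expect_gt(length(isi), 5)
    expect_lt(abs(mean(isi) - lifPeriod(I)) / lifPeriod(I), 0.01)
  }
})

test_that("refractory period separates spikes and caps the rate", {
  st <- isolatedNeuronSpikes(400, duration = 1000, dt = 0.01, tRef = 5)
  expect_true(all(diff(st) >= 5))
  expect_lt(abs(mean(diff(st)) - lifPeriod(400, new("LIFParams", tRef = 5))) /
              lifPeriod(400, new("LIFParams", tRef = 5)), 0.01)
})

test_that("with zero weights neurons are independent of each other", {
  pos <- neuronTemplate(electrodeGrid(2, 2), nFiller = 2, seed = 3)
  net <- buildNetwork(pos, electrodeGrid(2, 2), w0 = 1, pLong = 0)
  netZero <- net
  netZero@weights@x[] <- 0
  set.seed(8)
  cur <- matrix(runif(4 * 59, 0, 300), 4)
  coupled <- simulateWindow(netZero, cur, duration = 100)$record
  for (k in 1:4) {
    iso <- buildNetwork(matrix(0, 1, 3), matrix(0, 1, 3), pLong = 0)
    alone <- simulateWindow(iso, cur[k, , drop = FALSE],
                            duration = 100)$record
    expect_equal(coupled@spikes[[net@electrodeMap[k]]], alone@spikes[[1]])
  }
})

test_that("halving the integration step changes spike counts by <= 2%", {
  pos <- neuronTemplate(electrodeGrid(4, 4), nFiller = 34, seed = 4)
  set.seed(9)
  cur <- matrix(runif(16 * 59, 0, 250), 16)
  counts <- sapply(c(0.1, 0.05), function(step) {
    net <- buildNetwork(pos, electrodeGrid(4, 4), pLong = 0,
                        lif = new("LIFParams", dt = step))
    rec <- simulateWindow(net, cur, duration = 500)$record
    sum(lengths(rec@spikes))
  })
  expect_gt(counts[1], 100)   # the comparison is meaningful
  expect_lt(abs(counts[1] - counts[2]) / counts[2], 0.02)
})

test_that("membrane state persists across consecutive windows", {
  net <- buildNetwork(matrix(0, 1, 3), matrix(0, 1, 3), pLong = 0)
  cur <- matrix(150, 1, 59)
  # one long window vs the same drive split into two halves
  whole <- simulateWindow(net, cur, duration = 200)$record@spikes[[1]]
  first <- simulateWindow(net, cur, duration = 100)
  second <- simulateWindow(first$net, cur, duration = 100)
  stitched <- c(first$record@spikes[[1]], second$record@spikes[[1]] + 100)
  expect_equal(stitched, whole)
})

test_that("STDP matches the pair rule and clips to [0, wMax]", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  net <- buildNetwork(pos, pos, w0 = 1, sigmaD = 10, pLong = 0,
                      stdp = new("STDPParams", lambdaRate = 0.01,
                                 wMax = 2))
  w0 <- net@weights[1, 2]

  # no spikes: unchanged
  rec <- new("SpikeRecord", spikes = list(numeric(), numeric()),
             windowDuration = 100)
  expect_identical(stdpStep(net, rec)@weights, net@weights)

  # pre at 10 ms, post at 15 ms: potentiation by lambda*wMax*exp(-5/tau+)
  rec <- new("SpikeRecord", spikes = list(10, 15), windowDuration = 100)
  upd <- stdpStep(net, rec)
  expect_equal(upd@weights[1, 2] - w0, 0.01 * 2 * exp(-5 / 20),
               tolerance = 1e-12)
  # the reverse synapse saw post(neuron1)-before-pre(neuron2): depression
  expect_lt(upd@weights[2, 1], net@weights[2, 1])
  expect_equal(net@weights[2, 1] - upd@weights[2, 1],
               1.05 * 0.01 * 2 * exp(-5 / 20), tolerance = 1e-12)

  # a zero synapse that only depresses stays at zero
  netz <- net
  netz@weights@x[] <- 0
  updz <- stdpStep(netz, rec)
  expect_equal(updz@weights[2, 1], 0)
  expect_gt(updz@weights[1, 2], 0)   # potentiation can revive it

  # weights remain in [0, wMax] over many random windows
  set.seed(10)
  for (i in 1:200) {
    spk1 <- sort(runif(rpois(1, 4), 0, 100))
    spk2 <- sort(runif(rpois(1, 4), 0, 100))
    rec <- new("SpikeRecord", spikes = list(spk1, spk2),
               windowDuration = 100)
    net <- stdpStep(net, rec)
  }
  expect_true(all(net@weights@x >= 0))
  expect_true(all(net@weights@x <= 2))
})

test_that("spike-rate features implement count over window duration", {
  rec <- new("SpikeRecord",
             spikes = list(seq(0, 99, length.out = 10), numeric()),
             windowDuration = 59 * 1000 / 585.6)
  rates <- spikeRateFeatures(rec, c(1L, 2L))
  expect_equal(rates[1], 10 / (59 / 585.6), tolerance = 1e-12)
  expect_equal(round(rates[1], 2), 99.25)
  expect_equal(rates[2], 0)
  rec2 <- rec
  rec2@windowDuration <- 2 * rec@windowDuration
  expect_equal(spikeRateFeatures(rec2, 1L), rates[1] / 2)
})

test_that("network snapshots round-trip through the text format", {
  pos <- neuronTemplate(electrodeGrid(2, 2), nFiller = 3, seed = 6)
  net <- buildNetwork(pos, electrodeGrid(2, 2), pLong = 0.2, seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  saveNetwork(net, path)
  back <- loadNetwork(path)
  expect_equal(as.matrix(back@weights), as.matrix(net@weights))
  expect_equal(back@positions, net@positions)
  expect_equal(back@electrodeMap, net@electrodeMap)
  expect_equal(back@lif@vTh, net@lif@vTh)
  expect_equal(back@stdp@lambdaRate, net@stdp@lambdaRate)
})

test_that("state reset restores rest without touching learned weights", {
  pos <- neuronTemplate(electrodeGrid(2, 2), nFiller = 2, seed = 3)
  net <- buildNetwork(pos, electrodeGrid(2, 2), pLong = 0)
  run <- simulateWindow(net, matrix(200, 4, 59), duration = 100)
  expect_false(all(run$net@state$v == net@lif@eL))
  back <- resetNetworkState(run$net)
  expect_equal(back@state$v, rep(net@lif@eL, nrow(pos)))
  expect_equal(back@state$t0, 0)
  expect_identical(back@weights, run$net@weights)
})
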