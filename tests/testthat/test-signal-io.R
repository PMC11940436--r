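test_that("EDF write/read round-trips within quantisation", {
  ses <- tinySession(minutes = 0.1, nChannels = 4L)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(ses, path)
  back <- readEDF(path)
  expect_equal(nChannels(back), 4L)
  expect_equal(samplingRate(back), 585.6)
  n <- nSamples(ses)
  qstep <- (apply(ses@signal, 1, max) - apply(ses@signal, 1, min)) / 65535
  err <- apply(abs(back@signal[, seq_len(n)] - ses@signal), 1, max)
  expect_true(all(err <= qstep + 1e-9))
})

test_that("EDF channel selection preserves order and subsets", {
  ses <- tinySession(minutes = 0.1, nChannels = 4L)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(ses, path)
  sub <- readEDF(path, channels = c(1L, 3L))
  expect_equal(nChannels(sub), 2L)
  full <- readEDF(path)
  expect_equal(sub@signal, full@signal[c(1, 3), , drop = FALSE])

  ses64 <- tinySession(minutes = 0.05, nChannels = 64L)
  path64 <- withr::local_tempfile(fileext = ".edf")
  writeEDF(ses64, path64)
  cb <- checkerboardSelect(8, 8)
  half <- readEDF(path64, channels = cb)
  expect_equal(nChannels(half), 32L)
})

test_that("EDF reader raises distinct errors", {
  expect_error(readEDF(file.path(tempdir(), "nope.edf")), "not found")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file at all", bad)
  expect_error(readEDF(bad), "corrupt")
  ses <- tinySession(minutes = 0.05, nChannels = 4L)
  ok <- withr::local_tempfile(fileext = ".edf")
  writeEDF(ses, ok)
  expect_error(readEDF(ok, channels = 9L), "out of range")
})

test_that("EDF output is readable by an independent reader", {
  ses <- tinySession(minutes = 0.1, nChannels = 4L)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(ses, path)
  out <- withr::local_tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(r'%s', preload=True, verbose='error')\n",
    "sig = raw.get_data() * 1e6\n",  # MNE converts to volts
    "np.savetxt(r'%s', np.r_[[raw.info['sfreq']], sig.shape, sig[0, :50]])\n"),
    path, out)
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  vals <- scan(out, quiet = TRUE)
  expect_equal(vals[1], 585.6, tolerance = 1e-6)
  expect_equal(vals[2], 4)
  qstep <- (max(ses@signal[1, ]) - min(ses@signal[1, ])) / 65535
  expect_lt(max(abs(vals[-(1:3)] - ses@signal[1, 1:50])), qstep + 1e-9)
})

test_that("checkerboard selection alternates from the first cell", {
  expect_equal(checkerboardSelect(2, 2), c(1L, 4L))
  expect_equal(checkerboardSelect(1, 4), c(1L, 3L))
  expect_length(checkerboardSelect(8, 8), 32L)
  idx <- checkerboardSelect(3, 3)
  expect_equal(idx, c(1L, 3L, 5L, 7L, 9L))
  expect_error(checkerboardSelect(0, 4), "positive")
})

test_that("window partition conserves samples and drops the tail", {
  sig <- matrix(rnorm(2 * 600), 2)
  ses <- ECoGSession(sig, fs = 585.6)
  w <- makeWindows(ses, 59)
  expect_length(w, 10L)
  expect_equal(do.call(cbind, w), sig[, 1:590])
  expect_length(makeWindows(ECoGSession(sig[, 1:590], fs = 585.6), 59), 10L)
  expect_error(makeWindows(ECoGSession(sig[, 1:58, drop = FALSE],
                                       fs = 585.6), 59), "exceeds")
})

test_that("shift features are non-negative and offset-invariant", {
  expect_equal(as.numeric(shiftFeatures(matrix(c(-3, 0, 2), 1))),
               c(0, 3, 5))
  expect_equal(as.numeric(shiftFeatures(matrix(0, 1, 5))), rep(0, 5))
  w <- matrix(rnorm(3 * 59), 3)
  shifted <- w + c(5, -2, 100)
  expect_equal(unclass(shiftFeatures(w)), unclass(shiftFeatures(shifted)),
               ignore_attr = TRUE)
  expect_true(all(shiftFeatures(w) >= 0))
})

test_that("morlet features localise band power at the right frequency", {
  fs <- 585.6
  t <- (1:59) / fs
  # zero in, zero out; quadratic amplitude scaling
  expect_equal(as.numeric(morletFeatures(matrix(0, 1, 59), 30, fs)),
               rep(0, 59))
  s <- matrix(sin(2 * pi * 30 * t), 1)
  f1 <- morletFeatures(s, 30, fs)
  f2 <- morletFeatures(2 * s, 30, fs)
  expect_equal(unclass(f2), 4 * unclass(f1), ignore_attr = TRUE,
               tolerance = 1e-12)
  # 30 Hz sinusoid: power at f0=30 dominates f0=80 by >= 10x
  f80 <- morletFeatures(s, 80, fs)
  expect_gt(mean(f1) / mean(f80), 10)
  expect_true(all(f1 >= 0))
  expect_error(morletFeatures(s, 300, fs), "fs/2")
})

test_that("morlet bank maximises at the frequency nearest a pure tone", {
  fs <- 585.6
  n <- 59 * 8   # a few windows long, cut into windows below
  t <- (1:n) / fs
  for (f in c(20, 50, 100)) {
    x <- matrix(sin(2 * pi * f * t), 1)
    win <- x[, 60:118, drop = FALSE]
    bankPower <- vapply(frequencyBank(), function(f0)
      mean(morletFeatures(win, f0, fs)), numeric(1))
    expect_equal(frequencyBank()[which.max(bankPower)], f)
    # cross-check against the FFT band-power oracle on the same window
    oracle <- vapply(frequencyBank(), function(f0)
      fftBandPower(as.numeric(win), fs, f0), numeric(1))
    expect_equal(frequencyBank()[which.max(oracle)], f)
  }
})

test_that("the frequency bank is 10..150 Hz in steps of 10", {
  fb <- frequencyBank()
  expect_length(fb, 15L)
  expect_equal(fb[1], 10)
  expect_equal(fb[15], 150)
  expect_equal(unique(diff(fb)), 10)
})

test_that("CSV session and label sidecar round-trip", {
  ses <- tinySession(minutes = 0.05, nChannels = 4L)
  sigPath <- withr::local_tempfile(fileext = ".csv")
  labPath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(t(ses@signal)), sigPath, row.names = FALSE)
  writeLabelsCSV(ses, labPath)
  back <- readSessionCSV(sigPath, fs = 585.6, labelPath = labPath)
  expect_equal(back@signal, ses@signal, ignore_attr = TRUE)
  expect_equal(as.character(stateLabels(back)),
               as.character(stateLabels(ses)))
  expect_equal(satisfactionLabels(back), satisfactionLabels(ses))
  expect_equal(updateFlags(back), updateFlags(ses), ignore_attr = TRUE)
})

test_that("overlapping windows and label attachment modes work", {
  sig <- matrix(seq_len(20), 1)
  w <- makeWindows(sig, windowLen = 10, overlap = 5)
  expect_length(w, 3L)
  expect_equal(as.numeric(w[[2]]), 6:15)
  expect_error(makeWindows(sig, 10, overlap = 10), "overlap")

  # window 1 is 30 idle then 29 walk samples: the last-sample rule says
  # walk, the majority rule says idle
  labs <- rep(c("idle", "walk"), c(30, 88))
  expect_equal(as.character(labelsFromSamples(labs, 59)), c("walk", "walk"))
  expect_equal(as.character(labelsFromSamples(labs, 59, mode = "majority")),
               c("idle", "walk"))
  expect_equal(chosenFrequencies(), c(10, 30, 50, 70, 100, 110))
})
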