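# Minimal EDF (European Data Format) codec: 256-byte fixed header, 256 bytes
# of per-signal header fields, then 16-bit little-endian samples interleaved
# per data record. Only equal-rate continuous signals are handled, which is
# what ECoG acquisition produces.

edfField <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  trimws(rawToChar(raw))
}

edfNum <- function(con, n) as.numeric(edfField(con, n))

# format a number into at most `width` ASCII characters (EDF header fields)
edfFmt <- function(x, width) {
  for (digits in seq(10, 1)) {
    s <- formatC(x, format = "g", digits = digits, width = 1)
    s <- trimws(s)
    if (nchar(s) <= width && !is.na(as.numeric(s))) return(s)
  }
  stop(sprintf("cannot represent %g in %d characters", x, width))
}

edfPad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = "-")
}

#' Read an ECoG session from an EDF file
#'
#' Parses the EDF header, checks its internal consistency, and returns the
#' selected signals in acquisition order as an [ECoGSession-class] with the
#' sampling rate taken from the header. Labels are empty until attached
#' (see [attachLabels()]).
#'
#' @param path path to an EDF/EDF+ file.
#' @param channels optional integer vector of 1-based channel indices to
#'   keep, in the requested order (e.g. a checkerboard subset from
#'   [checkerboardSelect()]).
#' @param windowLen decoder window length in samples for the returned
#'   session.
#' @return an [ECoGSession-class].
#' @seealso [writeEDF()], [checkerboardSelect()]
#' @export
readEDF <- function(path, channels = NULL, windowLen = 59L) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edfField(con, 8)
  edfField(con, 80); edfField(con, 80)   # patient / recording id
  edfField(con, 8); edfField(con, 8)     # start date / time
  headerBytes <- edfNum(con, 8)
  edfField(con, 44)                      # reserved
  nRecords <- edfNum(con, 8)
  recDuration <- edfNum(con, 8)
  ns <- suppressWarnings(as.integer(edfField(con, 4)))
  if (is.na(ns) || ns < 1L || is.na(headerBytes) ||
      headerBytes != 256 * (ns + 1) || is.na(recDuration) || recDuration <= 0)
    stop("corrupt EDF header in ", path)
  labels <- vapply(seq_len(ns), function(i) edfField(con, 16), character(1))
  for (i in seq_len(ns)) edfField(con, 80)  # transducer
  for (i in seq_len(ns)) edfField(con, 8)   # physical dimension
  physMin <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  for (i in seq_len(ns)) edfField(con, 80)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) edfNum(con, 8), numeric(1))
  for (i in seq_len(ns)) edfField(con, 32)  # reserved
  if (any(!is.finite(spr)) || any(spr < 1) || any(!is.finite(physMin)) ||
      any(digMax <= digMin))
    stop("corrupt EDF header in ", path)
  if (is.null(channels)) channels <- seq_len(ns)
  channels <- as.integer(channels)
  if (any(channels < 1L) || any(channels > ns))
    stop("channel index out of range: file has ", ns, " signals")
  nRecords <- as.integer(nRecords)
  total <- sum(spr)
  sig <- matrix(0, nrow = length(channels), ncol = spr[channels[1]] * nRecords)
  offsets <- cumsum(c(0, spr))
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRecords)) {
    rec <- readBin(con, "integer", n = total, size = 2, endian = "little",
                   signed = TRUE)
    if (length(rec) < total) stop("truncated EDF data in ", path)
    for (k in seq_along(channels)) {
      ch <- channels[k]
      v <- rec[(offsets[ch] + 1):(offsets[ch] + spr[ch])]
      sig[k, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (v - digMin[ch]) * scale[ch] + physMin[ch]
    }
  }
  fs <- spr[channels] / recDuration
  if (length(unique(fs)) != 1L)
    stop("selected channels have differing sampling rates")
  rownames(sig) <- labels[channels]
  ECoGSession(sig, fs = fs[1], windowLen = windowLen)
}

#' Write an ECoG session to an EDF file
#'
#' Samples are quantised to 16 bits over each channel's observed range.
#' The record duration is chosen so that `fs * duration` is an integer;
#' the signal is zero-padded to a whole number of records.
#'
#' @param session an [ECoGSession-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(session, path) {
  sig <- session@signal
  fs <- session@fs
  recDuration <- NA_real_
  for (d in c(1, 0.1, 0.2, 0.25, 0.5, 2, 2.5, 4, 5, 10)) {
    if (abs(fs * d - round(fs * d)) < 1e-9) { recDuration <- d; break }
  }
  if (is.na(recDuration))
    stop("sampling rate ", fs, " Hz not representable as an integer number ",
         "of samples per EDF record")
  spr <- as.integer(round(fs * recDuration))
  nRecords <- as.integer(ceiling(ncol(sig) / spr))
  if (ncol(sig) < nRecords * spr)
    sig <- cbind(sig, matrix(0, nrow(sig), nRecords * spr - ncol(sig)))
  nc <- nrow(sig)
  physMin <- apply(sig, 1, min); physMax <- apply(sig, 1, max)
  flat <- physMax - physMin < 1e-12
  physMin[flat] <- physMin[flat] - 1; physMax[flat] <- physMax[flat] + 1
  # use the values as they will be parsed back, so quantisation is exact
  pminS <- vapply(physMin, edfFmt, character(1), width = 8)
  pmaxS <- vapply(physMax, edfFmt, character(1), width = 8)
  physMin <- as.numeric(pminS); physMax <- as.numeric(pmaxS)
  if (any(physMax <= physMin)) {
    physMin <- floor(physMin); physMax <- ceiling(physMax + 1)
    pminS <- vapply(physMin, edfFmt, character(1), width = 8)
    pmaxS <- vapply(physMax, edfFmt, character(1), width = 8)
  }
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edfPad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (nc + 1), 8)
  wr("", 44)
  wr(nRecords, 8)
  wr(edfFmt(recDuration, 8), 8)
  wr(nc, 4)
  chLabels <- rownames(sig)
  if (is.null(chLabels)) chLabels <- sprintf("ECoG %d", seq_len(nc))
  for (i in seq_len(nc)) wr(chLabels[i], 16)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(pminS[i], 8)
  for (i in seq_len(nc)) wr(pmaxS[i], 8)
  for (i in seq_len(nc)) wr(digMin, 8)
  for (i in seq_len(nc)) wr(digMax, 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(spr, 8)
  for (i in seq_len(nc)) wr("", 32)
  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- round((sig[, cols, drop = FALSE] - physMin) * scale + digMin)
    block <- pmin(pmax(block, digMin), digMax)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a session from a numeric CSV table
#'
#' Fallback signal input: one column per channel with a header row. An
#' optional sidecar label CSV (see [readLabelsCSV()]) attaches per-window
#' annotations.
#'
#' @param path CSV of samples x channels.
#' @param fs sampling rate in Hz.
#' @param labelPath optional label CSV path.
#' @param windowLen decoder window length in samples.
#' @return an [ECoGSession-class].
#' @export
readSessionCSV <- function(path, fs, labelPath = NULL, windowLen = 59L) {
  if (!file.exists(path)) stop("CSV file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  session <- ECoGSession(t(as.matrix(tab)), fs = fs, windowLen = windowLen)
  if (!is.null(labelPath)) session <- attachLabels(session, readLabelsCSV(labelPath))
  session
}

#' Read per-window labels from a sidecar CSV
#'
#' The table is keyed by 1-based window index (`window` column) and may
#' contain `state`, trajectory targets (`lx,ly,lz,rx,ry,rz`),
#' `satisfaction` and the three update-flag columns `flag_reinforcement`,
#' `flag_supervised`, `flag_satisfaction`.
#'
#' @param path CSV path.
#' @return a data.frame, one row per window.
#' @export
readLabelsCSV <- function(path) {
  if (!file.exists(path)) stop("label CSV not found: ", path)
  utils::read.csv(path, check.names = FALSE)
}

#' Attach per-window labels to a session
#'
#' @param session an [ECoGSession-class].
#' @param labels a data.frame as returned by [readLabelsCSV()].
#' @return the annotated session.
#' @export
attachLabels <- function(session, labels) {
  nw <- nWindows(session)
  if (!"window" %in% names(labels)) labels$window <- seq_len(nrow(labels))
  if (any(labels$window < 1L) || any(labels$window > nw))
    stop("label window index out of range (session has ", nw, " windows)")
  ord <- order(labels$window)
  labels <- labels[ord, , drop = FALSE]
  if (nrow(labels) != nw)
    stop("labels must cover every window exactly once")
  st <- if ("state" %in% names(labels)) factor(labels$state) else factor()
  trajCols <- c("lx", "ly", "lz", "rx", "ry", "rz")
  traj <- if (all(trajCols %in% names(labels)))
    as.matrix(labels[, trajCols]) else NULL
  sat <- if ("satisfaction" %in% names(labels))
    as.integer(labels$satisfaction) else integer()
  flagCols <- c("flag_reinforcement", "flag_supervised", "flag_satisfaction")
  flags <- if (all(flagCols %in% names(labels))) {
    m <- sapply(labels[, flagCols], function(v) as.logical(as.integer(v)))
    colnames(m) <- c("reinforcement", "supervised", "satisfaction")
    m
  } else NULL
  initialize(session, stateLabels = st, trajectoryTargets = traj,
             satisfactionLabels = sat, updateFlags = flags)
}

#' Write a session's per-window labels to a sidecar CSV
#'
#' @param session an [ECoGSession-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLabelsCSV <- function(session, path) {
  nw <- nWindows(session)
  out <- data.frame(window = seq_len(nw))
  if (length(session@stateLabels)) out$state <- as.character(session@stateLabels)
  if (!is.null(session@trajectoryTargets)) {
    traj <- session@trajectoryTargets
    colnames(traj) <- c("lx", "ly", "lz", "rx", "ry", "rz")
    out <- cbind(out, traj)
  }
  if (length(session@satisfactionLabels))
    out$satisfaction <- session@satisfactionLabels
  if (!is.null(session@updateFlags)) {
    fl <- session@updateFlags * 1L
    colnames(fl) <- c("flag_reinforcement", "flag_supervised",
                      "flag_satisfaction")
    out <- cbind(out, fl)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
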