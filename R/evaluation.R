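#' Balanced accuracy
#'
#' Mean of per-class recalls over the classes observed in the truth;
#' robust to class imbalance (e.g. idle vs movement windows).
#'
#' @param truth,pred equal-length label vectors.
#' @return fraction in \[0, 1\].
#' @export
balancedAccuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  classes <- unique(truth)
  recalls <- vapply(classes, function(cl)
    mean(pred[truth == cl] == cl), numeric(1))
  mean(recalls)
}

#' F-score of one class
#'
#' Harmonic mean of precision and recall for `positive`; 0 by convention
#' when precision or recall is undefined (no predicted or no true
#' positives).
#'
#' @param truth,pred equal-length label vectors.
#' @param positive the positive class label.
#' @return fraction in \[0, 1\].
#' @export
fScore <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (tp == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

#' Mean per-window cosine similarity of trajectories
#'
#' Cosine of the angle between the predicted and true 3D vectors of each
#' window, averaged over the windows where the true vector is nonzero
#' (idle windows with a zero target carry no direction and are skipped).
#'
#' @param predTraj,trueTraj T x 3 coordinate matrices (one hand).
#' @param perWindow average the per-window cosines (the default); when
#'   `FALSE` a single cosine of the flattened whole trajectories is
#'   returned instead.
#' @return mean cosine in \[-1, 1\], or `NA` when the truth is all zero.
#' @export
cosineSimilarity <- function(predTraj, trueTraj, perWindow = TRUE) {
  predTraj <- as.matrix(predTraj); trueTraj <- as.matrix(trueTraj)
  if (!all(dim(predTraj) == dim(trueTraj)))
    stop("trajectory shapes differ")
  if (!perWindow) {
    p <- as.numeric(predTraj); tr <- as.numeric(trueTraj)
    if (sqrt(sum(tr^2)) < 1e-12) return(NA_real_)
    if (sqrt(sum(p^2)) < 1e-12) return(0)
    return(sum(p * tr) / (sqrt(sum(p^2)) * sqrt(sum(tr^2))))
  }
  nrmT <- sqrt(rowSums(trueTraj^2))
  keep <- nrmT > 1e-12
  if (!any(keep)) return(NA_real_)
  nrmP <- sqrt(rowSums(predTraj^2))
  num <- rowSums(predTraj * trueTraj)
  cosw <- ifelse(nrmP > 1e-12, num / (nrmP * nrmT), 0)
  mean(cosw[keep])
}

#' Compare two models' per-session accuracies by t-test
#'
#' Two-sided Welch t-test on per-session balanced accuracies (the paired
#' variant is available when sessions match one-to-one).
#'
#' @param accA,accB per-session accuracy vectors (>= 2 each).
#' @param paired logical; use a paired test.
#' @return the two-sided p-value.
#' @export
compareModels <- function(accA, accB, paired = FALSE) {
  if (length(accA) < 2L || length(accB) < 2L)
    stop("need at least two sessions per model")
  if (isTRUE(all.equal(as.numeric(accA), as.numeric(accB)))) return(1)
  degenerate <- stats::sd(accA) < 1e-14 && stats::sd(accB) < 1e-14
  if (degenerate && !paired)
    return(if (mean(accA) == mean(accB)) 1 else 0)
  stats::t.test(accA, accB, paired = paired)$p.value
}

#' Evaluate decoded steps against a labeled session
#'
#' @param steps the `steps` data.frame from [runOnline()].
#' @param session the [ECoGSession-class] carrying the ground truth.
#' @return list with `balancedAccuracy`, `fscorePerClass`, `cosinePerHand`
#'   (left/right, when trajectory targets exist) and `nWindows`.
#' @export
evaluateDecoding <- function(steps, session) {
  truth <- session@stateLabels
  if (length(truth) == 0L) stop("session has no state labels")
  pred <- steps$state
  classes <- levels(truth)
  out <- list(
    balancedAccuracy = balancedAccuracy(truth, pred),
    fscorePerClass = vapply(classes, function(cl)
      fScore(truth, pred, cl), numeric(1)),
    nWindows = length(pred)
  )
  if (!is.null(session@trajectoryTargets)) {
    tt <- session@trajectoryTargets
    out$cosinePerHand <- c(
      left = cosineSimilarity(as.matrix(steps[, c("lx", "ly", "lz")]),
                              tt[, 1:3]),
      right = cosineSimilarity(as.matrix(steps[, c("rx", "ry", "rz")]),
                               tt[, 4:6]))
  }
  out
}
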