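#' Coverage of the true object region (C_good)
#'
#' `C_good = |detected & truth| / |truth|`: the fraction of the real object
#' region that the detection covers. Undefined when the truth mask has no
#' foreground; such frames return `NA` (with a warning) and are excluded
#' from sequence means by [evaluateMasks()].
#'
#' @param detected,truth logical matrices of the same shape
#' @return value in \[0, 1\], or `NA` for empty truth
#' @export
cGood <- function(detected, truth) {
  checkMaskPair(detected, truth)
  no <- sum(truth)
  if (no == 0L) {
    warning("C_good undefined: truth mask has no object pixels")
    return(NA_real_)
  }
  sum(detected & truth) / no
}

#' False-alarm ratio over the true background (C_false)
#'
#' `C_false = |detected & !truth| / |!truth|`: the fraction of the real
#' background wrongly included in the detection.
#'
#' @param detected,truth logical matrices of the same shape
#' @return value in \[0, 1\]
#' @export
cFalse <- function(detected, truth) {
  checkMaskPair(detected, truth)
  nb <- sum(!truth)
  if (nb == 0L) stop("C_false undefined: truth mask has no background pixels")
  sum(detected & !truth) / nb
}

checkMaskPair <- function(detected, truth) {
  if (!identical(dim(detected), dim(truth)))
    stop("detected and truth masks must have the same shape")
  invisible(TRUE)
}

#' Evaluate detected masks against ground truth
#'
#' Computes per-frame C_good / C_false and their sequence means. Frames with
#' an empty true object region contribute to the C_false mean but are
#' excluded from the C_good mean (coverage of nothing is undefined).
#'
#' @param detected list of logical masks, or a [DetectionSet-class] (its
#'   refined masks are evaluated)
#' @param truth list of logical truth masks, or a [SyntheticScene-class]
#' @param frames optional integer vector of frame indices to evaluate
#'   (e.g. to drop burn-in frames); default all
#' @return an [EvalReport-class]
#' @export
evaluateMasks <- function(detected, truth, frames = NULL) {
  if (is(detected, "DetectionSet")) detected <- refinedMasks(detected)
  if (is(truth, "SyntheticScene")) truth <- truthMasks(truth)
  if (length(detected) != length(truth))
    stop("detected and truth sequences have different lengths")
  if (is.null(frames)) frames <- seq_along(detected)
  cg <- cf <- rep.int(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    cg[k] <- suppressWarnings(cGood(detected[[t]], truth[[t]]))
    cf[k] <- cFalse(detected[[t]], truth[[t]])
  }
  new("EvalReport",
      perFrame = data.frame(frame = frames, cGood = cg, cFalse = cf),
      meanCGood = if (all(is.na(cg))) NA_real_ else mean(cg, na.rm = TRUE),
      meanCFalse = mean(cf))
}

#' Per-pixel single-Gaussian background baseline
#'
#' The classic reference detector: each pixel keeps a running mean and
#' variance; a pixel is foreground when its intensity deviates from the mean
#' by more than `lambda` standard deviations. Mean and variance follow
#' exponential moving averages at rate `rate`, updated only on
#' background-classified pixels (selective update), with the variance
#' floored at `sigmaFloor^2`. Frame 1 initializes the model and emits an
#' all-background mask.
#'
#' @param frames list of numeric matrices or a [SyntheticScene-class]
#' @param lambda standard-deviation multiplier (default 2.5)
#' @param rate EMA learning rate (default 0.05)
#' @param sigmaFloor minimum modeled standard deviation, intensity units
#' @return list of logical foreground masks, one per frame
#' @export
gaussianBaselineDetect <- function(frames, lambda = 2.5, rate = 0.05,
                                   sigmaFloor = 2) {
  if (is(frames, "SyntheticScene")) frames <- sceneFrames(frames)
  if (length(frames) == 0L) stop("empty frame sequence")
  mu <- frames[[1L]]
  v <- matrix(sigmaFloor^2, nrow(mu), ncol(mu))
  masks <- vector("list", length(frames))
  masks[[1L]] <- matrix(FALSE, nrow(mu), ncol(mu))
  for (t in seq_along(frames)[-1L]) {
    x <- frames[[t]]
    fg <- abs(x - mu) > lambda * sqrt(v)
    bg <- !fg
    mu[bg] <- (1 - rate) * mu[bg] + rate * x[bg]
    v[bg] <- pmax((1 - rate) * v[bg] + rate * (x[bg] - mu[bg])^2, sigmaFloor^2)
    masks[[t]] <- fg
  }
  masks
}
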