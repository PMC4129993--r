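#' Detector configuration
#'
#' All tunable parameters of the hierarchical detector, with defaults.
#' Coarse (block) stage: `blockDim` subblock size; `K` model depth per
#' subblock; `T` cumulative-weight threshold separating background entries
#' from transient ones; `TDBase` base feature-distance threshold (intensity
#' units), scaled per block and frame by `alpha + S` (see
#' [adaptiveThreshold()]); `alphaB`/`alphaW` feature and weight learning
#' rates. Fine (pixel) stage: LBP parameters `P`, `R`, `beta` (see
#' [lbpConfig()]); `KPix` texture history depth; `TDPix` texture distance
#' threshold. `cleanup` optionally applies a 3 x 3 morphological opening to
#' the refined mask (off by default; the core method uses none).
#'
#' @param blockDim integer(2), subblock rows/cols
#' @param K model depth (feature vectors per subblock)
#' @param T background cumulative-weight threshold in (0, 1)
#' @param TDBase base distance threshold, intensity units
#' @param alpha constant of the adaptive threshold, in \[0.7, 0.8\]
#' @param alphaB feature/exemplar learning rate in (0, 1)
#' @param alphaW weight learning rate in (0, 1)
#' @param P,R,beta LBP neighbor count, radius, moderation offset
#' @param KPix pixel texture history depth
#' @param TDPix pixel texture distance threshold (> 0)
#' @param cleanup logical, apply morphological opening to refined masks
#' @return validated configuration list
#' @export
detectorConfig <- function(blockDim = c(4L, 4L), K = 3L, T = 0.7,
                           TDBase = 16.5, alpha = 0.75,
                           alphaB = 0.05, alphaW = 0.01,
                           P = 12L, R = 2, beta = 3,
                           KPix = 3L, TDPix = 1.0, cleanup = FALSE) {
  if (T <= 0 || T >= 1) stop("T must lie in (0, 1)")
  if (alpha < 0) stop("alpha must be nonnegative")
  if (alphaB <= 0 || alphaB >= 1 || alphaW <= 0 || alphaW >= 1)
    stop("learning rates must lie in (0, 1)")
  if (K < 1L || KPix < 1L) stop("model depths must be at least 1")
  if (TDPix <= 0) stop("TDPix must be positive")
  c(list(blockDim = as.integer(blockDim), K = as.integer(K), T = T,
         TDBase = TDBase, alpha = alpha, alphaB = alphaB, alphaW = alphaW,
         KPix = as.integer(KPix), TDPix = TDPix, cleanup = isTRUE(cleanup)),
    lbpConfig(P = P, R = R, beta = beta))
}

#' Initialize detector state from the first frame
#'
#' Every subblock receives a background model carrying the frame-1 feature
#' at weight 1 (see [initBlockModel()]); no pixel texture models exist yet.
#' Frame 1 is all-background by construction, so its detection result (see
#' [detectStep()]) is an empty mask pair.
#'
#' @param firstFrame numeric matrix, intensities on the 0-255 scale
#' @param config a [detectorConfig()]
#' @return a [DetectorState-class]
#' @export
initDetector <- function(firstFrame, config = detectorConfig()) {
  grid <- partitionBlocks(firstFrame, config$blockDim[1L], config$blockDim[2L])
  gd <- grid@gridDim
  models <- vector("list", prod(gd))
  for (i in seq_len(gd[1L])) {
    for (j in seq_len(gd[2L])) {
      blk <- blockAt(grid, i, j)
      models[[(i - 1L) * gd[2L] + j]] <-
        initBlockModel(btcFeature(blk), blk, config)
    }
  }
  padDim <- dim(grid@padded)
  new("DetectorState", config = config, blockModels = models,
      gridDim = gd, padDim = padDim, origDim = grid@origDim,
      pixelHist = array(NA_integer_, c(padDim, config$KPix)),
      pixelCount = matrix(0L, padDim[1L], padDim[2L]),
      frameIndex = 1L)
}

#' Advance the detector by one frame
#'
#' The coarse stage classifies every subblock ([classifyAndUpdate()]); the
#' union of object-labeled blocks, painted at block resolution, is the rough
#' object region. Background blocks are final: their pixels are background
#' in both masks and receive no pixel processing. Inside the rough region
#' the fine stage computes the moderated LBP of each pixel, classifies it
#' against its texture history ([classifyPixel()] semantics, vectorized),
#' and absorbs background-classified patterns (FIFO); object-classified
#' pixels form the refined mask and leave their history untouched. All block
#' decisions complete before any pixel processing. Masks are cropped back to
#' the input frame size.
#'
#' @param state a [DetectorState-class]
#' @param frame next frame, same shape as the initializing frame
#' @return list with `state` (advanced), `rough` and `refined` (logical
#'   masks at frame size)
#' @export
detectStep <- function(state, frame) {
  if (state@frameIndex < 1L) stop("detector state not initialized")
  if (!identical(dim(frame), state@origDim))
    stop("frame shape ", paste(dim(frame), collapse = "x"),
         " does not match detector geometry ",
         paste(state@origDim, collapse = "x"))
  cfg <- state@config
  t <- state@frameIndex + 1L
  gd <- state@gridDim
  M <- cfg$blockDim[1L]; N <- cfg$blockDim[2L]
  padded <- padReplicate(frame, state@padDim[1L] - state@origDim[1L],
                         state@padDim[2L] - state@origDim[2L])

  roughBlocks <- matrix(FALSE, gd[1L], gd[2L])
  models <- state@blockModels
  for (i in seq_len(gd[1L])) {
    for (j in seq_len(gd[2L])) {
      idx <- (i - 1L) * gd[2L] + j
      blk <- padded[((i - 1L) * M + 1L):(i * M), ((j - 1L) * N + 1L):(j * N),
                    drop = FALSE]
      res <- classifyAndUpdate(models[[idx]], blk, cfg, frameIndex = t)
      models[[idx]] <- res$model
      roughBlocks[i, j] <- res$label == "object"
    }
  }
  rough <- roughBlocks[rep(seq_len(gd[1L]), each = M),
                       rep(seq_len(gd[2L]), each = N)]

  refined <- matrix(FALSE, state@padDim[1L], state@padDim[2L])
  hist <- state@pixelHist
  count <- state@pixelCount
  if (any(rough)) {
    codes <- lbpCodes(padded, cfg$P, cfg$R, cfg$beta)
    pc <- getPopcount(cfg$P)
    HW <- prod(state@padDim)
    idx <- which(rough)
    isNew <- count[idx] == 0L
    newPix <- idx[isNew]
    oldPix <- idx[!isNew]
    if (length(oldPix)) {
      minHam <- rep.int(Inf, length(oldPix))
      for (k in seq_len(cfg$KPix)) {
        valid <- count[oldPix] >= k
        if (!any(valid)) break
        hk <- hist[oldPix[valid] + (k - 1L) * HW]
        hd <- pc[bitwXor(codes[oldPix[valid]], hk) + 1L]
        minHam[valid] <- pmin(minHam[valid], hd)
      }
      bg <- minHam < cfg$TDPix^2
      bgPix <- oldPix[bg]
      refined[oldPix[!bg]] <- TRUE
      if (length(bgPix)) {
        if (cfg$KPix > 1L)
          for (k in seq.int(cfg$KPix, 2L))
            hist[bgPix + (k - 1L) * HW] <- hist[bgPix + (k - 2L) * HW]
        hist[bgPix] <- codes[bgPix]
        count[bgPix] <- pmin(count[bgPix] + 1L, cfg$KPix)
      }
    }
    if (length(newPix)) {
      # first sight of this pixel: no temporal evidence, classify object
      refined[newPix] <- TRUE
      hist[newPix] <- codes[newPix]
      count[newPix] <- 1L
    }
  }

  rough <- rough[seq_len(state@origDim[1L]), seq_len(state@origDim[2L]),
                 drop = FALSE]
  refined <- refined[seq_len(state@origDim[1L]), seq_len(state@origDim[2L]),
                     drop = FALSE]
  if (cfg$cleanup)
    refined <- EBImage::imageData(EBImage::opening(
      EBImage::Image(t(refined * 1)), EBImage::makeBrush(3L, "box"))) |>
      t() >= 0.5
  state@blockModels <- models
  state@pixelHist <- hist
  state@pixelCount <- count
  state@frameIndex <- t
  list(state = state, rough = rough, refined = refined)
}

#' Run the hierarchical detector over a whole sequence
#'
#' Initializes on the first frame (whose result is all-background) and steps
#' through the rest. Fully deterministic: identical frames and configuration
#' give bit-identical masks.
#'
#' @param frames a list of numeric matrices or a [SyntheticScene-class]
#' @param config a [detectorConfig()]
#' @return a [DetectionSet-class] with one rough and one refined mask per
#'   input frame
#' @examples
#' scn <- generateScene(sceneConfig(height = 48, width = 48, nFrames = 8,
#'   objects = list(list(shape = "disk", size = 10, start = c(12, 12),
#'                       velocity = c(2, 2), intensityOffset = 50,
#'                       textureContrast = 25))))
#' det <- detectSequence(scn)
#' sum(refinedMasks(det)[[8]])
#' @export
detectSequence <- function(frames, config = detectorConfig()) {
  if (is(frames, "SyntheticScene")) frames <- sceneFrames(frames)
  if (length(frames) == 0L) stop("empty frame sequence")
  state <- initDetector(frames[[1L]], config)
  d <- state@origDim
  empty <- matrix(FALSE, d[1L], d[2L])
  rough <- vector("list", length(frames))
  refined <- vector("list", length(frames))
  rough[[1L]] <- empty
  refined[[1L]] <- empty
  for (t in seq_along(frames)[-1L]) {
    step <- detectStep(state, frames[[t]])
    state <- step$state
    rough[[t]] <- step$rough
    refined[[t]] <- step$refined
  }
  new("DetectionSet", rough = rough, refined = refined, config = config)
}

# cache popcount tables per P within a session
.popcountCache <- new.env(parent = emptyenv())
getPopcount <- function(P) {
  key <- as.character(P)
  if (is.null(.popcountCache[[key]]))
    .popcountCache[[key]] <- popcountTable(P)
  .popcountCache[[key]]
}
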