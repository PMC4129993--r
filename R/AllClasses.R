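#' @import methods
NULL

#' BlockGrid: a frame partitioned into nonoverlapping subblocks
#'
#' The coarse detection stage operates on M x N subblocks tiling the frame.
#' Frames whose dimensions are not multiples of the block size are padded by
#' edge replication (last row/column repeated); the padding extent is recorded
#' so masks computed on the padded grid can be cropped back to frame size.
#'
#' @slot padded numeric matrix, the edge-replicated frame actually tiled
#' @slot blockDim integer(2), subblock size c(M, N) in pixels
#' @slot gridDim integer(2), number of block rows and columns
#' @slot padRows,padCols integer(1), rows/cols of replication padding added
#' @slot origDim integer(2), dimensions of the unpadded source frame
#'
#' @seealso [partitionBlocks()], [blockAt()]
#' @exportClass BlockGrid
setClass("BlockGrid",
  representation(
    padded  = "matrix",
    blockDim = "integer",
    gridDim  = "integer",
    padRows  = "integer",
    padCols  = "integer",
    origDim  = "integer"
  )
)

setValidity("BlockGrid", function(object) {
  d <- dim(object@padded)
  if (length(object@blockDim) != 2L || any(object@blockDim < 1L))
    return("blockDim must be two positive integers")
  if (d[1L] != object@gridDim[1L] * object@blockDim[1L] ||
      d[2L] != object@gridDim[2L] * object@blockDim[2L])
    return("padded frame does not tile exactly into gridDim blocks of blockDim")
  if (object@padRows != d[1L] - object@origDim[1L] ||
      object@padCols != d[2L] - object@origDim[2L])
    return("padding bookkeeping inconsistent with dimensions")
  TRUE
})

#' SyntheticScene: a generated frame sequence with ground truth
#'
#' Container for a seeded synthetic underwater-like sequence: grayscale frames
#' on the 0-255 scale and, per frame, the exact binary support of the rendered
#' moving objects.
#'
#' @slot frames list of numeric matrices (intensities in \[0, 255\])
#' @slot truth list of logical matrices (TRUE = object pixel), same length
#' @slot config the [sceneConfig()] list the scene was rendered from
#'
#' @seealso [generateScene()], [standardSuite()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(frames = "list", truth = "list", config = "list")
)

setValidity("SyntheticScene", function(object) {
  if (length(object@frames) != length(object@truth))
    return("frames and truth must have the same length")
  if (length(object@frames) > 0L) {
    d <- dim(object@frames[[1L]])
    okf <- vapply(object@frames, function(f) identical(dim(f), d), logical(1L))
    okt <- vapply(object@truth, function(m) identical(dim(m), d) && is.logical(m),
                  logical(1L))
    if (!all(okf)) return("all frames must share one shape")
    if (!all(okt)) return("all truth masks must be logical and frame-shaped")
  }
  TRUE
})

#' DetectorState: full state of the hierarchical detector
#'
#' Aggregates the per-subblock weighted background models of the coarse stage
#' and the per-pixel LBP texture histories of the fine stage, plus geometry
#' and configuration. Advance it one frame at a time with [detectStep()].
#'
#' @slot config a [detectorConfig()] list
#' @slot blockModels list of per-subblock model records, in row-major block
#'   order (block (i, j) at index `(i - 1) * gridCols + j`)
#' @slot gridDim integer(2), block rows/cols
#' @slot padDim integer(2), padded frame dimensions the state operates on
#' @slot origDim integer(2), dimensions of input frames
#' @slot pixelHist integer array padDim x KPix of stored LBP codes (NA = empty)
#' @slot pixelCount integer matrix, number of stored patterns per pixel
#' @slot frameIndex integer, ordinal of the last frame consumed
#'
#' @seealso [initDetector()], [detectStep()], [detectSequence()]
#' @exportClass DetectorState
setClass("DetectorState",
  representation(
    config      = "list",
    blockModels = "list",
    gridDim     = "integer",
    padDim      = "integer",
    origDim     = "integer",
    pixelHist   = "array",
    pixelCount  = "matrix",
    frameIndex  = "integer"
  )
)

setValidity("DetectorState", function(object) {
  if (length(object@blockModels) != prod(object@gridDim))
    return("blockModels length must equal gridDim product")
  if (!identical(dim(object@pixelCount), object@padDim))
    return("pixelCount shape must match padded frame")
  hd <- dim(object@pixelHist)
  if (length(hd) != 3L || !identical(hd[1:2], object@padDim))
    return("pixelHist must be padDim x KPix")
  TRUE
})

#' DetectionSet: per-frame masks produced by a detector run
#'
#' One rough (block-resolution, painted to pixels) and one refined
#' (pixel-level) foreground mask per input frame, cropped to frame size.
#' The refined foreground is always a subset of the rough foreground: the
#' texture stage only examines pixels inside the rough object region.
#'
#' @slot rough list of logical matrices
#' @slot refined list of logical matrices
#' @slot config the [detectorConfig()] used
#'
#' @seealso [detectSequence()], [roughMasks()], [refinedMasks()]
#' @exportClass DetectionSet
setClass("DetectionSet",
  representation(rough = "list", refined = "list", config = "list")
)

setValidity("DetectionSet", function(object) {
  if (length(object@rough) != length(object@refined))
    return("rough and refined must have the same length")
  for (t in seq_along(object@rough)) {
    if (!identical(dim(object@rough[[t]]), dim(object@refined[[t]])))
      return("rough/refined shape mismatch")
    if (any(object@refined[[t]] & !object@rough[[t]]))
      return("refined foreground must be contained in rough foreground")
  }
  TRUE
})

#' EvalReport: detection-quality summary over a sequence
#'
#' Per-frame coverage (C_good: fraction of the true object region detected)
#' and false-alarm ratio (C_false: fraction of the true background detected),
#' with their sequence means. C_good is undefined on frames with an empty
#' true object region; such frames are excluded from its mean.
#'
#' @slot perFrame data.frame with columns frame, cGood, cFalse
#' @slot meanCGood mean C_good over frames with nonempty truth
#' @slot meanCFalse mean C_false over all evaluated frames
#'
#' @seealso [evaluateMasks()], [cGood()], [cFalse()]
#' @exportClass EvalReport
setClass("EvalReport",
  representation(perFrame = "data.frame", meanCGood = "numeric",
                 meanCFalse = "numeric")
)

setValidity("EvalReport", function(object) {
  v <- c(object@perFrame$cGood, object@perFrame$cFalse)
  v <- v[!is.na(v)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    return("C_good / C_false values must lie in [0, 1]")
  TRUE
})
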