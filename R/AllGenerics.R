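#' Accessors for hierbg containers
#'
#' Slot access for the package's S4 containers: frames and truth masks of a
#' [SyntheticScene-class], rough/refined masks of a [DetectionSet-class], and
#' the per-frame table and means of an [EvalReport-class].
#'
#' @param object a hierbg S4 object
#' @return the requested component (a list of matrices, a data.frame, or a
#'   numeric scalar)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sceneFrames", function(object) standardGeneric("sceneFrames"))

#' @rdname accessors
#' @export
setGeneric("truthMasks", function(object) standardGeneric("truthMasks"))

#' @rdname accessors
#' @export
setGeneric("roughMasks", function(object) standardGeneric("roughMasks"))

#' @rdname accessors
#' @export
setGeneric("refinedMasks", function(object) standardGeneric("refinedMasks"))

#' @rdname accessors
#' @export
setGeneric("perFrame", function(object) standardGeneric("perFrame"))

#' @rdname accessors
#' @export
setGeneric("meanCGood", function(object) standardGeneric("meanCGood"))

#' @rdname accessors
#' @export
setGeneric("meanCFalse", function(object) standardGeneric("meanCFalse"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
setMethod("sceneFrames", "SyntheticScene", function(object) object@frames)

#' @rdname accessors
setMethod("truthMasks", "SyntheticScene", function(object) object@truth)

#' @rdname accessors
setMethod("roughMasks", "DetectionSet", function(object) object@rough)

#' @rdname accessors
setMethod("refinedMasks", "DetectionSet", function(object) object@refined)

#' @rdname accessors
setMethod("perFrame", "EvalReport", function(object) object@perFrame)

#' @rdname accessors
setMethod("meanCGood", "EvalReport", function(object) object@meanCGood)

#' @rdname accessors
setMethod("meanCFalse", "EvalReport", function(object) object@meanCFalse)

#' @rdname accessors
setMethod("nFrames", "SyntheticScene", function(object) length(object@frames))

#' @rdname accessors
setMethod("nFrames", "DetectionSet", function(object) length(object@rough))

setMethod("show", "SyntheticScene", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1L]]) else c(0L, 0L)
  nobj <- length(object@config$objects)
  cat("SyntheticScene:", length(object@frames), "frames of", d[1L], "x", d[2L],
      "\n  objects:", nobj,
      " illumination:", object@config$illumination$mode,
      " noise sd:", object@config$noiseSigma,
      " seed:", object@config$seed, "\n")
})

setMethod("show", "DetectionSet", function(object) {
  n <- length(object@refined)
  fg <- vapply(object@refined, sum, numeric(1L))
  cat("DetectionSet:", n, "frames;",
      "refined foreground px per frame: median", stats::median(fg),
      "max", max(fg), "\n")
})

setMethod("show", "DetectorState", function(object) {
  cat("DetectorState: frame", object@frameIndex, "consumed;",
      object@gridDim[1L], "x", object@gridDim[2L], "block grid (",
      object@config$blockDim[1L], "x", object@config$blockDim[2L], "px );",
      sum(object@pixelCount > 0L), "pixels carry texture models\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d frames: mean C_good = %.4f, mean C_false = %.4f\n",
              nrow(object@perFrame), object@meanCGood, object@meanCFalse))
})

setMethod("show", "BlockGrid", function(object) {
  cat("BlockGrid:", object@gridDim[1L], "x", object@gridDim[2L], "blocks of",
      object@blockDim[1L], "x", object@blockDim[2L], "px; padding",
      object@padRows, "rows,", object@padCols, "cols\n")
})
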