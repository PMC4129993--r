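#' Euclidean distance between two LBP texture patterns
#'
#' Computed over the P bit components, `D = sqrt(sum_p (b_p - b'_p)^2)`,
#' which equals the square root of the Hamming distance. The comparison is
#' deliberately per-bit rather than on the packed decimal codes: numerically
#' differencing codes would weight bit 7 over bit 0 by a factor 128 with no
#' textural meaning.
#'
#' @param h,hj `TexturePattern` objects (see [lbpPattern()]) with equal P
#' @return nonnegative distance; patterns differing in k bits give `sqrt(k)`
#' @export
textureDistance <- function(h, hj) {
  if (length(h$bits) != length(hj$bits))
    stop("patterns have different P")
  d <- h$bits - hj$bits
  sqrt(sum(d * d))
}

#' Create a pixel texture model from its first observed pattern
#'
#' Pixels are modeled lazily: a pixel entering the rough object region for
#' the first time gets a history holding only the current pattern. Having no
#' temporal evidence yet, such a pixel classifies as object on the frame of
#' its initialization.
#'
#' @param h the first `TexturePattern`
#' @param frameIndex frame ordinal of initialization
#' @return pixel-model record: list with `codes` (integer FIFO, newest
#'   first), `P`, `initializedAt`
#' @export
newPixelModel <- function(h, frameIndex = 1L) {
  list(codes = h$code, P = h$P, initializedAt = as.integer(frameIndex))
}

#' Classify a pixel from its texture history
#'
#' The pixel is background iff the minimum distance between the current
#' pattern and any stored pattern is below `TDPix`; otherwise object. At the
#' default `TDPix = 1.5` this means background iff some stored pattern is
#' within 2 bits of the current one.
#'
#' @param model record from [newPixelModel()] / [updatePixelModel()]
#' @param h current `TexturePattern`
#' @param TDPix texture distance threshold (> 0)
#' @return "background" or "object"
#' @export
classifyPixel <- function(model, h, TDPix = 1.5) {
  if (length(model$codes) == 0L) stop("empty pixel history")
  ham <- vapply(model$codes, function(code) hammingCodes(code, h$code), numeric(1L))
  if (min(ham) < TDPix^2) "background" else "object"
}

#' Absorb a background-classified pattern into a pixel history
#'
#' FIFO shift: the new pattern enters at the front, older patterns move
#' back, and the oldest is dropped once the history holds `KPix` patterns.
#' Only background-classified pixels call this; object pixels leave their
#' history untouched so the background description is never polluted by the
#' object.
#'
#' @param model pixel-model record
#' @param h the `TexturePattern` to absorb
#' @param KPix history capacity (>= 1)
#' @return updated record
#' @export
updatePixelModel <- function(model, h, KPix = 3L) {
  model$codes <- c(h$code, model$codes)[seq_len(min(KPix, length(model$codes) + 1L))]
  model
}

# Hamming distance between two packed LBP codes
hammingCodes <- function(a, b) {
  x <- bitwXor(as.integer(a), as.integer(b))
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# popcount lookup table for codes in [0, 2^P - 1]
popcountTable <- function(P) {
  vapply(0:(2^P - 1L), function(x) hammingCodes(x, 0L), integer(1L))
}
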