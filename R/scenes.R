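#' Synthetic-scene configuration
#'
#' Describes a seeded underwater-like test sequence: a static smoothed
#' random-texture background plate, an optional global illumination drift
#' (additive or multiplicative ramp across the sequence), an optional
#' localized temporally oscillating "ripple" region (unstable background),
#' zero or more moving textured objects with exact ground-truth support, and
#' per-frame Gaussian sensor noise. Frames are rounded to the integer 8-bit
#' grid, as a camera would deliver them.
#'
#' @param height,width frame size in pixels
#' @param nFrames number of frames (>= 2)
#' @param seed RNG seed; scenes are bit-identical given the same config
#' @param backgroundTextureScale Gaussian smoothing sigma (px) of the plate
#' @param backgroundLevel,backgroundContrast mean and sd of the plate
#' @param noiseSigma per-frame sensor noise sd, intensity units
#' @param illumination list(mode = "none" | "additive_ramp" |
#'   "multiplicative_ramp", start, end); the gain interpolates linearly from
#'   `start` at frame 1 to `end` at the last frame and applies to every pixel
#' @param ripple NULL or list(region = c(row1, row2, col1, col2), amplitude,
#'   period): inside the region, `amplitude * sin(2 pi t / period)` is added
#'   (uniformly, so only the region border changes local texture)
#' @param objects list of object descriptions: list(shape = "disk" |
#'   "rectangle", size (diameter / side, px), start = c(row, col) center,
#'   velocity = c(rows, cols) per frame, intensityOffset (vs background
#'   level), textureContrast (half-range of the object's own fine-scale
#'   texture))
#' @return validated configuration list
#' @export
sceneConfig <- function(height = 96L, width = 96L, nFrames = 60L, seed = 1L,
                        backgroundTextureScale = 6,
                        backgroundLevel = 110, backgroundContrast = 12,
                        noiseSigma = 2,
                        illumination = list(mode = "none", start = 0, end = 0),
                        ripple = NULL,
                        objects = list()) {
  if (nFrames < 2L) stop("nFrames must be at least 2")
  if (noiseSigma < 0) stop("noiseSigma must be nonnegative")
  illumination$mode <- match.arg(illumination$mode,
                                 c("none", "additive_ramp", "multiplicative_ramp"))
  if (!is.null(ripple)) {
    r <- ripple$region
    if (length(r) != 4L || r[1L] < 1L || r[2L] > height ||
        r[3L] < 1L || r[4L] > width || r[1L] > r[2L] || r[3L] > r[4L])
      stop("invalid ripple region")
    if (ripple$amplitude < 0) stop("ripple amplitude must be nonnegative")
  }
  list(height = as.integer(height), width = as.integer(width),
       nFrames = as.integer(nFrames), seed = as.integer(seed),
       backgroundTextureScale = backgroundTextureScale,
       backgroundLevel = backgroundLevel,
       backgroundContrast = backgroundContrast,
       noiseSigma = noiseSigma, illumination = illumination,
       ripple = ripple, objects = objects)
}

#' Generate a synthetic scene
#'
#' Renders the sequence described by a [sceneConfig()]: per frame the static
#' plate gets the illumination gain, the ripple oscillation, the moving
#' objects composited opaquely on top (each object carries its own
#' fine-scale texture patch, rigidly translated along its path), and sensor
#' noise; intensities are clipped to \[0, 255\] and rounded. Truth masks
#' record the exact rendered object support. An object whose support would
#' leave the frame on any frame is an error. The global RNG state is left
#' untouched.
#'
#' @param cfg a [sceneConfig()]
#' @return a [SyntheticScene-class]
#' @export
generateScene <- function(cfg) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(cfg$seed)

  h <- cfg$height; w <- cfg$width
  # blur an enlarged noise field and crop, so the Gaussian brush always fits
  # and the frame edges carry the same texture statistics as the interior
  m <- ceiling(3 * cfg$backgroundTextureScale) + 1L
  z <- EBImage::gblur(matrix(stats::rnorm((h + 2 * m) * (w + 2 * m)),
                             h + 2 * m, w + 2 * m),
                      sigma = cfg$backgroundTextureScale)
  z <- z[(m + 1):(m + h), (m + 1):(m + w)]
  plate <- cfg$backgroundLevel +
    cfg$backgroundContrast * (z - mean(z)) / stats::sd(z)

  objs <- lapply(cfg$objects, function(o) {
    o$shape <- match.arg(o$shape, c("disk", "rectangle"))
    half <- ceiling(o$size / 2) + 2L
    o$patchOff <- half + 1L
    side <- 2L * half + 1L
    o$patch <- matrix(stats::runif(side^2, -o$textureContrast,
                                   o$textureContrast), side, side)
    o
  })

  gains <- switch(cfg$illumination$mode,
    none = rep.int(if (cfg$illumination$mode == "multiplicative_ramp") 1 else 0,
                   cfg$nFrames),
    additive_ramp = ,
    multiplicative_ramp = seq(cfg$illumination$start, cfg$illumination$end,
                              length.out = cfg$nFrames))

  rowIdx <- matrix(seq_len(h), h, w)
  colIdx <- matrix(seq_len(w), h, w, byrow = TRUE)
  frames <- vector("list", cfg$nFrames)
  truth <- vector("list", cfg$nFrames)
  for (t in seq_len(cfg$nFrames)) {
    img <- plate
    mask <- matrix(FALSE, h, w)
    if (!is.null(cfg$ripple)) {
      r <- cfg$ripple$region
      img[r[1L]:r[2L], r[3L]:r[4L]] <- img[r[1L]:r[2L], r[3L]:r[4L]] +
        cfg$ripple$amplitude * sin(2 * pi * t / cfg$ripple$period)
    }
    for (o in objs) {
      ctr <- o$start + (t - 1) * o$velocity
      du <- rowIdx - ctr[1L]
      dv <- colIdx - ctr[2L]
      supp <- if (o$shape == "disk") {
        du^2 + dv^2 <= (o$size / 2)^2
      } else {
        abs(du) <= o$size / 2 & abs(dv) <= o$size / 2
      }
      if (ctr[1L] - o$size / 2 < 1 || ctr[1L] + o$size / 2 > h ||
          ctr[2L] - o$size / 2 < 1 || ctr[2L] + o$size / 2 > w)
        stop("object leaves the frame at frame ", t)
      ui <- round(du[supp]) + o$patchOff
      vi <- round(dv[supp]) + o$patchOff
      img[supp] <- cfg$backgroundLevel + o$intensityOffset +
        o$patch[cbind(ui, vi)]
      mask <- mask | supp
    }
    img <- switch(cfg$illumination$mode,
                  none = img,
                  additive_ramp = img + gains[t],
                  multiplicative_ramp = img * gains[t])
    if (cfg$noiseSigma > 0)
      img <- img + stats::rnorm(h * w, 0, cfg$noiseSigma)
    frames[[t]] <- round(pmin(pmax(img, 0), 255))
    truth[[t]] <- mask
  }
  new("SyntheticScene", frames = frames, truth = truth, config = cfg)
}

#' Standard synthetic test suite
#'
#' Eight fixed, seeded scene configurations: four families ("static", no
#' object; "close", one large object of diameter about a quarter of the
#' frame; "distant", one 5 px object; "multi", two objects, one bright disk
#' and one dark square) each in a clean variant (no noise, stable
#' illumination) and a degraded variant. Degraded object scenes add the
#' additive illumination ramp, the oscillating ripple region, and sensor
#' noise; the degraded static scene carries the ramp and the noise, so an
#' empty detection on it isolates illumination robustness.
#'
#' @param baseSeed integer offset for the per-scene seeds
#' @return named list of [sceneConfig()] objects; pass each to
#'   [generateScene()]
#' @examples
#' suite <- standardSuite()
#' names(suite)
#' @export
standardSuite <- function(baseSeed = 904L) {
  ramp <- list(mode = "additive_ramp", start = 0, end = 12)
  flat <- list(mode = "none", start = 0, end = 0)
  ripple <- list(region = c(60L, 87L, 8L, 35L), amplitude = 8, period = 12)
  # objects are deliberately low-contrast: their intensity range overlaps the
  # background, so parts of each object are "similar to the background" - the
  # regime that breaks pure-intensity per-pixel detectors underwater
  closeObj <- list(list(shape = "disk", size = 22, start = c(12, 12),
                        velocity = c(1.2, 1.2), intensityOffset = 30,
                        textureContrast = 30))
  distantObj <- list(list(shape = "disk", size = 5, start = c(20, 14),
                          velocity = c(0.8, 1.2), intensityOffset = 35,
                          textureContrast = 25))
  multiObj <- list(
    list(shape = "disk", size = 14, start = c(24, 10),
         velocity = c(0.25, 1.2), intensityOffset = 30, textureContrast = 30),
    list(shape = "rectangle", size = 12, start = c(72, 12),
         velocity = c(-0.25, 1.2), intensityOffset = -30, textureContrast = 25))
  mk <- function(seedOff, noise, illum, rip, objects)
    sceneConfig(seed = baseSeed + seedOff, noiseSigma = noise,
                illumination = illum, ripple = rip, objects = objects)
  list(
    static_clean    = mk(1L, 0, flat, NULL, list()),
    static_degraded = mk(2L, 2, ramp, NULL, list()),
    close_clean     = mk(3L, 0, flat, NULL, closeObj),
    close_degraded  = mk(4L, 2, ramp, ripple, closeObj),
    distant_clean   = mk(5L, 0, flat, NULL, distantObj),
    distant_degraded = mk(6L, 2, ramp, ripple, distantObj),
    multi_clean     = mk(7L, 0, flat, NULL, multiObj),
    multi_degraded  = mk(8L, 2, ramp, ripple, multiObj)
  )
}
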