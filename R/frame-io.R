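#' Read an ordered frame sequence from a directory
#'
#' Reads every raster image in `path` (PNG, TIFF, PGM/PNM) as a grayscale
#' frame on the 0-255 intensity scale. Files are ordered by the numeric part
#' of their names (`f1, f2, f10`, not `f1, f10, f2`); color images are
#' converted with [toGrayscale()]. All frames must share one shape.
#'
#' @param path directory containing the frames, or a character vector of
#'   image file paths (used in the given order)
#' @param pattern optional regular expression restricting the files read
#' @return a list of numeric matrices, intensities in \[0, 255\]
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeMasks(list(matrix(c(TRUE, FALSE), 4, 4)), d, prefix = "f")
#' frames <- loadFrames(d)
#' length(frames)
#' @export
loadFrames <- function(path, pattern = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, full.names = TRUE,
                        pattern = "\\.(png|tif|tiff|pgm|ppm|pnm)$",
                        ignore.case = TRUE)
    if (!is.null(pattern))
      files <- files[grepl(pattern, basename(files))]
    files <- files[orderFilenames(basename(files))]
  } else {
    if (!all(file.exists(path)))
      stop("input path does not exist: ", paste(path[!file.exists(path)], collapse = ", "))
    files <- path
  }
  if (length(files) == 0L)
    stop("no frames found under ", paste(path, collapse = ", "))
  frames <- lapply(files, readFrame)
  d <- dim(frames[[1L]])
  for (t in seq_along(frames))
    if (!identical(dim(frames[[t]]), d))
      stop("frame shape mismatch: '", basename(files[t]), "' is ",
           paste(dim(frames[[t]]), collapse = "x"), ", expected ",
           paste(d, collapse = "x"))
  frames
}

# order filenames by their embedded integer (first digit run), falling back
# to lexicographic order for names without digits or with equal numbers
orderFilenames <- function(x) {
  num <- suppressWarnings(as.integer(sub("^\\D*(\\d+).*$", "\\1", x)))
  num[!grepl("\\d", x)] <- NA_integer_
  order(num, x, na.last = TRUE)
}

# read one raster file as a grayscale 0-255 matrix (rows = image rows)
readFrame <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("pgm", "pnm", "ppm")) return(readPGM(file))
  img <- EBImage::imageData(EBImage::readImage(file))
  # EBImage stores [x, y(, c)] on a [0,1] scale
  if (length(dim(img)) == 2L) {
    t(img) * 255
  } else if (length(dim(img)) == 3L && dim(img)[3L] >= 3L) {
    toGrayscale(aperm(img[, , 1:3, drop = FALSE], c(2L, 1L, 3L)) * 255)
  } else if (length(dim(img)) == 3L && dim(img)[3L] == 1L) {
    t(img[, , 1L]) * 255
  } else {
    stop("unsupported channel count in ", file)
  }
}

#' Convert a color raster to a grayscale frame
#'
#' BT.601 luma: `0.299 R + 0.587 G + 0.114 B`, clipped to \[0, 255\].
#'
#' @param colorFrame H x W x 3 numeric array on the 0-255 scale
#' @return H x W numeric matrix
#' @examples
#' arr <- array(77, dim = c(2, 2, 3))
#' toGrayscale(arr)  # gray input is a fixed point
#' @export
toGrayscale <- function(colorFrame) {
  d <- dim(colorFrame)
  if (length(d) != 3L || d[3L] != 3L)
    stop("expected an H x W x 3 array, got dimensions ",
         paste(d, collapse = "x"))
  y <- 0.299 * colorFrame[, , 1L] + 0.587 * colorFrame[, , 2L] +
       0.114 * colorFrame[, , 3L]
  matrix(pmin(pmax(y, 0), 255), d[1L], d[2L])
}

#' Partition a frame into nonoverlapping subblocks
#'
#' Pads the frame by edge replication up to the next multiple of the block
#' size, then tiles it into an M x N block grid (the unit of the coarse
#' detection stage). Edge replication is used rather than zero fill so the
#' padding does not manufacture high-contrast block features at the borders.
#'
#' @param frame numeric matrix
#' @param M,N subblock height and width in pixels (both >= 2)
#' @return a [BlockGrid-class]
#' @examples
#' g <- partitionBlocks(matrix(0, 17, 16), 8, 8)
#' g@gridDim  # 3 x 2, with 7 padded rows
#' @export
partitionBlocks <- function(frame, M = 8L, N = 8L) {
  if (M < 2L || N < 2L) stop("block size must be at least 2 x 2")
  d <- dim(frame)
  gr <- as.integer(ceiling(d[1L] / M))
  gc <- as.integer(ceiling(d[2L] / N))
  padded <- padReplicate(frame, gr * M - d[1L], gc * N - d[2L])
  new("BlockGrid", padded = padded,
      blockDim = as.integer(c(M, N)), gridDim = c(gr, gc),
      padRows = as.integer(gr * M - d[1L]), padCols = as.integer(gc * N - d[2L]),
      origDim = as.integer(d))
}

# replicate the last row/column padRows/padCols times
padReplicate <- function(frame, padRows, padCols) {
  d <- dim(frame)
  ri <- c(seq_len(d[1L]), rep.int(d[1L], padRows))
  ci <- c(seq_len(d[2L]), rep.int(d[2L], padCols))
  frame[ri, ci, drop = FALSE]
}

#' Extract one subblock from a BlockGrid
#'
#' @param grid a [BlockGrid-class]
#' @param i,j block row and column (1-based)
#' @return M x N numeric matrix
#' @export
blockAt <- function(grid, i, j) {
  M <- grid@blockDim[1L]; N <- grid@blockDim[2L]
  if (i < 1L || i > grid@gridDim[1L] || j < 1L || j > grid@gridDim[2L])
    stop("block index out of range")
  grid@padded[((i - 1L) * M + 1L):(i * M), ((j - 1L) * N + 1L):(j * N),
              drop = FALSE]
}

#' Write binary masks as image files
#'
#' Masks are written one file per frame with the 0 = background,
#' 255 = foreground convention; they round-trip through [loadMasks()].
#'
#' @param masks list of logical matrices
#' @param path output directory (created if missing)
#' @param prefix filename prefix; files are `<prefix>_0001.<format>`, ...
#' @param format "png", "tiff" or "pgm"
#' @return invisibly, the vector of files written
#' @export
writeMasks <- function(masks, path, prefix = "mask", format = "png") {
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  format <- match.arg(format, c("png", "tiff", "pgm"))
  files <- file.path(path, sprintf("%s_%04d.%s", prefix, seq_along(masks), format))
  for (t in seq_along(masks)) {
    m <- masks[[t]]
    if (format == "pgm") {
      writePGM(ifelse(m, 255, 0), files[t])
    } else {
      EBImage::writeImage(EBImage::Image(t(ifelse(m, 1, 0))), files[t])
    }
  }
  invisible(files)
}

#' Read binary masks back from image files
#'
#' @param path directory of mask images (numeric filename order) or a vector
#'   of files
#' @return list of logical matrices (TRUE = foreground); pixels are
#'   thresholded at half scale
#' @export
loadMasks <- function(path) {
  lapply(loadFrames(path), function(f) f >= 127.5)
}

# --- PGM (P2/P5, maxval <= 255) ------------------------------------------
# No installed R package reads PNM, so a minimal codec lives here.

readPGM <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic '", magic, "'): ", file)
  tokens <- integer(0L)
  # header: width, height, maxval; '#' comments allowed between tokens
  readToken <- function() {
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0L || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch %in% c("\n", "\r")) break
        }
      } else if (!grepl("[[:space:]]", ch)) {
        tok <- ch
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch == "" || grepl("[[:space:]]", ch)) break
          tok <- paste0(tok, ch)
        }
        return(as.integer(tok))
      }
    }
  }
  w <- readToken(); h <- readToken(); maxval <- readToken()
  if (maxval > 255L) stop("16-bit PGM not supported: ", file)
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    txt <- readLines(con, warn = FALSE)
    txt <- sub("#.*$", "", txt)
    vals <- as.integer(scan(text = paste(txt, collapse = " "), quiet = TRUE))
    if (length(vals) < n) stop("truncated P2 data in ", file)
    vals <- vals[seq_len(n)]
  }
  matrix(vals * (255 / maxval), nrow = h, ncol = w, byrow = TRUE)
}

writePGM <- function(mat, file) {
  vals <- as.integer(round(pmin(pmax(mat, 0), 255)))
  con <- file(file, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(mat), nrow(mat)), con, eos = NULL)
  writeBin(as.raw(as.vector(t(matrix(vals, nrow(mat), ncol(mat))))), con)
  invisible(file)
}
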