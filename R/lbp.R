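#' Sample the P circular neighbors of a pixel
#'
#' Neighbor `p` (0-based) sits at angle `2 pi p / P` from the center,
#' starting due east and proceeding counterclockwise: offset
#' `(dx, dy) = (R cos theta, -R sin theta)` with x = column, y = row.
#' Non-integer positions are bilinearly interpolated; positions outside the
#' frame read from an edge-replicated extension. Two classical layouts are
#' kept on the integer grid: `P = 8, R = 1` uses the 8-connected ring
#' (E, NE, N, NW, W, SW, S, SE) and `P = 4, R = 1` the 4-connected cross,
#' with no interpolation.
#'
#' @param frame numeric matrix
#' @param x column of the center pixel (1-based)
#' @param y row of the center pixel (1-based)
#' @param P number of neighbors (>= 4)
#' @param R circle radius in pixels (>= 1)
#' @return numeric vector of P neighbor intensities in sampling order
#' @export
sampleNeighbors <- function(frame, x, y, P = 8L, R = 1) {
  d <- dim(frame)
  if (x < 1L || x > d[2L] || y < 1L || y > d[1L])
    stop("center pixel outside frame")
  off <- neighborOffsets(P, R)
  vapply(seq_len(P), function(p)
    bilinearAt(frame, y + off$dy[p], x + off$dx[p]), numeric(1L))
}

# (dx, dy) offsets of the P neighbors; snaps the classical integer layouts
neighborOffsets <- function(P, R) {
  if (P == 8L && R == 1) {
    dx <- c(1, 1, 0, -1, -1, -1, 0, 1)
    dy <- c(0, -1, -1, -1, 0, 1, 1, 1)
  } else {
    theta <- 2 * pi * (seq_len(P) - 1L) / P
    dx <- R * cos(theta)
    dy <- -R * sin(theta)
    dx[abs(dx - round(dx)) < 1e-9] <- round(dx[abs(dx - round(dx)) < 1e-9])
    dy[abs(dy - round(dy)) < 1e-9] <- round(dy[abs(dy - round(dy)) < 1e-9])
  }
  list(dx = dx, dy = dy)
}

# bilinear sample at (row r, col c), edge-replicated outside the frame
bilinearAt <- function(frame, r, c) {
  d <- dim(frame)
  clampR <- function(v) pmin(pmax(v, 1), d[1L])
  clampC <- function(v) pmin(pmax(v, 1), d[2L])
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  v00 <- frame[clampR(r0), clampC(c0)]
  if (fr == 0 && fc == 0) return(v00)
  v01 <- frame[clampR(r0), clampC(c0 + 1)]
  v10 <- frame[clampR(r0 + 1), clampC(c0)]
  v11 <- frame[clampR(r0 + 1), clampC(c0 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Moderated sign indicator for LBP bits
#'
#' The plain LBP bit is `s(g_p - g_c)` with `s(x) = 1` for `x >= 0`, else 0.
#' In near-flat underwater regions the neighbor-center differences hover
#' around zero and the plain sign is noise-driven, so a moderation offset
#' `beta` is added inside the sign: the bit is `s(g_p - g_c + beta)`, i.e.
#' a neighbor counts as "not darker" unless it is darker by more than `beta`.
#'
#' @param diff neighbor minus center intensity (vectorized)
#' @param beta moderation offset in intensity units (0 recovers plain LBP)
#' @return integer 0/1 bit(s)
#' @examples
#' signIndicator(19 - 20, beta = 0)  # 0: plain sign sees "darker"
#' signIndicator(19 - 20, beta = 3)  # 1: a 1-level dip is tolerated
#' @export
signIndicator <- function(diff, beta = 3) {
  as.integer(diff + beta >= 0)
}

#' Moderated local binary pattern at one pixel
#'
#' Samples the P circular neighbors (see [sampleNeighbors()]), takes the
#' moderated sign of each neighbor-center difference, and packs the bits
#' into a code: `code = sum_p bit_p 2^p` with `p` in sampling order. Because
#' the code depends only on intensity differences, it is exactly invariant
#' under adding a constant to every pixel of the frame.
#'
#' @param frame numeric matrix
#' @param x column of the center pixel
#' @param y row of the center pixel
#' @param P,R,beta see [lbpConfig()]
#' @return list of class `TexturePattern`: `bits` (integer P-vector) and
#'   `code` (integer in \[0, 2^P - 1\])
#' @examples
#' f <- matrix(10, 5, 5); f[3, 3] <- 20
#' lbpPattern(f, 3, 3)$code  # 0: all neighbors darker by 7 or more
#' @export
lbpPattern <- function(frame, x, y, P = 8L, R = 1, beta = 3) {
  g <- sampleNeighbors(frame, x, y, P, R)
  bits <- signIndicator(g - frame[y, x], beta)
  structure(list(bits = bits, code = sum(bits * 2^(seq_len(P) - 1L)), P = P),
            class = "TexturePattern")
}

#' LBP codes of every pixel of a frame
#'
#' Vectorized form of [lbpPattern()] over the whole frame: each neighbor
#' offset contributes one shifted (bilinearly weighted where off-grid) copy
#' of the edge-replicated frame, so the cost is P matrix operations rather
#' than one call per pixel.
#'
#' @inheritParams lbpPattern
#' @return integer matrix of codes, same shape as `frame`
#' @export
lbpCodes <- function(frame, P = 8L, R = 1, beta = 3) {
  d <- dim(frame)
  off <- neighborOffsets(P, R)
  m <- as.integer(ceiling(R)) + 1L
  padded <- frame[pmin(pmax(seq_len(d[1L] + 2L * m) - m, 1L), d[1L]),
                  pmin(pmax(seq_len(d[2L] + 2L * m) - m, 1L), d[2L])]
  rows <- (m + 1L):(m + d[1L])
  cols <- (m + 1L):(m + d[2L])
  codes <- matrix(0L, d[1L], d[2L])
  for (p in seq_len(P)) {
    dy <- off$dy[p]; dx <- off$dx[p]
    r0 <- floor(dy); c0 <- floor(dx)
    fr <- dy - r0; fc <- dx - c0
    nb <- (1 - fr) * ((1 - fc) * padded[rows + r0, cols + c0] +
                      fc * padded[rows + r0, cols + c0 + 1L]) +
          fr * ((1 - fc) * padded[rows + r0 + 1L, cols + c0] +
                fc * padded[rows + r0 + 1L, cols + c0 + 1L])
    codes <- codes + as.integer(nb - frame + beta >= 0) * as.integer(2^(p - 1L))
  }
  codes
}

#' LBP stage configuration
#'
#' @param P neighbors on the sampling circle (default 8)
#' @param R circle radius in pixels (default 1, the 8-connected ring)
#' @param beta moderation offset in intensity units (default 3)
#' @return validated list
#' @export
lbpConfig <- function(P = 8L, R = 1, beta = 3) {
  P <- as.integer(P)
  if (P < 4L) stop("P must be at least 4")
  if (R < 1) stop("R must be at least 1")
  if (beta < 0) stop("beta must be nonnegative")
  list(P = P, R = R, beta = beta)
}
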